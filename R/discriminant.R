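PROVENANCE_COLS <- c("patient_id", "sample_id", "tissue_label", "fov_id",
                     "tile_row", "tile_col")
CLASS_LEVELS <- c("normal", "tumor")

feature_matrix <- function(features, feat_names) {
  missing <- setdiff(feat_names, names(features))
  if (length(missing)) {
    stop("feature columns absent from data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(features[, feat_names, drop = FALSE])
  if (!all(is.finite(X))) {
    bad <- which(rowSums(!is.finite(X)) > 0)[1]
    id <- if ("fov_id" %in% names(features)) features$fov_id[bad] else bad
    stop("non-finite feature value in row ", bad, " (fov ", id, ")",
         call. = FALSE)
  }
  X
}

infer_feature_cols <- function(features) {
  setdiff(names(features), PROVENANCE_COLS)
}

# symmetric-eigendecomposition inverse with ridge escalation when the
# condition number exceeds `cond_max`; returns inverse, log-determinant and
# the relative ridge coefficient actually applied
stable_inverse <- function(S, cond_max = 1e8) {
  d <- nrow(S)
  scale <- sum(diag(S)) / d
  if (scale <= 0) scale <- 1
  eps <- 0
  repeat {
    Sr <- S + diag(eps * scale, d)
    e <- eigen(Sr, symmetric = TRUE)
    cond <- if (min(e$values) <= 0) Inf else max(e$values) / min(e$values)
    if (is.finite(cond) && cond <= cond_max) break
    eps <- if (eps == 0) 1e-8 else eps * 10
    if (eps > 1) stop("covariance matrix is numerically singular",
                      call. = FALSE)
  }
  inv <- e$vectors %*% (t(e$vectors) / e$values)
  list(inv = inv, logdet = sum(log(e$values)), ridge = eps, cov = Sr)
}

#' Fit a Gaussian discriminant classifier
#'
#' Fits the class-conditional Gaussian model underlying linear and
#' quadratic discriminant analysis for the two tissue classes. Class means
#' are per-class sample means. The linear model uses the pooled
#' within-class covariance with divisor `N - K`; the quadratic model uses
#' per-class covariances with divisor `n_k - 1`. When a covariance is
#' ill-conditioned (condition number above 1e8) a ridge term
#' `eps * (trace/dim) * I` is added, with the applied `eps` recorded in the
#' model. `model_type = "prior"` fits no densities and classifies from the
#' class priors alone (a baseline).
#'
#' @param features Tibble with one row per image: the feature columns plus
#'   a `tissue_label` column (`"normal"`/`"tumor"`). Provenance columns
#'   (`patient_id`, `sample_id`, `fov_id`, `tile_row`, `tile_col`) are
#'   ignored during fitting.
#' @param spec Optional [feature_spec()]; when supplied, its
#'   [feature_names()] select and order the feature columns, otherwise all
#'   non-provenance columns are used.
#' @param model_type `"linear"`, `"quadratic"`, or `"prior"`.
#' @param priors `"empirical"` (class frequencies in the training data,
#'   the default) or `"uniform"`.
#' @return An object of class `discriminant_model`.
#' @export
fit_discriminant <- function(features, spec = NULL,
                             model_type = c("linear", "quadratic", "prior"),
                             priors = c("empirical", "uniform")) {
  model_type <- match.arg(model_type)
  priors <- match.arg(priors)
  if (!"tissue_label" %in% names(features)) {
    stop("features must contain a tissue_label column", call. = FALSE)
  }
  labels <- as.character(features$tissue_label)
  if (!all(labels %in% CLASS_LEVELS)) {
    stop("tissue_label values must be 'normal' or 'tumor'", call. = FALSE)
  }
  n_k <- vapply(CLASS_LEVELS, function(k) sum(labels == k), numeric(1))
  if (any(n_k < 2)) {
    stop("class '", CLASS_LEVELS[which(n_k < 2)[1]],
         "' has fewer than 2 training images", call. = FALSE)
  }
  pri <- if (priors == "empirical") n_k / sum(n_k) else c(0.5, 0.5)
  names(pri) <- CLASS_LEVELS

  feat_names <- if (is.null(spec)) infer_feature_cols(features)
                else feature_names(spec)
  model <- list(model_type = model_type, classes = CLASS_LEVELS,
                priors = pri, feature_names = feat_names,
                n_per_class = n_k, priors_mode = priors, spec = spec)

  if (model_type != "prior") {
    X <- feature_matrix(features, feat_names)
    d <- ncol(X)
    means <- do.call(rbind, lapply(CLASS_LEVELS, function(k) {
      colMeans(X[labels == k, , drop = FALSE])
    }))
    dimnames(means) <- list(CLASS_LEVELS, feat_names)
    centered <- X - means[labels, , drop = FALSE]
    if (model_type == "linear") {
      S <- crossprod(centered) / (nrow(X) - length(CLASS_LEVELS))
      si <- stable_inverse(S)
      model$means <- means
      model$cov <- list(pooled = si$cov)
      model$inv <- list(pooled = si$inv)
      model$logdet <- c(pooled = si$logdet)
      model$ridge <- c(pooled = si$ridge)
    } else {
      if (any(n_k <= d)) {
        warning("per-class n <= dimension for quadratic model; ",
                "ridge regularization will be forced if needed",
                call. = FALSE)
      }
      covs <- invs <- list()
      logdet <- ridge <- stats::setNames(numeric(2), CLASS_LEVELS)
      for (k in CLASS_LEVELS) {
        Ck <- centered[labels == k, , drop = FALSE]
        Sk <- crossprod(Ck) / (n_k[[k]] - 1)
        si <- stable_inverse(Sk)
        covs[[k]] <- si$cov; invs[[k]] <- si$inv
        logdet[k] <- si$logdet; ridge[k] <- si$ridge
      }
      model$means <- means
      model$cov <- covs
      model$inv <- invs
      model$logdet <- logdet
      model$ridge <- ridge
    }
  }
  structure(model, class = "discriminant_model")
}

#' @export
print.discriminant_model <- function(x, ...) {
  cat(sprintf(
    "<discriminant_model %s: %d features, n = %s, priors = %s (%s)%s>\n",
    x$model_type, length(x$feature_names),
    paste(sprintf("%s %d", x$classes, x$n_per_class), collapse = " / "),
    paste(sprintf("%.3f", x$priors), collapse = "/"), x$priors_mode,
    if (!is.null(x$ridge) && any(x$ridge > 0))
      sprintf(", ridge %s", paste(format(x$ridge), collapse = "/")) else ""))
  invisible(x)
}

log_density_class <- function(model, X, k) {
  d <- ncol(X)
  if (model$model_type == "linear") {
    inv <- model$inv$pooled; logdet <- model$logdet[["pooled"]]
  } else {
    inv <- model$inv[[k]]; logdet <- model$logdet[[k]]
  }
  dx <- X - matrix(model$means[k, ], nrow(X), d, byrow = TRUE)
  quad <- rowSums((dx %*% inv) * dx)
  -0.5 * (d * log(2 * pi) + logdet + quad)
}

#' Posterior class probabilities
#'
#' Evaluates `posterior_k` proportional to `prior_k * N(x; mu_k, Sigma_k)`
#' in log space with stable (log-sum-exp) normalization.
#'
#' @param model A fitted [fit_discriminant()] model.
#' @param features Tibble (or data frame) containing the model's feature
#'   columns; any provenance columns are carried along untouched.
#' @return The input tibble with columns `posterior_normal` and
#'   `posterior_tumor` appended (each row sums to 1).
#' @export
posterior <- function(model, features) {
  stopifnot(inherits(model, "discriminant_model"))
  features <- tibble::as_tibble(features)
  n <- nrow(features)
  if (model$model_type == "prior") {
    post <- matrix(model$priors, n, 2, byrow = TRUE)
  } else {
    X <- feature_matrix(features, model$feature_names)
    if (ncol(X) != length(model$feature_names)) {
      stop("feature dimension mismatch", call. = FALSE)
    }
    lp <- vapply(model$classes, function(k) {
      log(model$priors[[k]]) + log_density_class(model, X, k)
    }, numeric(n))
    lp <- matrix(lp, nrow = n)
    mx <- apply(lp, 1, max)
    w <- exp(lp - mx)
    post <- w / rowSums(w)
  }
  features$posterior_normal <- post[, 1]
  features$posterior_tumor <- post[, 2]
  features
}

#' Classify images with the 0.5 posterior rule
#'
#' An image is assigned to class "tumor" if and only if its tumor
#' posterior probability exceeds 0.5; a posterior of exactly 0.5 is
#' assigned to "normal" (conservative tie rule). Input order is preserved.
#'
#' @inheritParams posterior
#' @return Tibble of classification results, one row per image: the
#'   provenance columns present in `features`, `posterior_tumor`,
#'   `predicted`, and `truth` (copied from `tissue_label` when present).
#' @export
classify_images <- function(model, features) {
  scored <- posterior(model, features)
  keep <- intersect(PROVENANCE_COLS, names(scored))
  out <- scored[, keep, drop = FALSE]
  out$posterior_tumor <- scored$posterior_tumor
  out$predicted <- ifelse(scored$posterior_tumor > 0.5, "tumor", "normal")
  if ("tissue_label" %in% names(scored)) {
    out$truth <- as.character(scored$tissue_label)
  }
  tibble::as_tibble(out)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.discriminant_model <- function(x, ...) {
  if (x$model_type == "prior") {
    return(tibble::tibble(class = x$classes, prior = unname(x$priors)))
  }
  purrr::map_dfr(x$classes, function(k) {
    tibble::tibble(class = k, term = x$feature_names,
                   mean = unname(x$means[k, ]), prior = x$priors[[k]])
  })
}

#' @exportS3Method generics::glance
glance.discriminant_model <- function(x, ...) {
  tibble::tibble(
    model_type = x$model_type,
    n_features = length(x$feature_names),
    n_normal = x$n_per_class[["normal"]],
    n_tumor = x$n_per_class[["tumor"]],
    prior_tumor = x$priors[["tumor"]],
    ridge_max = if (is.null(x$ridge)) 0 else max(x$ridge)
  )
}
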