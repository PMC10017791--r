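normalize_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  defaults <- list(
    mode = "simulate",
    seed = 1L,
    out_dir = "mpmtex_run",
    synthetic = list(),
    input_dirs = NULL,
    qc = list(),
    features = list(spec = "selected", distances = c(1L, 12L, 30L),
                    levels = 8L, symmetric = FALSE),
    model_type = "linear",
    priors = "empirical",
    select_candidates = TRUE,
    map_tile_px = 8L
  )
  cfg <- utils::modifyList(defaults, config)
  cfg$features <- utils::modifyList(defaults$features,
                                    as.list(cfg$features))
  if (!cfg$mode %in% c("simulate", "ingest")) {
    stop("config mode must be 'simulate' or 'ingest'", call. = FALSE)
  }
  if (!cfg$features$spec %in% c("full", "selected", "cars_only")) {
    stop("config features$spec must be full, selected or cars_only",
         call. = FALSE)
  }
  if (!cfg$model_type %in% c("linear", "quadratic")) {
    stop("config model_type must be linear or quadratic", call. = FALSE)
  }
  if (cfg$mode == "ingest" && is.null(cfg$input_dirs)) {
    stop("config mode 'ingest' requires input_dirs", call. = FALSE)
  }
  cfg
}

spec_by_name <- function(name, f) {
  builder <- switch(name, full = feature_spec_full,
                    selected = feature_spec_selected,
                    cars_only = feature_spec_cars_only)
  builder(distances = f$distances, levels = f$levels,
          symmetric = f$symmetric)
}

#' Run the classification pipeline from a configuration
#'
#' Executes, in order, the requested stages of
#' simulate/ingest -> qc -> features -> crossval -> evaluate -> map and
#' writes every artifact under `out_dir`, together with a
#' `manifest.json` recording the fully normalized configuration (defaults
#' filled in), its hash, and the seed, so a rerun with the same config
#' and seed reproduces the feature table byte for byte.
#'
#' Configuration keys (all optional except `mode`-specific ones):
#' `mode` (`"simulate"` draws a synthetic cohort from `synthetic`;
#' `"ingest"` reads FoV stacks from `input_dirs`), `seed`, `out_dir`,
#' `qc` (threshold overrides), `features` (`spec` name, `distances`,
#' `levels`, `symmetric`), `model_type`, `priors`, `select_candidates`
#' (run the candidate-subset selection table during crossval),
#' `map_tile_px`.
#'
#' @param config A list, or a path to a JSON/YAML config file.
#' @param stages Character vector of stages, or `"all"`. Stages:
#'   `"simulate"`/`"ingest"`, `"qc"`, `"features"`, `"crossval"`,
#'   `"evaluate"`, `"map"`. Earlier stages a later one depends on are run
#'   implicitly.
#' @return Invisible list with the normalized config, artifact paths, and
#'   in-memory results (`features`, `selection`, `cv`, `maps`).
#' @export
run_pipeline <- function(config, stages = "all") {
  cfg <- normalize_pipeline_config(config)
  all_stages <- c("simulate", "ingest", "qc", "features", "crossval",
                  "evaluate", "map")
  if (identical(stages, "all")) {
    stages <- setdiff(all_stages,
                      if (cfg$mode == "simulate") "ingest" else "simulate")
  }
  bad <- setdiff(stages, c(all_stages, "train", "classify"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)

  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()

  # source cohort
  cohort <- if (cfg$mode == "simulate") {
    syn <- do.call(synthetic_config,
                   utils::modifyList(as.list(cfg$synthetic),
                                     list(seed = as.integer(cfg$seed))))
    cfg$synthetic <- unclass(syn)
    write_synthetic_config(syn, file.path(out, "synthetic_config.json"))
    artifacts$synthetic_config <- file.path(out, "synthetic_config.json")
    generate_cohort(syn)
  } else {
    lapply(cfg$input_dirs, read_fov_stack)
  }

  # qc
  thresholds <- do.call(qc_thresholds, as.list(cfg$qc))
  filtered <- lapply(cohort, filter_sample, thresholds = thresholds)
  kept <- lapply(filtered, `[[`, "kept")
  discards <- purrr::map_dfr(seq_along(filtered), function(i) {
    d <- filtered[[i]]$discards
    if (nrow(d)) d$sample_id <- cohort[[i]]$sample_id
    d
  })
  utils::write.csv(discards, file.path(out, "discards.csv"),
                   row.names = FALSE)
  artifacts$discards <- file.path(out, "discards.csv")

  result <- list(config = cfg, artifacts = artifacts)
  if (!any(c("features", "crossval", "evaluate", "map") %in% stages)) {
    result$artifacts <- artifacts
    write_manifest(cfg, artifacts, out)
    return(invisible(result))
  }

  # features (extract the full set so candidate selection can subset)
  full_spec <- spec_by_name("full", cfg$features)
  features <- extract_features(kept, spec = full_spec)
  write_feature_table(features, file.path(out, "features.csv"))
  artifacts$features <- file.path(out, "features.csv")
  result$features <- features

  if (any(c("crossval", "evaluate", "map") %in% stages)) {
    spec <- spec_by_name(cfg$features$spec, cfg$features)
    if (isTRUE(cfg$select_candidates)) {
      sel <- select_model(features,
                          candidates = default_candidate_specs(
                            cfg$features$distances, cfg$features$levels,
                            cfg$features$symmetric),
                          model_types = c("linear", "quadratic"),
                          priors = cfg$priors)
      utils::write.csv(sel$table, file.path(out, "selection.csv"),
                       row.names = FALSE)
      artifacts$selection <- file.path(out, "selection.csv")
      result$selection <- sel
    }
    cv <- loso_cv(features, spec = spec, model_type = cfg$model_type,
                  priors = cfg$priors)
    result$cv <- cv
    utils::write.csv(cv$predictions, file.path(out, "predictions.csv"),
                     row.names = FALSE)
    artifacts$predictions <- file.path(out, "predictions.csv")

    model <- fit_discriminant(features, spec = spec,
                              model_type = cfg$model_type,
                              priors = cfg$priors)
    write_model(model, file.path(out, "model.json"))
    artifacts$model <- file.path(out, "model.json")

    rep <- cv$report
    jsonlite::write_json(
      list(glance = as.list(glance(rep))),
      file.path(out, "report.json"), auto_unbox = TRUE, digits = NA)
    utils::write.csv(tidy(rep), file.path(out, "per_sample.csv"),
                     row.names = FALSE)
    artifacts$report <- file.path(out, "report.json")
    artifacts$per_sample <- file.path(out, "per_sample.csv")

    if ("map" %in% stages) {
      map_dir <- file.path(out, "maps")
      dir.create(map_dir, showWarnings = FALSE)
      maps <- list()
      for (i in seq_along(cohort)) {
        sid <- cohort[[i]]$sample_id
        res <- cv$predictions[cv$predictions$sample_id == sid, ,
                              drop = FALSE]
        dis <- filtered[[i]]$discards
        m <- assemble_map(res, dis, cohort[[i]]$grid_shape)
        write_map(m, png_path = file.path(map_dir, paste0(sid, ".png")),
                  csv_path = file.path(map_dir, paste0(sid, ".csv")),
                  tile_px = cfg$map_tile_px)
        maps[[sid]] <- m
      }
      artifacts$maps <- map_dir
      result$maps <- maps
    }
  }
  result$artifacts <- artifacts
  write_manifest(cfg, artifacts, out)
  invisible(result)
}

write_manifest <- function(cfg, artifacts, out) {
  manifest <- list(config = cfg,
                   config_hash = rlang::hash(cfg),
                   seed = cfg$seed,
                   package_version = as.character(
                     utils::packageVersion("mpmtex")),
                   artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
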