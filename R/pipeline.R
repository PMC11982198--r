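#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master seed and a stage index to a stage
#' seed, so that every stochastic stage of a pipeline run is seeded from
#' one master seed but stages draw from unrelated streams. The result is
#' always in `[0, 2^31 - 2]`.
#'
#' @param master Integer master seed.
#' @param stage Integer stage index (1 = SMOTE, 2 = simulation, ...).
#' @return Integer stage seed.
#' @export
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 31 + as.numeric(stage) * 104729) %%
               2147483647)
}

.default_config <- function() {
  list(input = NULL,                 # path to a WDBC-style file; NULL = synthetic preset
       dialect = "auto",
       threshold = 0.9,
       smote_k = 5L,
       nu = 0.01,
       gamma = "one_over_p",
       anchor_feature = "radius_mean",
       offset_sd = 0.4,
       noise_fracs = c(0.05, 0.10, 0.30),
       n_per_side = 5000L,
       window = 100L,
       alert_alpha = 0.01,
       seed = 1L,
       out_model = NULL, out_matrix = NULL, out_simulated = NULL,
       out_report = NULL, out_log = NULL)
}

#' Run the complete drift-detection pipeline
#'
#' Chains the stages end to end: load (or synthesise) the labelled
#' cohort, prepare it (prune, SMOTE, scale), fit the one-class frontier,
#' simulate drifted cohorts, and tabulate inlier rates. Every stochastic
#' stage is seeded from the single master seed via [derive_seed()], so a
#' run is fully reproducible from its configuration alone.
#'
#' @param config Named list of settings (missing entries take defaults),
#'   or a path to a YAML/JSON file holding one. Keys: `input` (path to a
#'   WDBC-style file, the string `"wdbc"` for the bundled public WDBC
#'   data, or `NULL` to use the synthetic WDBC-shaped preset), `dialect`, `threshold`, `smote_k`, `nu`, `gamma`, `anchor_feature`,
#'   `offset_sd`, `noise_fracs`, `n_per_side`, `window`, `alert_alpha`,
#'   `seed`, and optional output paths `out_model`, `out_matrix`,
#'   `out_simulated`, `out_report`, `out_log`.
#' @return A list with `cohort`, `prepared` (matrix), `preprocess`,
#'   `frontier`, `cohorts`, `report` and `log` (the resolved
#'   configuration plus stage summaries).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the 'yaml' package")
      yaml::read_yaml(config)
    }
  }
  cfg <- utils::modifyList(.default_config(), config, keep.null = TRUE)

  cohort <- if (is.null(cfg$input)) {
    generate_wdbc_shaped(seed = derive_seed(cfg$seed, 3L))
  } else if (identical(cfg$input, "wdbc")) {
    wdbc_cohort()
  } else {
    load_wdbc(cfg$input, dialect = cfg$dialect)
  }

  prep <- prepare(cohort, threshold = cfg$threshold,
                  k_neighbors = cfg$smote_k,
                  seed = derive_seed(cfg$seed, 1L))
  frontier <- fit_frontier(prep$matrix, nu = cfg$nu, gamma = cfg$gamma)
  spec <- drift_spec(anchor_feature = cfg$anchor_feature,
                     offset_sd = cfg$offset_sd,
                     noise_fracs = cfg$noise_fracs,
                     n_per_side = cfg$n_per_side,
                     seed = derive_seed(cfg$seed, 2L))
  cohorts <- simulate_drift(prep$matrix, spec)
  report <- evaluate_cohorts(frontier, cohorts)

  log <- list(config = cfg[setdiff(names(cfg), "input")],
              input = if (is.null(cfg$input)) "synthetic_preset" else cfg$input,
              stage_seeds = list(smote = derive_seed(cfg$seed, 1L),
                                 simulate = derive_seed(cfg$seed, 2L),
                                 synthetic = derive_seed(cfg$seed, 3L)),
              n_records = nrow(cohort$features),
              removed_features = prep$prune$removed,
              n_prepared = nrow(prep$matrix),
              p_prepared = ncol(prep$matrix),
              n_support_vectors = nrow(frontier$support_vectors),
              report = as.data.frame(report))

  if (!is.null(cfg$out_model)) write_model(prep$model, frontier, cfg$out_model)
  if (!is.null(cfg$out_matrix))
    utils::write.csv(as.data.frame(prep$matrix, check.names = FALSE),
                     cfg$out_matrix, row.names = FALSE, quote = FALSE)
  if (!is.null(cfg$out_simulated)) write_drift_csv(cohorts, cfg$out_simulated)
  if (!is.null(cfg$out_report)) write_report_json(report, cfg$out_report)
  if (!is.null(cfg$out_log))
    jsonlite::write_json(log, cfg$out_log, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)

  list(cohort = cohort, prepared = prep$matrix, preprocess = prep$model,
       frontier = frontier, cohorts = cohorts, report = report, log = log)
}
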