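# End-to-end orchestration: simulate/read -> filter -> log10 -> features ->
# select -> search -> evaluate -> leadtime, with every artefact written to a
# run directory and checksummed in a MANIFEST. Reruns with the same config
# are byte-identical.

#' Configure a pipeline run
#'
#' @param out_dir run directory (created if needed).
#' @param sim a [sim_config()] to simulate the cohort, or `NULL` to read it.
#' @param cohort_path long-format cohort CSV (used when `sim` is `NULL`).
#' @param selection a [selection_config()].
#' @param targets fixed specificities (default 0.903, 0.954).
#' @param strata case strata to evaluate (default `"all"` and `"TypeII"`).
#' @param windows evaluation windows (default both).
#' @param spec_unit specificity unit, `"visit"` or `"subject"`.
#' @param reference_feature the single-feature cut-off reference model
#'   (default `"CA125{5}"`, the final CA125 measurement).
#' @param top_models how many ranked models to carry into evaluation.
#' @param boot_B bootstrap replicates for sensitivity CIs (default 2000).
#' @param seed master seed; per-stage seeds are derived as seed + 1, + 2, ...
#'   (selection, evaluation CIs), so stages can be reproduced in isolation.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, sim = NULL, cohort_path = NULL,
                       selection = selection_config(),
                       targets = c(0.903, 0.954),
                       strata = c("all", "TypeII"),
                       windows = c("within_1yr", "yr1_to_2"),
                       spec_unit = "visit",
                       reference_feature = "CA125{5}",
                       top_models = 5, boot_B = 2000, seed = 1L) {
  if (is.null(sim) && is.null(cohort_path)) {
    stop("provide either a sim config or a cohort_path")
  }
  stopifnot(all(targets > 0 & targets < 1))
  structure(list(out_dir = out_dir, sim = sim, cohort_path = cohort_path,
                 selection = selection, targets = targets, strata = strata,
                 windows = windows, spec_unit = spec_unit,
                 reference_feature = reference_feature,
                 top_models = top_models, boot_B = boot_B,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the full longitudinal multimarker pipeline
#'
#' Executes every stage in order and writes: the cohort (`cohort.csv`, with
#' `ground_truth.json` when simulated), terminal and rolling feature
#' matrices, the selection report and consensus pool, the ranked model
#' table, a performance table across all configured strata and windows
#' (each model and the reference, with AUC, fixed-specificity sensitivities
#' and CIs, McNemar and calibration p-values), lead-time crossings, and a
#' `MANIFEST.json` listing every artefact with its MD5 checksum. Model
#' selection and search run on the within-1-year, all-cases stratum; the
#' winning models are refitted there and then scored on each evaluation
#' subset.
#'
#' @param cfg a [run_config()].
#' @return The manifest (named list of file checksums), invisibly; all
#'   artefacts are on disk under `cfg$out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  files <- character(0)

  # -- stage 1: obtain cohort -------------------------------------------------
  if (!is.null(cfg$sim)) {
    sim_cfg <- cfg$sim
    sim_cfg$seed <- cfg$seed
    gen <- generate_cohort(sim_cfg)
    cohort <- gen$cohort
    truth <- gen$truth
    write_json_file(list(
      subjects = truth$subjects,
      markers = truth$markers,
      baselines = as.data.frame(truth$baselines)
    ), out("ground_truth.json"))
    files <- c(files, "ground_truth.json")
  } else {
    cohort <- read_cohort(cfg$cohort_path)
  }
  write_cohort(cohort, out("cohort.csv"))
  files <- c(files, "cohort.csv")

  # -- stage 2: filtering and transform --------------------------------------
  filtered <- suppressMessages(modelling_filter(cohort))
  logged <- log10_transform(filtered)
  modelling <- suppressMessages(evaluation_subset(logged, "within_1yr"))

  # -- stage 3: features ------------------------------------------------------
  fm_terminal <- build_feature_matrix(modelling, mode = "terminal")
  fm_rolling <- build_feature_matrix(modelling, mode = "rolling")
  write_feature_matrix(fm_terminal, out("features_terminal.csv"))
  write_feature_matrix(fm_rolling, out("features_rolling.csv"))
  files <- c(files, "features_terminal.csv", "features_rolling.csv")

  # -- stage 4: variable selection -------------------------------------------
  sel_cfg <- cfg$selection
  sel_cfg$seed <- cfg$seed + 1L
  report <- suppressMessages(select_features(fm_terminal, sel_cfg))
  pool <- consensus_pool(report, sel_cfg)
  write.csv(as.data.frame(report), out("selection_report.csv"),
            row.names = FALSE)
  files <- c(files, "selection_report.csv")

  # -- stage 5: model search --------------------------------------------------
  search <- search_models(fm_terminal, pool, targets = cfg$targets,
                          target = cfg$targets[1])
  write.csv(search$table, out("ranked_models.csv"), row.names = FALSE)
  files <- c(files, "ranked_models.csv")

  ref_spec <- model_spec(cfg$reference_feature)
  if (!cfg$reference_feature %in% feature_names(fm_terminal)) {
    stop("reference feature not in the feature matrix: ", cfg$reference_feature)
  }
  top_names <- head(search$table$name, cfg$top_models)
  # always carry the best multimarker model into evaluation, even when
  # single-feature models monopolise the top ranks
  top_multi <- search$table$name[search$table$n_features >= 2][1]
  if (!is.na(top_multi) && !top_multi %in% top_names) {
    top_names <- c(top_names, top_multi)
  }
  specs_by_name <- c(
    setNames(lapply(top_names, function(nm) {
      feats <- attr(search$results[[nm]], "spec")$features
      model_spec(feats)
    }), top_names),
    setNames(list(ref_spec), ref_spec$name)
  )
  fits <- lapply(specs_by_name, fit_logistic, fm = fm_terminal)

  # -- stage 6: evaluation ----------------------------------------------------
  perf_rows <- list()
  for (stratum in cfg$strata) {
    for (window in cfg$windows) {
      eval_cohort <- suppressMessages(
        case_stratum(evaluation_subset(logged, window), stratum))
      fme_t <- build_feature_matrix(eval_cohort, mode = "terminal")
      fme_r <- build_feature_matrix(eval_cohort, mode = "rolling")
      for (nm in names(fits)) {
        ps <- evaluate_model(fits[[nm]], fits[[ref_spec$name]], fme_t, fme_r,
                             targets = cfg$targets, spec_unit = cfg$spec_unit,
                             boot_B = cfg$boot_B, seed = cfg$seed + 2L)
        row <- data.frame(stratum = stratum, window = window, model = nm,
                          n_cases = ps$n_cases, n_controls = ps$n_controls,
                          auc = ps$auc, auc_lo = ps$auc_ci[1],
                          auc_hi = ps$auc_ci[2], stringsAsFactors = FALSE)
        for (j in seq_along(cfg$targets)) {
          tg <- format(cfg$targets[j])
          row[[paste0("sens_", tg)]] <- ps$sensitivities[j]
          row[[paste0("sens_", tg, "_lo")]] <- ps$sens_ci[j, 1]
          row[[paste0("sens_", tg, "_hi")]] <- ps$sens_ci[j, 2]
        }
        row$mcnemar_p <- ps$mcnemar_p
        row$hl_p <- ps$hl_p
        perf_rows[[length(perf_rows) + 1L]] <- row
      }
    }
  }
  perf <- do.call(rbind, perf_rows)
  write.csv(perf, out("performance.csv"), row.names = FALSE)
  files <- c(files, "performance.csv")

  # -- stage 7: lead time -----------------------------------------------------
  lead <- tryCatch({
    top_fit <- if (!is.na(top_multi)) fits[[top_multi]] else fits[[top_names[1]]]
    ref_fit <- fits[[ref_spec$name]]
    ctrl_r <- complete_units(fm_rolling[fm_rolling$label == 0, , drop = FALSE],
                             union(top_fit$spec$features, ref_fit$spec$features),
                             quiet = TRUE)
    thr_model <- threshold_at_specificity(predict(top_fit, ctrl_r),
                                          cfg$targets[1])
    thr_ref <- threshold_at_specificity(predict(ref_fit, ctrl_r),
                                        cfg$targets[1])
    pts_model <- score_trajectory_points(top_fit, fm_rolling, modelling)
    pts_ref <- score_trajectory_points(ref_fit, fm_rolling, modelling)
    curve_model <- fit_trajectory(pts_model$time_years, pts_model$score)
    curve_ref <- fit_trajectory(pts_ref$time_years, pts_ref$score)
    gain <- lead_time_gain(curve_model, curve_ref, thr_model, thr_ref)
    list(model = top_fit$spec$name, reference = ref_fit$spec$name,
         model_threshold = thr_model, ref_threshold = thr_ref,
         model_crossing_years = gain$model_crossing,
         ref_crossing_years = gain$ref_crossing,
         gain_months = gain$gain_months)
  }, error = function(e) list(error = conditionMessage(e)))
  write_json_file(lead, out("leadtime.json"))
  files <- c(files, "leadtime.json")

  # -- stage 8: summary and manifest -----------------------------------------
  write_json_file(list(
    seed = cfg$seed, targets = cfg$targets, spec_unit = cfg$spec_unit,
    reference = ref_spec$name, pool = pool,
    lasso_lambda = attr(report, "lasso_lambda"),
    top_models = top_names,
    selection = cfg$selection[setdiff(names(cfg$selection), "seed")]
  ), out("summary.json"))
  files <- c(files, "summary.json")

  sums <- tools::md5sum(file.path(cfg$out_dir, sort(files)))
  manifest <- setNames(as.list(unname(sums)), sort(files))
  write_json_file(manifest, out("MANIFEST.json"))
  invisible(manifest)
}
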