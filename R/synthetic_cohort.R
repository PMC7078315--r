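# Synthetic nested case-control screening cohorts with change-point marker
# kinetics, plus the noise-free latent trajectory oracle used for
# parameter-recovery testing.

#' Describe the generative kinetics of one serum marker
#'
#' Each marker's log10 concentration follows a subject-specific flat baseline
#' that, for cases, begins a linear rise a fixed number of months before
#' diagnosis (a change-point trajectory). Within-subject assay noise is
#' multiplicative on the raw scale: the log10 noise SD is `log10(1 + assay_cv)`,
#' which matches a constant assay coefficient of variation at small CV.
#'
#' @param name marker identifier (e.g. `"CA125"`).
#' @param baseline_log10_mean population mean of the subject baseline, log10
#'   concentration units.
#' @param baseline_between_subject_sd between-subject SD of the baseline,
#'   log10 units.
#' @param assay_cv within-subject assay coefficient of variation (fraction).
#' @param changepoint_tau months before diagnosis at which case trajectories
#'   begin to rise.
#' @param rise_slope_type1,rise_slope_type2,rise_slope_borderline post
#'   change-point slope, log10 units per year, by tumour type (0 for an
#'   uninformative marker).
#' @return An object of class `marker_kinetics`.
#' @export
marker_kinetics <- function(name, baseline_log10_mean,
                            baseline_between_subject_sd = 0.25,
                            assay_cv = 0.1, changepoint_tau = 24,
                            rise_slope_type1 = 0, rise_slope_type2 = 0,
                            rise_slope_borderline = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(assay_cv >= 0, changepoint_tau >= 0,
            baseline_between_subject_sd >= 0)
  structure(list(name = name,
                 baseline_log10_mean = baseline_log10_mean,
                 baseline_between_subject_sd = baseline_between_subject_sd,
                 assay_cv = assay_cv,
                 changepoint_tau = changepoint_tau,
                 rise_slope_type1 = rise_slope_type1,
                 rise_slope_type2 = rise_slope_type2,
                 rise_slope_borderline = rise_slope_borderline),
            class = "marker_kinetics")
}

#' Default ten-marker panel emulating the assayed candidate set
#'
#' Ten serum markers with assay CVs taken from the reported intra-assay
#' reproducibility of the commercial kits (4--22%). Markers that featured in
#' the top multimarker models (CA125, HE4, CHI3L1, PEBP4, AGR2) are given
#' change-point rises, strongest for Type II disease; the remaining five are
#' generated as uninformative (zero slope). Baselines are plausible
#' post-menopausal serum levels on the log10 scale of each assay's reporting
#' unit; their absolute placement is immaterial to the analysis, which works
#' on within-panel contrasts.
#'
#' @return A list of [marker_kinetics()] objects.
#' @export
default_marker_panel <- function() {
  list(
    marker_kinetics("CA125",      1.10, 0.25, 0.04, changepoint_tau = 24,
                    rise_slope_type1 = 0.30, rise_slope_type2 = 0.45,
                    rise_slope_borderline = 0.15),
    marker_kinetics("HE4",        1.65, 0.20, 0.08, changepoint_tau = 30,
                    rise_slope_type1 = 0.18, rise_slope_type2 = 0.30,
                    rise_slope_borderline = 0.08),
    marker_kinetics("CHI3L1",     4.55, 0.22, 0.14, changepoint_tau = 36,
                    rise_slope_type1 = 0.12, rise_slope_type2 = 0.22,
                    rise_slope_borderline = 0.06),
    marker_kinetics("PEBP4",      1.30, 0.25, 0.20, changepoint_tau = 30,
                    rise_slope_type1 = 0.12, rise_slope_type2 = 0.18,
                    rise_slope_borderline = 0.05),
    marker_kinetics("AGR2",       1.00, 0.22, 0.18, changepoint_tau = 30,
                    rise_slope_type1 = 0.10, rise_slope_type2 = 0.18,
                    rise_slope_borderline = 0.05),
    marker_kinetics("LRG1",       4.30, 0.15, 0.16),
    marker_kinetics("FSTL1",      4.00, 0.15, 0.11),
    marker_kinetics("SLPI",       4.50, 0.15, 0.12),
    marker_kinetics("glycodelin", 1.50, 0.30, 0.22),
    marker_kinetics("DNAH17",     2.00, 0.20, 0.17)
  )
}

#' Configure a synthetic screening cohort
#'
#' Defaults reproduce the study composition: 31 cancer-free controls and 49
#' cases (9 Type I, 30 Type II, 10 Borderline) of post-menopausal age, each
#' contributing 3--10 annual screening samples, assayed for the default
#' ten-marker panel. Case diagnosis falls 0--12 months after the final
#' sample, so every case's last annual sample lies within one year of
#' diagnosis.
#'
#' @param n_controls,n_type1,n_type2,n_borderline group sizes.
#' @param age_at_entry_mean,age_at_entry_sd entry age distribution (years).
#' @param visits_min,visits_max per-subject annual visit count range.
#' @param visit_jitter_sd SD (years) of the jitter around exact annual
#'   spacing; truncated at +/-0.4 yr so visit order stays strict.
#' @param markers list of [marker_kinetics()].
#' @param months_to_dx_of_last_sample_max months: diagnosis is drawn
#'   uniformly within this many months after the final sample.
#' @param seed integer RNG seed; fixes every generated byte.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_controls = 31, n_type1 = 9, n_type2 = 30,
                       n_borderline = 10,
                       age_at_entry_mean = 61, age_at_entry_sd = 4,
                       visits_min = 3, visits_max = 10,
                       visit_jitter_sd = 0.03,
                       markers = default_marker_panel(),
                       months_to_dx_of_last_sample_max = 12,
                       seed = 1L) {
  counts <- c(n_controls, n_type1, n_type2, n_borderline)
  if (any(counts < 0)) stop("group counts must be non-negative")
  if (visits_min < 1) stop("visits_min must be >= 1")
  if (visits_max < visits_min) stop("visits_max must be >= visits_min")
  if (visit_jitter_sd < 0) stop("visit_jitter_sd must be >= 0")
  stopifnot(length(markers) >= 1,
            all(vapply(markers, inherits, logical(1), "marker_kinetics")))
  marker_names <- vapply(markers, `[[`, character(1), "name")
  if (anyDuplicated(marker_names)) stop("duplicate marker names in panel")
  structure(list(n_controls = n_controls, n_type1 = n_type1,
                 n_type2 = n_type2, n_borderline = n_borderline,
                 age_at_entry_mean = age_at_entry_mean,
                 age_at_entry_sd = age_at_entry_sd,
                 visits_min = visits_min, visits_max = visits_max,
                 visit_jitter_sd = visit_jitter_sd,
                 markers = markers,
                 months_to_dx_of_last_sample_max = months_to_dx_of_last_sample_max,
                 seed = as.integer(seed)),
            class = "sim_config")
}

slope_for_type <- function(mk, tumour_type) {
  switch(tumour_type,
         TypeI = mk$rise_slope_type1,
         TypeII = mk$rise_slope_type2,
         Borderline = mk$rise_slope_borderline,
         none = 0)
}

#' Generate a synthetic screening cohort with ground truth
#'
#' Draws a nested case-control cohort under the change-point model: each
#' subject has annual visits at entry age + 0, 1, 2, ... years (with small
#' truncated jitter); each case's diagnosis age is the final visit age plus a
#' Uniform(0, `months_to_dx_of_last_sample_max`) months offset; and each
#' measured log10 concentration is
#' `baseline + slope * max(0, years past change-point) + Normal(0, log10(1 + assay_cv))`,
#' where the change-point sits `changepoint_tau` months before diagnosis.
#' Controls have no diagnosis timing and no rise term. Output is
#' deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list with elements `cohort` (a raw-scale [cohort_set()]) and
#'   `truth` (a `ground_truth` object holding the per-subject groups,
#'   diagnosis ages, subject-level baselines, per-marker informativeness
#'   flags, and the config itself).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_total <- config$n_controls + config$n_type1 + config$n_type2 +
    config$n_borderline
  if (n_total == 0) stop("empty cohort: all group sizes are zero")

  set.seed(config$seed)
  types <- c(rep("none", config$n_controls),
             rep("TypeI", config$n_type1),
             rep("TypeII", config$n_type2),
             rep("Borderline", config$n_borderline))
  groups <- ifelse(types == "none", "control", "case")
  ids <- sprintf("S%04d", seq_len(n_total))
  marker_names <- vapply(config$markers, `[[`, character(1), "name")

  rows <- vector("list", n_total)
  truth_subjects <- vector("list", n_total)
  baselines <- matrix(NA_real_, n_total, length(marker_names),
                      dimnames = list(ids, marker_names))

  for (i in seq_len(n_total)) {
    n_visits <- if (config$visits_min == config$visits_max) config$visits_min
    else sample(config$visits_min:config$visits_max, 1L)
    entry <- rnorm(1, config$age_at_entry_mean, config$age_at_entry_sd)
    jitter <- rnorm(n_visits, 0, config$visit_jitter_sd)
    jitter <- pmin(pmax(jitter, -0.4), 0.4)
    ages <- entry + (seq_len(n_visits) - 1) + jitter

    if (groups[i] == "case") {
      dx_age <- max(ages) +
        runif(1, 0, config$months_to_dx_of_last_sample_max) / 12
      months_to_dx <- (dx_age - ages) * 12
    } else {
      dx_age <- NA_real_
      months_to_dx <- rep(NA_real_, n_visits)
    }

    sub_base <- vapply(config$markers, function(mk) {
      rnorm(1, mk$baseline_log10_mean, mk$baseline_between_subject_sd)
    }, numeric(1))
    baselines[i, ] <- sub_base

    vals <- matrix(NA_real_, n_visits, length(marker_names))
    for (m in seq_along(config$markers)) {
      mk <- config$markers[[m]]
      slope <- slope_for_type(mk, types[i])
      yrs_past <- if (groups[i] == "case") {
        pmax(0, (mk$changepoint_tau - months_to_dx) / 12)
      } else rep(0, n_visits)
      noise_sd <- log10(1 + mk$assay_cv)
      noise <- if (noise_sd > 0) rnorm(n_visits, 0, noise_sd) else rep(0, n_visits)
      vals[, m] <- sub_base[m] + slope * yrs_past + noise
    }

    rows[[i]] <- data.frame(
      subject_id = ids[i], group = groups[i], tumour_type = types[i],
      age_years = rep(ages, times = length(marker_names)),
      months_to_dx = rep(months_to_dx, times = length(marker_names)),
      sample_kind = "annual_screen",
      marker = rep(marker_names, each = n_visits),
      value = 10^as.vector(vals),
      stringsAsFactors = FALSE
    )
    truth_subjects[[i]] <- data.frame(
      subject_id = ids[i], group = groups[i], tumour_type = types[i],
      entry_age = entry, dx_age = dx_age, n_visits = n_visits,
      stringsAsFactors = FALSE
    )
  }

  cohort <- cohort_set(do.call(rbind, rows), markers = marker_names,
                       log_scale = FALSE,
                       provenance = sprintf("simulated (seed %d)", config$seed))
  informative <- vapply(config$markers, function(mk) {
    mk$rise_slope_type1 != 0 || mk$rise_slope_type2 != 0 ||
      mk$rise_slope_borderline != 0
  }, logical(1))
  truth <- structure(
    list(subjects = do.call(rbind, truth_subjects),
         baselines = baselines,
         markers = data.frame(name = marker_names, informative = informative,
                              stringsAsFactors = FALSE),
         config = config),
    class = "ground_truth"
  )
  list(cohort = cohort, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", nrow(x$subjects), "subjects,",
      sum(x$markers$informative), "of", nrow(x$markers),
      "markers informative\n")
  invisible(x)
}

#' Noise-free latent trajectory values at each subject's final visit
#'
#' Evaluates the generative change-point trajectory (subject baseline plus
#' rise term, without assay noise) at every subject's final visit, per
#' marker. For controls this is the subject baseline; for cases it increases
#' monotonically in the rise slope and in time past the change-point, so it
#' serves as the true latent risk score in parameter-recovery tests.
#'
#' @param truth the `ground_truth` returned by [generate_cohort()] (embeds
#'   the generating config).
#' @param cohort the matching `cohort_set` from the same call.
#' @return data.frame: `subject_id`, `group`, then one column of latent
#'   log10 values per marker.
#' @export
oracle_scores <- function(truth, cohort) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cohort, "cohort_set"))
  config <- truth$config
  marker_names <- vapply(config$markers, `[[`, character(1), "name")
  if (!identical(sort(marker_names), sort(cohort$markers)) ||
      !setequal(truth$subjects$subject_id, unique(cohort$data$subject_id))) {
    stop("config/cohort mismatch: cohort was not produced by this ground truth")
  }
  subs <- truth$subjects
  out <- data.frame(subject_id = subs$subject_id, group = subs$group,
                    stringsAsFactors = FALSE)
  d <- cohort$data
  final_age <- vapply(subs$subject_id, function(sid) {
    max(d$age_years[d$subject_id == sid])
  }, numeric(1))
  for (m in seq_along(config$markers)) {
    mk <- config$markers[[m]]
    latent <- numeric(nrow(subs))
    for (i in seq_len(nrow(subs))) {
      base <- truth$baselines[subs$subject_id[i], mk$name]
      if (subs$group[i] == "case") {
        months_to_dx <- (subs$dx_age[i] - final_age[i]) * 12
        slope <- slope_for_type(mk, subs$tumour_type[i])
        latent[i] <- base + slope * max(0, (mk$changepoint_tau - months_to_dx) / 12)
      } else {
        latent[i] <- base
      }
    }
    out[[mk$name]] <- latent
  }
  out
}
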