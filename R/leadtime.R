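# Smoothed prediction-score trajectories against time to diagnosis and
# threshold-crossing lead-time comparison between models.

#' Loess-smoothed score trajectory
#'
#' Fits a locally weighted regression (tricube weights, configurable degree)
#' of pooled case scores against time before diagnosis and evaluates it,
#' with pointwise 95% bands from the smoother's standard errors, on a
#' regular grid over the observed time range.
#'
#' @param time numeric vector: years before diagnosis (cases).
#' @param score numeric vector of model scores, same length.
#' @param span loess span in (0, 1] (default 0.75).
#' @param degree local polynomial degree (default 2).
#' @param grid_n evaluation grid size (default 200).
#' @return A `trajectory_curve`: list with `grid` (increasing years before
#'   diagnosis), `fit`, `lower`, `upper`, `span`, `degree`.
#' @export
fit_trajectory <- function(time, score, span = 0.75, degree = 2,
                           grid_n = 200) {
  stopifnot(length(time) == length(score))
  if (length(time) < 10) stop("fit_trajectory needs at least 10 points")
  stopifnot(span > 0, span <= 1, degree %in% 0:2)
  lo <- tryCatch(
    loess(score ~ time, span = span, degree = degree, family = "gaussian",
          surface = "direct",
          control = loess.control(iterations = 1)),
    error = function(e) {
      stop("loess fit failed (", conditionMessage(e),
           "); try a larger span")
    })
  grid <- seq(min(time), max(time), length.out = grid_n)
  pr <- predict(lo, newdata = data.frame(time = grid), se = TRUE)
  if (any(!is.finite(pr$fit))) {
    stop("loess fit is undefined on part of the grid; try a larger span")
  }
  z <- qnorm(0.975)
  se <- ifelse(is.finite(pr$se.fit), pr$se.fit, 0)
  structure(list(grid = grid, fit = as.numeric(pr$fit),
                 lower = as.numeric(pr$fit - z * se),
                 upper = as.numeric(pr$fit + z * se),
                 span = span, degree = degree),
            class = "trajectory_curve")
}

#' @importFrom stats loess.control
#' @export
print.trajectory_curve <- function(x, ...) {
  cat(sprintf("trajectory_curve: %d grid points over [%.2f, %.2f] yr before diagnosis (span %.2f, degree %d)\n",
              length(x$grid), min(x$grid), max(x$grid), x$span, x$degree))
  invisible(x)
}

#' Threshold-crossing time of a smoothed trajectory
#'
#' Scans the curve from the earliest time toward diagnosis (time before
#' diagnosis decreasing to 0). Under the default `"sustained"` rule the
#' crossing is the first time after which the curve stays at or above the
#' threshold all the way to diagnosis — a single early blip above threshold
#' does not count; `"first_touch"` instead returns the earliest time at
#' which the curve reaches the threshold at all. The crossing is linearly
#' interpolated between grid points; if the curve is above the threshold on
#' the whole grid the earliest grid time is returned, and if positivity is
#' never sustained the crossing is absent (`NA`).
#'
#' @param curve a `trajectory_curve`.
#' @param threshold the positivity threshold.
#' @param rule `"sustained"` (default) or `"first_touch"`.
#' @return A `crossing_result`: list with `crossing_time` (years before
#'   diagnosis, or `NA`), `threshold`, `rule`.
#' @export
crossing_time <- function(curve, threshold,
                          rule = c("sustained", "first_touch")) {
  stopifnot(inherits(curve, "trajectory_curve"))
  rule <- match.arg(rule)
  g <- curve$grid; f <- curve$fit
  above <- f >= threshold
  ct <- NA_real_
  if (rule == "sustained") {
    if (above[1]) {  # grid[1] is the time closest to diagnosis
      j <- which(!above)
      if (length(j) == 0) {
        ct <- g[length(g)]
      } else {
        j <- j[1]  # first grid point (moving away from diagnosis) below threshold
        ct <- g[j - 1] + (g[j] - g[j - 1]) *
          (f[j - 1] - threshold) / (f[j - 1] - f[j])
      }
    }
  } else {
    j <- which(above)
    if (length(j) > 0) {
      j <- j[length(j)]  # farthest-from-diagnosis grid point at/above threshold
      if (j == length(g)) {
        ct <- g[j]
      } else {
        ct <- g[j] + (g[j + 1] - g[j]) *
          (f[j] - threshold) / (f[j] - f[j + 1])
      }
    }
  }
  structure(list(crossing_time = ct, threshold = threshold, rule = rule),
            class = "crossing_result")
}

#' Lead-time gain of a model over a reference
#'
#' Computes both threshold crossings on the same time axis and returns how
#' many months earlier the model's smoothed score becomes (and stays)
#' positive: positive values mean the model crosses its threshold further
#' from diagnosis than the reference does. Absent if either curve never
#' crosses.
#'
#' @param model_curve,ref_curve `trajectory_curve` objects on the same axis.
#' @param model_threshold,ref_threshold the two positivity thresholds.
#' @param rule crossing rule, see [crossing_time()].
#' @return List: `gain_months` (`NA` when undefined), `model_crossing`,
#'   `ref_crossing` (years before diagnosis), `reason` (when undefined).
#' @export
lead_time_gain <- function(model_curve, ref_curve, model_threshold,
                           ref_threshold, rule = "sustained") {
  mc <- crossing_time(model_curve, model_threshold, rule)
  rc <- crossing_time(ref_curve, ref_threshold, rule)
  if (is.na(mc$crossing_time) || is.na(rc$crossing_time)) {
    reason <- if (is.na(rc$crossing_time)) "reference crossing undefined"
    else "model crossing undefined"
    return(list(gain_months = NA_real_,
                model_crossing = mc$crossing_time,
                ref_crossing = rc$crossing_time, reason = reason))
  }
  list(gain_months = (mc$crossing_time - rc$crossing_time) * 12,
       model_crossing = mc$crossing_time, ref_crossing = rc$crossing_time,
       reason = NULL)
}

#' Case score-versus-time points for the lead-time analysis
#'
#' Scores every case (subject, visit) unit of a rolling feature matrix with
#' a fitted model and pairs the score with the visit's time before
#' diagnosis, the raw material for [fit_trajectory()].
#'
#' @param fitted a `fitted_model`.
#' @param fm_rolling rolling-mode `feature_matrix` of the cases (visit ages
#'   in `age_years`).
#' @param cohort the matching `cohort_set` (supplies months to diagnosis).
#' @return data.frame: `subject_id`, `time_years` (years before diagnosis),
#'   `score`.
#' @export
score_trajectory_points <- function(fitted, fm_rolling, cohort) {
  stopifnot(inherits(fitted, "fitted_model"), inherits(cohort, "cohort_set"))
  fm <- complete_units(fm_rolling[fm_rolling$label == 1, , drop = FALSE],
                       fitted$spec$features, quiet = TRUE)
  if (nrow(fm) == 0) stop("no scoreable case units")
  d <- unique(cohort$data[, c("subject_id", "age_years", "months_to_dx")])
  key <- paste(d$subject_id, format(d$age_years, digits = 10))
  fk <- paste(fm$subject_id, format(fm$age_years, digits = 10))
  months <- d$months_to_dx[match(fk, key)]
  if (any(is.na(months))) stop("rolling units not found in cohort")
  data.frame(subject_id = fm$subject_id, time_years = months / 12,
             score = predict(fitted, fm), stringsAsFactors = FALSE)
}
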