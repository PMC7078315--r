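# The five per-marker trend indices that collapse a serial (age, log10 value)
# trajectory into a scalar, and feature-matrix assembly in terminal and
# rolling modes. Feature columns are named "MARKER{index}", e.g. "CA125{3}".

check_series <- function(t, y) {
  stopifnot(is.numeric(t), is.numeric(y), length(t) == length(y))
  if (length(t) >= 2 && any(diff(t) == 0)) {
    stop("tied time points in marker series")
  }
  if (length(t) >= 2 && any(diff(t) < 0)) {
    stop("marker series times must be increasing")
  }
  invisible(NULL)
}

#' Trend index 1: mean derivative
#'
#' The average gradient over consecutive measurement pairs,
#' `mean((y[j+1] - y[j]) / (t[j+1] - t[j]))`. A series following an exact
#' line of slope b returns b. With `variant = "telescoping"` each gradient is
#' weighted by its interval length, which telescopes to the overall chord
#' slope `(y[k] - y[1]) / (t[k] - t[1])`.
#'
#' @param t ages (years), strictly increasing.
#' @param y log10 concentrations.
#' @param variant `"mean"` (default, unweighted mean of gradients) or
#'   `"telescoping"` (interval-weighted, i.e. the chord slope).
#' @return The index value, or `NA_real_` when the series has fewer than two
#'   points (the index is then undefined, not zero).
#' @export
index1_mean_derivative <- function(t, y, variant = c("mean", "telescoping")) {
  variant <- match.arg(variant)
  check_series(t, y)
  k <- length(t)
  if (k < 2) return(NA_real_)
  if (variant == "telescoping") {
    (y[k] - y[1]) / (t[k] - t[1])
  } else {
    mean(diff(y) / diff(t))
  }
}

#' Trend index 2: area under the series
#'
#' The average per-interval trapezoidal area,
#' `mean((t[j+1] - t[j]) * (y[j] + y[j+1]) / 2)`: the area under the time
#' series divided by the number of intervals. A constant series `y = c`
#' with mean interval length L returns `c * L`. The alternative reading
#' `variant = "sum_to_end"` computes `sum((t[k] - t[j]) * y[j]) / k`.
#'
#' @inheritParams index1_mean_derivative
#' @param variant `"trapezoid"` (default) or `"sum_to_end"`.
#' @return Index value, or `NA_real_` when fewer than two points.
#' @export
index2_area <- function(t, y, variant = c("trapezoid", "sum_to_end")) {
  variant <- match.arg(variant)
  check_series(t, y)
  k <- length(t)
  if (k < 2) return(NA_real_)
  if (variant == "sum_to_end") {
    sum((t[k] - t) * y) / k
  } else {
    mean(diff(t) * (y[-k] + y[-1]) / 2)
  }
}

#' Trend index 3: coefficient of variation
#'
#' `sd(y) / mean(y)` with the sample (k-1 denominator) standard deviation;
#' time stamps are ignored. Scale-invariant: multiplying the series by any
#' positive constant leaves it unchanged. On log10 values a near-zero mean
#' makes the ratio unstable, so a warning is emitted when `|mean(y)| < 0.1`.
#'
#' @inheritParams index1_mean_derivative
#' @return Index value, or `NA_real_` when fewer than two points.
#' @export
index3_cv <- function(t, y) {
  check_series(t, y)
  if (length(y) < 2) return(NA_real_)
  m <- mean(y)
  if (m == 0) stop("coefficient of variation undefined: mean is zero")
  if (abs(m) < 0.1) {
    warning("index3_cv: |mean| < 0.1; coefficient of variation is unstable")
  }
  sd(y) / m
}

#' Trend index 4: centre of mass
#'
#' `sum(t * y) / sum(t)` — the age-weighted mean concentration, intended to
#' damp any age dependence of marker level. With all ages positive it is a
#' convex combination of the y values, hence lies within `[min(y), max(y)]`;
#' a constant series returns that constant. Defined for a single point.
#'
#' @inheritParams index1_mean_derivative
#' @return Index value.
#' @export
index4_center_of_mass <- function(t, y) {
  check_series(t, y)
  if (length(t) < 1) stop("empty marker series")
  if (any(t <= 0)) stop("index4 requires strictly positive ages")
  sum(t * y) / sum(t)
}

#' Trend index 5: final measurement
#'
#' The last value of the series — the conventional single-measurement
#' cut-off feature (e.g. `CA125{5}` is the final CA125 level).
#'
#' @inheritParams index1_mean_derivative
#' @return `y[k]`.
#' @export
index5_last <- function(t, y) {
  check_series(t, y)
  if (length(y) < 1) stop("empty marker series")
  y[length(y)]
}

trend_index <- function(i, t, y, index1_variant = "mean",
                        index2_variant = "trapezoid") {
  switch(as.character(i),
         "1" = index1_mean_derivative(t, y, index1_variant),
         "2" = index2_area(t, y, index2_variant),
         "3" = index3_cv(t, y),
         "4" = index4_center_of_mass(t, y),
         "5" = index5_last(t, y),
         stop("unknown trend index: ", i))
}

#' Assemble a trend-index feature matrix from a cohort
#'
#' For each analysis unit, every (marker, index) pair becomes one feature
#' column named `"MARKER{i}"`. In `terminal` mode there is one unit per
#' subject, computed from the subject's full retained series. In `rolling`
#' mode there is one unit per (subject, visit), computed from the visits at
#' or before that visit — the information available at screening time.
#' Indices 1--3 need at least two measurements and are `NA` for one-visit
#' units; visits missing a marker value simply shorten that marker's series.
#'
#' @param cohort a log-scale `cohort_set` that has been through
#'   [modelling_filter()].
#' @param indices subset of 1:5 (default all five).
#' @param mode `"terminal"` or `"rolling"`.
#' @param index1_variant,index2_variant passed to the index functions.
#' @return A `feature_matrix`: data.frame with columns `unit_id`,
#'   `subject_id`, `age_years` (the unit's final visit age), `label`
#'   (1 = case, 0 = control), followed by the feature columns.
#' @export
build_feature_matrix <- function(cohort, indices = 1:5,
                                 mode = c("terminal", "rolling"),
                                 index1_variant = "mean",
                                 index2_variant = "trapezoid") {
  stopifnot(inherits(cohort, "cohort_set"))
  mode <- match.arg(mode)
  if (!cohort$log_scale) {
    stop("build_feature_matrix expects a log10-scale cohort; apply log10_transform() first")
  }
  indices <- as.integer(indices)
  if (length(indices) == 0 || any(!indices %in% 1:5)) {
    stop("indices must be a non-empty subset of 1:5")
  }
  d <- cohort$data
  markers <- cohort$markers
  feature_names <- as.vector(t(outer(markers, indices,
                                     function(m, i) paste0(m, "{", i, "}"))))

  sids <- unique(d$subject_id)
  rows <- list()
  for (sid in sids) {
    sd_rows <- d[d$subject_id == sid, ]
    ages <- sort(unique(sd_rows$age_years))
    cut_ages <- if (mode == "terminal") max(ages) else ages
    label <- as.integer(sd_rows$group[1] == "case")
    for (cut_age in cut_ages) {
      feats <- setNames(rep(NA_real_, length(feature_names)), feature_names)
      for (m in markers) {
        mrows <- sd_rows[sd_rows$marker == m & sd_rows$age_years <= cut_age, ]
        mrows <- mrows[order(mrows$age_years), ]
        mrows <- mrows[!is.na(mrows$value), ]
        if (nrow(mrows) == 0) next
        for (i in indices) {
          v <- tryCatch(
            trend_index(i, mrows$age_years, mrows$value,
                        index1_variant, index2_variant),
            warning = function(w) {
              suppressWarnings(trend_index(i, mrows$age_years, mrows$value,
                                           index1_variant, index2_variant))
            })
          feats[paste0(m, "{", i, "}")] <- v
        }
      }
      unit_id <- if (mode == "terminal") sid
      else paste0(sid, "@", format(cut_age, digits = 10))
      rows[[length(rows) + 1L]] <- c(
        list(unit_id = unit_id, subject_id = sid, age_years = cut_age,
             label = label),
        as.list(feats))
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- as.data.frame(c(list(unit_id = character(0),
                                subject_id = character(0),
                                age_years = numeric(0), label = integer(0)),
                           setNames(rep(list(numeric(0)), length(feature_names)),
                                    feature_names)),
                         check.names = FALSE)
  }
  rownames(out) <- NULL
  structure(out, class = c("feature_matrix", "data.frame"),
            mode = mode, markers = markers, indices = indices)
}

#' Feature column names of a feature matrix
#'
#' @param fm a `feature_matrix`.
#' @return Character vector of the `"MARKER{i}"` columns.
#' @export
feature_names <- function(fm) {
  setdiff(names(fm), c("unit_id", "subject_id", "age_years", "label"))
}

#' Drop units with any missing value among the given features
#'
#' @param fm a `feature_matrix`.
#' @param features columns to require (default all features).
#' @param quiet suppress the dropped-unit message.
#' @return The complete-case `feature_matrix`.
#' @export
complete_units <- function(fm, features = feature_names(fm), quiet = FALSE) {
  keep <- stats::complete.cases(fm[, features, drop = FALSE])
  if (!quiet && any(!keep)) {
    message("dropping ", sum(!keep), " unit(s) with undefined features")
  }
  out <- fm[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("mode", "markers", "indices")) attr(out, a) <- attr(fm, a)
  out
}

#' Write a feature matrix as wide CSV
#'
#' Columns: unit id, subject id, age, label, then features; absent cells
#' are written empty.
#'
#' @param fm a `feature_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  write.csv(as.data.frame(fm, check.names = FALSE), path,
            row.names = FALSE, na = "")
  invisible(path)
}
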