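# Programmatic fixtures: tiny hand-built cohorts and feature matrices.

# long-format rows for one subject with given visit ages and one marker
subject_rows <- function(id, group, type, ages, values, marker = "CA125",
                         dx_age = NA, kind = "annual_screen") {
  months <- if (group == "case") (dx_age - ages) * 12 else NA_real_
  data.frame(subject_id = id, group = group, tumour_type = type,
             age_years = ages, months_to_dx = months,
             sample_kind = kind, marker = marker, value = values,
             stringsAsFactors = FALSE)
}

# a minimal valid two-subject, one-marker cohort
tiny_cohort <- function() {
  d <- rbind(
    subject_rows("C1", "control", "none", c(60, 61, 62), c(10, 12, 11)),
    subject_rows("K1", "case", "TypeII", c(58, 59, 60), c(10, 20, 40),
                 dx_age = 60.5)
  )
  cohort_set(d, markers = "CA125")
}

# feature matrix straight from numeric columns (bypasses cohort machinery)
fm_from_matrix <- function(X, label, unit_ids = NULL) {
  n <- nrow(X)
  if (is.null(unit_ids)) unit_ids <- sprintf("U%04d", seq_len(n))
  out <- data.frame(unit_id = unit_ids, subject_id = unit_ids,
                    age_years = seq_len(n), label = as.integer(label),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(ncol(X))) out[[colnames(X)[j]]] <- X[, j]
  structure(out, class = c("feature_matrix", "data.frame"),
            mode = "terminal", markers = colnames(X), indices = NA)
}

# gaussian feature matrix with the first `k_strong` features carrying a
# logistic signal of the given log-odds coefficient
simulate_fm <- function(n = 100, p = 10, k_strong = 3, beta = 2, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("M%02d{5}", seq_len(p))))
  eta <- X[, seq_len(k_strong), drop = FALSE] %*% rep(beta, k_strong)
  y <- rbinom(n, 1, plogis(drop(eta)))
  # guard against degenerate draws in small samples
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  fm_from_matrix(X, y)
}

# the study-conditions cohort for recovery experiments: 3 markers with
# change-point rises, 7 uninformative, sized at three times the evaluation set
recovery_config <- function(seed) {
  informative <- list(
    marker_kinetics("CA125", 1.10, 0.25, 0.04, changepoint_tau = 24,
                    rise_slope_type1 = 0.30, rise_slope_type2 = 0.45),
    marker_kinetics("HE4", 1.65, 0.20, 0.08, changepoint_tau = 30,
                    rise_slope_type1 = 0.20, rise_slope_type2 = 0.35),
    marker_kinetics("CHI3L1", 4.55, 0.22, 0.14, changepoint_tau = 36,
                    rise_slope_type1 = 0.15, rise_slope_type2 = 0.30)
  )
  noise <- lapply(sprintf("NOISE%02d", 1:7), function(nm) {
    marker_kinetics(nm, 2.0, 0.20, 0.15)
  })
  sim_config(n_controls = 93, n_type1 = 18, n_type2 = 66, n_borderline = 0,
             markers = c(informative, noise), seed = seed)
}
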