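# Fixed-specificity performance, interval estimation, paired comparison
# against a single-marker cut-off reference, calibration, and the univariate
# group-comparison screen.

#' Decision threshold achieving a target specificity
#'
#' Returns the smallest threshold such that the fraction of control scores
#' strictly below it is at least `target`; scores at or above the threshold
#' are called positive (ties count as positive, which is conservative for
#' the specificity claim). The threshold is the smallest observed control
#' score achieving the target (the set of achieving real thresholds is open
#' below it), `-Inf` at `target = 0` (everything positive), or — when no
#' observed score achieves the target, as with fully tied controls — a value
#' just above the control maximum (specificity 1).
#'
#' @param control_scores numeric vector of control scores (non-empty).
#' @param target specificity in `[0, 1)`.
#' @return The threshold.
#' @export
threshold_at_specificity <- function(control_scores, target) {
  if (length(control_scores) == 0) stop("no control scores")
  if (anyNA(control_scores)) stop("control scores contain NA")
  stopifnot(is.numeric(target), length(target) == 1, target >= 0, target < 1)
  candidates <- c(-Inf, sort(unique(control_scores)))
  for (thr in candidates) {
    if (mean(control_scores < thr) >= target) return(thr)
  }
  # no observed score achieves the target (e.g. all controls tied): any
  # threshold just above the maximum gives specificity 1 >= target
  mx <- max(control_scores)
  mx + max(abs(mx), 1) * 1e-9
}

#' Sensitivity at a fixed specificity
#'
#' Sets the threshold from the control scores with
#' [threshold_at_specificity()], then reports the fraction of case scores at
#' or above it, together with the achieved (not target) specificity and the
#' threshold itself.
#'
#' @param case_scores,control_scores numeric score vectors (non-empty).
#' @param target specificity in `[0, 1)`.
#' @return List: `sensitivity`, `achieved_specificity`, `threshold`.
#' @export
sensitivity_at_specificity <- function(case_scores, control_scores, target) {
  if (length(case_scores) == 0) stop("no case scores")
  thr <- threshold_at_specificity(control_scores, target)
  list(sensitivity = mean(case_scores >= thr),
       achieved_specificity = mean(control_scores < thr),
       threshold = thr)
}

#' Stratified-bootstrap confidence interval for sensitivity at fixed specificity
#'
#' Cases and controls are resampled independently with replacement; in every
#' replicate both the threshold and the sensitivity are recomputed, so
#' threshold uncertainty propagates into the interval. The 95% interval is
#' the 2.5/97.5 percentile of the replicate sensitivities; the bootstrap
#' median is reported alongside the plug-in point estimate.
#'
#' @inheritParams sensitivity_at_specificity
#' @param B number of replicates (default 2000, minimum 100).
#' @param seed integer seed; fixes the interval exactly.
#' @return List: `sensitivity` (plug-in), `boot_median`, `ci` (length-2),
#'   `B`.
#' @export
bootstrap_sensitivity_ci <- function(case_scores, control_scores, target,
                                     B = 2000, seed = 1L) {
  stopifnot(B >= 100)
  n1 <- length(case_scores); n0 <- length(control_scores)
  if (n1 == 0 || n0 == 0) stop("both groups must be non-empty")
  set.seed(seed)
  sens <- numeric(B)
  for (b in seq_len(B)) {
    cs <- case_scores[sample.int(n1, n1, replace = TRUE)]
    ct <- control_scores[sample.int(n0, n0, replace = TRUE)]
    thr <- threshold_at_specificity(ct, target)
    sens[b] <- mean(cs >= thr)
  }
  point <- sensitivity_at_specificity(case_scores, control_scores, target)
  list(sensitivity = point$sensitivity,
       boot_median = unname(quantile(sens, 0.5)),
       ci = unname(quantile(sens, c(0.025, 0.975))),
       B = B)
}

#' Area under the ROC curve (point estimate)
#'
#' The Mann-Whitney probability that a random case scores above a random
#' control, with ties counted one half; computed from ranks.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (1 = case).
#' @return AUC in `[0, 1]`.
#' @export
auc_point <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC with a DeLong 95% confidence interval
#'
#' The point estimate is the tie-corrected Mann-Whitney AUC; the interval is
#' the asymptotic Wald interval with DeLong's structural-component variance,
#' truncated to `[0, 1]`.
#'
#' @inheritParams auc_point
#' @return List: `auc`, `ci` (length-2).
#' @export
auc_delong <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("AUC needs both classes present")
  roc <- pROC::roc(response = labels, predictor = scores,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(pROC::ci.auc(roc, method = "delong"))
  list(auc = as.numeric(pROC::auc(roc)),
       ci = pmin(pmax(as.numeric(ci[c(1, 3)]), 0), 1))
}

#' Exact one-tailed McNemar test on paired case calls
#'
#' With `b` the number of cases caught by the model but not the reference
#' and `c` the number caught by the reference only, the exact one-tailed
#' p-value is `P(X >= b)` for `X ~ Binomial(b + c, 1/2)` — the alternative
#' being that the model is more sensitive than the reference. With no
#' discordant pairs the p-value is 1.
#'
#' @param model_calls,ref_calls 0/1 vectors of positivity calls, paired on
#'   identical units.
#' @param labels optional 0/1 labels; when given, the comparison is
#'   restricted to cases (`labels == 1`), the paired-sensitivity setting.
#' @return List: `p`, `b`, `c`.
#' @export
mcnemar_exact_one_tailed <- function(model_calls, ref_calls, labels = NULL) {
  stopifnot(length(model_calls) == length(ref_calls))
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(model_calls))
    keep <- labels == 1
    model_calls <- model_calls[keep]
    ref_calls <- ref_calls[keep]
  }
  model_calls <- as.integer(model_calls)
  ref_calls <- as.integer(ref_calls)
  b <- sum(model_calls == 1 & ref_calls == 0)
  cc <- sum(model_calls == 0 & ref_calls == 1)
  p <- if (b + cc == 0) 1.0 else pbinom(b - 1, b + cc, 0.5, lower.tail = FALSE)
  list(p = p, b = b, c = cc)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Units are grouped into deciles of predicted risk (tied probabilities stay
#' together, so fewer than `groups` bins can result); groups with zero
#' expected variance are merged downward. The statistic is
#' `sum((O - E)^2 / (E * (1 - E / n_g)))` over groups with `O` observed and
#' `E` expected event counts, referred to a chi-square with
#' (number of groups - 2) degrees of freedom. p < 0.05 indicates a poorly
#' calibrated model.
#'
#' @param probs predicted probabilities in (0, 1).
#' @param labels 0/1 outcomes.
#' @param groups target number of risk groups (default 10).
#' @return List: `statistic`, `df`, `p`, `n_groups`.
#' @export
hosmer_lemeshow <- function(probs, labels, groups = 10) {
  stopifnot(length(probs) == length(labels))
  n <- length(probs)
  if (n < 2 * groups) stop("hosmer_lemeshow needs n >= 2 * groups")
  if (any(probs <= 0 | probs >= 1)) stop("probabilities must lie in (0, 1)")
  if (length(unique(probs)) < 3) stop("cannot form groups: fewer than 3 distinct probabilities")
  labels <- as.integer(labels)

  breaks <- unique(quantile(probs, seq(0, 1, length.out = groups + 1)))
  if (length(breaks) < 3) stop("cannot form groups: probabilities too concentrated")
  grp <- cut(probs, breaks = breaks, include.lowest = TRUE, labels = FALSE)

  O <- tapply(labels, grp, sum)
  E <- tapply(probs, grp, sum)
  ng <- tapply(labels, grp, length)
  # merge groups whose variance term would vanish into their lower neighbour
  keep_O <- numeric(0); keep_E <- numeric(0); keep_n <- numeric(0)
  for (g in seq_along(O)) {
    v <- E[g] * (1 - E[g] / ng[g])
    if (v <= 1e-12 && length(keep_O) > 0) {
      last <- length(keep_O)
      keep_O[last] <- keep_O[last] + O[g]
      keep_E[last] <- keep_E[last] + E[g]
      keep_n[last] <- keep_n[last] + ng[g]
    } else {
      keep_O <- c(keep_O, O[g]); keep_E <- c(keep_E, E[g]); keep_n <- c(keep_n, ng[g])
    }
  }
  v <- keep_E * (1 - keep_E / keep_n)
  v[v <= 1e-12] <- NA  # a still-degenerate first group contributes nothing
  stat <- sum((keep_O - keep_E)^2 / v, na.rm = TRUE)
  df <- max(length(keep_O) - 2, 1)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE),
       n_groups = length(keep_O))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness and kurtosis Z statistics into
#' `K2 = Zs^2 + Zk^2`, referred to a chi-square with 2 degrees of freedom.
#' Requires n >= 8 (the kurtosis approximation breaks down below that).
#'
#' @param x numeric sample.
#' @return List: `statistic` (K2), `p`.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8) stop("dagostino_pearson requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  if (m2 == 0) stop("constant sample")

  # skewness: D'Agostino (1970) transformation to normality
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Zs <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983) transformation
  b2 <- m4 / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  Zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- Zs^2 + Zk^2
  list(statistic = K2, p = pchisq(K2, df = 2, lower.tail = FALSE))
}

#' Univariate two-group comparison with a normality gate
#'
#' Runs the D'Agostino-Pearson omnibus test on each group at alpha = 0.05;
#' if both pass, a two-sided Welch t-test is used, otherwise a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test. Groups smaller than 8 fall back
#' to Mann-Whitney with a warning (the normality test is invalid there).
#'
#' @param group_a_values,group_b_values numeric samples (each n >= 3).
#' @param alpha normality-gate level (default 0.05).
#' @return List: `test_used` (`"t"` or `"mann_whitney"`), `p`.
#' @export
univariate_compare <- function(group_a_values, group_b_values, alpha = 0.05) {
  na <- length(group_a_values); nb <- length(group_b_values)
  if (na < 3 || nb < 3) stop("univariate_compare needs n >= 3 per group")
  if (na < 8 || nb < 8) {
    warning("group too small for the normality test; using Mann-Whitney")
    parametric <- FALSE
  } else {
    parametric <- dagostino_pearson(group_a_values)$p > alpha &&
      dagostino_pearson(group_b_values)$p > alpha
  }
  if (parametric) {
    list(test_used = "t",
         p = t.test(group_a_values, group_b_values)$p.value)
  } else {
    list(test_used = "mann_whitney",
         p = suppressWarnings(
           wilcox.test(group_a_values, group_b_values, exact = FALSE,
                       correct = TRUE)$p.value))
  }
}

case_final_units <- function(fm) {
  # one row per case subject: its final (largest-age) unit
  cases <- fm[fm$label == 1, , drop = FALSE]
  keep <- unlist(lapply(split(seq_len(nrow(cases)), cases$subject_id),
                        function(ix) ix[which.max(cases$age_years[ix])]))
  out <- cases[sort(keep), , drop = FALSE]
  out[order(out$subject_id), , drop = FALSE]
}

#' Full fixed-specificity performance summary for one model
#'
#' Orchestrates the evaluation of a fitted model against a reference on an
#' evaluation cohort: control scores are collected per visit
#' (`spec_unit = "visit"`, from the rolling feature matrix — the setting in
#' which 158/175 and 167/175 control samples below threshold give the
#' conventional 0.903 and 0.954 specificity levels) or per subject
#' (`spec_unit = "subject"`, terminal matrix); case positivity always uses
#' each case subject's final eligible unit. For every target specificity the
#' threshold, sensitivity and stratified-bootstrap CI are computed; the
#' model is compared with the reference by exact one-tailed McNemar on the
#' paired case calls at the first target; AUC (DeLong CI) uses the same
#' score sets; calibration is Hosmer-Lemeshow on the model's predicted
#' probabilities for all evaluation units.
#'
#' @param fitted the `fitted_model` under evaluation.
#' @param reference the reference `fitted_model` (e.g. the final-measurement
#'   CA125 cut-off model), evaluated on identical units.
#' @param fm_terminal terminal-mode `feature_matrix` of the evaluation
#'   cohort.
#' @param fm_rolling rolling-mode `feature_matrix` (required when
#'   `spec_unit = "visit"`).
#' @param targets fixed specificities (default 0.903, 0.954).
#' @param spec_unit `"visit"` (default) or `"subject"`.
#' @param boot_B,seed bootstrap CI settings.
#' @return A `performance_summary` list: `model`, `n_cases`, `n_controls`
#'   (control scoring units), `auc`, `auc_ci`, per-target `thresholds`,
#'   `sensitivities`, `sens_ci` (matrix), `boot_median`, `mcnemar_p`
#'   (+ `mcnemar_b`, `mcnemar_c`), `hl_p`, `hl_statistic`.
#' @export
evaluate_model <- function(fitted, reference, fm_terminal, fm_rolling = NULL,
                           targets = c(0.903, 0.954),
                           spec_unit = c("visit", "subject"),
                           boot_B = 2000, seed = 1L) {
  stopifnot(inherits(fitted, "fitted_model"), inherits(reference, "fitted_model"))
  spec_unit <- match.arg(spec_unit)
  if (spec_unit == "visit" && is.null(fm_rolling)) {
    stop("spec_unit = 'visit' requires the rolling feature matrix")
  }
  ctrl_fm <- if (spec_unit == "visit") {
    fm_rolling[fm_rolling$label == 0, , drop = FALSE]
  } else {
    fm_terminal[fm_terminal$label == 0, , drop = FALSE]
  }
  needed <- union(fitted$spec$features, reference$spec$features)
  ctrl_fm <- complete_units(ctrl_fm, needed, quiet = TRUE)
  case_fm <- complete_units(case_final_units(fm_terminal), needed, quiet = TRUE)
  if (nrow(ctrl_fm) == 0 || nrow(case_fm) == 0) {
    stop("evaluation set has no complete-case units in one group")
  }

  score_sets <- lapply(list(model = fitted, ref = reference), function(f) {
    list(ctrl = predict(f, ctrl_fm), case = predict(f, case_fm))
  })

  k <- length(targets)
  thresholds <- numeric(k); sens <- numeric(k); boot_med <- numeric(k)
  sens_ci <- matrix(NA_real_, k, 2,
                    dimnames = list(format(targets), c("lo", "hi")))
  for (j in seq_len(k)) {
    ci <- bootstrap_sensitivity_ci(score_sets$model$case, score_sets$model$ctrl,
                                   targets[j], B = boot_B,
                                   seed = seed + j - 1L)
    thresholds[j] <- threshold_at_specificity(score_sets$model$ctrl, targets[j])
    sens[j] <- ci$sensitivity
    boot_med[j] <- ci$boot_median
    sens_ci[j, ] <- ci$ci
  }

  thr_ref <- threshold_at_specificity(score_sets$ref$ctrl, targets[1])
  model_calls <- as.integer(score_sets$model$case >= thresholds[1])
  ref_calls <- as.integer(score_sets$ref$case >= thr_ref)
  mc <- mcnemar_exact_one_tailed(model_calls, ref_calls)

  auc <- auc_delong(c(score_sets$model$case, score_sets$model$ctrl),
                    c(rep(1L, nrow(case_fm)), rep(0L, nrow(ctrl_fm))))

  all_fm <- complete_units(fm_terminal, fitted$spec$features, quiet = TRUE)
  hl <- tryCatch(
    hosmer_lemeshow(pmin(pmax(predict(fitted, all_fm), 1e-10), 1 - 1e-10),
                    all_fm$label,
                    groups = min(10, max(3, floor(nrow(all_fm) / 4)))),
    error = function(e) list(statistic = NA_real_, p = NA_real_))

  structure(list(model = fitted$spec$name, reference = reference$spec$name,
                 spec_unit = spec_unit,
                 n_cases = nrow(case_fm), n_controls = nrow(ctrl_fm),
                 targets = targets, thresholds = thresholds,
                 sensitivities = setNames(sens, format(targets)),
                 boot_median = setNames(boot_med, format(targets)),
                 sens_ci = sens_ci,
                 auc = auc$auc, auc_ci = auc$ci,
                 mcnemar_p = mc$p, mcnemar_b = mc$b, mcnemar_c = mc$c,
                 hl_p = hl$p, hl_statistic = hl$statistic),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat("performance_summary:", x$model, "vs", x$reference,
      sprintf("(%d cases, %d control %s-units)\n",
              x$n_cases, x$n_controls, x$spec_unit))
  cat(sprintf("  AUC %.3f (%.3f-%.3f)\n", x$auc, x$auc_ci[1], x$auc_ci[2]))
  for (j in seq_along(x$targets)) {
    cat(sprintf("  sens@%.3f = %.3f (%.3f-%.3f)\n", x$targets[j],
                x$sensitivities[j], x$sens_ci[j, 1], x$sens_ci[j, 2]))
  }
  cat(sprintf("  McNemar one-tailed p = %.4g (b = %d, c = %d); HL p = %.3g\n",
              x$mcnemar_p, x$mcnemar_b, x$mcnemar_c, x$hl_p))
  invisible(x)
}
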