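test_that("threshold at specificity follows the counting rule", {
  set.seed(1)
  ctrl31 <- rnorm(31)
  thr <- threshold_at_specificity(ctrl31, 0.903)
  expect_lte(sum(ctrl31 >= thr), 3)        # at most 3 of 31 called positive
  expect_gte(sum(ctrl31 < thr), ceiling(0.903 * 31))
  expect_equal(threshold_at_specificity(c(0.1, 0.2, 0.9), 0.66), 0.9)
  expect_equal(mean(c(0.1, 0.2, 0.9) < 0.9), 2 / 3)
  expect_equal(threshold_at_specificity(c(0.3, 0.5), 0), -Inf)
  expect_error(threshold_at_specificity(numeric(0), 0.9), "no control")
  expect_error(threshold_at_specificity(c(1, NA), 0.9), "NA")
})

test_that("the chosen threshold is minimal among all achieving thresholds", {
  set.seed(2)
  for (n in 1:8) {
    for (rep in 1:12) {
      scores <- sample(round(runif(n, 0, 1), 1))  # ties likely
      for (target in c(0, 0.25, 0.5, 0.66, 0.9)) {
        thr <- threshold_at_specificity(scores, target)
        expect_gte(mean(scores < thr), target)
        # no smaller observed score would achieve the target specificity
        for (s2 in scores[scores < thr]) {
          expect_lt(mean(scores < s2), target)
        }
      }
    }
  }
})

test_that("threshold choice is invariant to score order", {
  scores <- c(0.4, 0.1, 0.1, 0.8, 0.3)
  perms <- list(scores, rev(scores), sample(scores), sort(scores))
  thr <- vapply(perms, threshold_at_specificity, numeric(1), target = 0.6)
  expect_true(all(thr == thr[1]))
})

test_that("sensitivity at fixed specificity handles separation and exchangeability", {
  res <- sensitivity_at_specificity(c(5, 6, 7), c(1, 2, 3), 0.6)
  expect_equal(res$sensitivity, 1.0)
  # identical multisets: sensitivity approximately 1 - target
  set.seed(3)
  x <- rnorm(200)
  res2 <- sensitivity_at_specificity(x, x, 0.9)
  expect_lt(abs(res2$sensitivity - (1 - 0.9)), 0.02)
  # order-statistic arithmetic with 175 control visit-scores
  set.seed(4)
  ctrl <- rnorm(175)
  case <- max(ctrl) + 1
  res3 <- sensitivity_at_specificity(case, ctrl, 0.954)
  expect_equal(res3$sensitivity, 1.0)
  expect_lte(sum(ctrl >= res3$threshold), 175 - 167)  # at most 8 positive
  expect_gte(sum(ctrl < res3$threshold), 167)         # ceil(0.954*175)
})

test_that("sensitivity is non-increasing in target specificity", {
  set.seed(5)
  case <- rnorm(40, 1); ctrl <- rnorm(60)
  targets <- seq(0.05, 0.95, by = 0.05)
  sens <- vapply(targets, function(tg) {
    sensitivity_at_specificity(case, ctrl, tg)$sensitivity
  }, numeric(1))
  expect_true(all(diff(sens) <= 1e-12))
})

test_that("bootstrap CI is degenerate under perfect separation and covers the point", {
  ci <- bootstrap_sensitivity_ci(c(10, 11, 12), c(1, 2, 3), 0.6,
                                 B = 200, seed = 1)
  expect_equal(unname(ci$ci), c(1, 1))
  for (s in 1:20) {
    set.seed(100 + s)
    case <- rnorm(25, 0.8); ctrl <- rnorm(30)
    ci <- bootstrap_sensitivity_ci(case, ctrl, 0.9, B = 400, seed = s)
    expect_gte(ci$sensitivity, ci$ci[1] - 1e-12)
    expect_lte(ci$sensitivity, ci$ci[2] + 1e-12)
  }
})

test_that("bootstrap CI width shrinks with the case sample size", {
  widths <- sapply(c(20, 200), function(n1) {
    w <- numeric(10)
    for (s in 1:10) {
      set.seed(200 + s)
      case <- rnorm(n1, 1.2); ctrl <- rnorm(100)
      ci <- bootstrap_sensitivity_ci(case, ctrl, 0.9, B = 300, seed = s)
      w[s] <- diff(ci$ci)
    }
    mean(w)
  })
  expect_lt(widths[2], widths[1])
})

test_that("AUC matches the pair-counting oracle and handles ties", {
  expect_equal(auc_delong(c(0, 1, 2, 3), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(auc_point(c(1, 1), c(0, 1)), 0.5)
  set.seed(6)
  for (rep in 1:30) {
    n <- sample(5:30, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    scores <- round(rnorm(n), 1)  # induces ties
    expect_equal(auc_point(scores, labels), oracle_auc(scores, labels),
                 tolerance = 1e-12)
    expect_equal(auc_delong(scores, labels)$auc, oracle_auc(scores, labels),
                 tolerance = 1e-12)
  }
  ci <- auc_delong(rnorm(30), rbinom(30, 1, 0.5) + c(1, 0))$ci
  expect_true(ci[1] <= ci[2] && ci[1] >= 0 && ci[2] <= 1)
})

test_that("exact one-tailed McNemar equals the binomial tail", {
  mk_calls <- function(b, cc, both = 2, neither = 2) {
    model <- c(rep(1, b), rep(0, cc), rep(1, both), rep(0, neither))
    ref <- c(rep(0, b), rep(1, cc), rep(1, both), rep(0, neither))
    list(model = model, ref = ref)
  }
  x <- mk_calls(6, 0)
  expect_equal(mcnemar_exact_one_tailed(x$model, x$ref)$p, 0.015625)
  x <- mk_calls(3, 3)
  expect_equal(mcnemar_exact_one_tailed(x$model, x$ref)$p, 0.65625)
  x <- mk_calls(0, 5)
  expect_equal(mcnemar_exact_one_tailed(x$model, x$ref)$p, 1.0)
  x <- mk_calls(0, 0)
  expect_equal(mcnemar_exact_one_tailed(x$model, x$ref)$p, 1.0)
  # agreement with explicit binomial summation over a grid of tables
  for (b in 0:6) for (cc in 0:6) {
    x <- mk_calls(b, cc)
    expect_equal(mcnemar_exact_one_tailed(x$model, x$ref)$p,
                 oracle_mcnemar_tail(b, cc), tolerance = 1e-12)
  }
  # model calls a subset of reference calls on cases: p must be 1
  labels <- rep(1, 6)
  expect_equal(mcnemar_exact_one_tailed(c(1, 1, 0, 0, 0, 0),
                                        c(1, 1, 1, 1, 0, 0), labels)$p, 1.0)
})

test_that("Hosmer-Lemeshow is zero on exactly group-calibrated input", {
  # 10 groups of 20 with event counts exactly matching the probabilities
  probs <- rep(seq(0.05, 0.5, by = 0.05), each = 20)
  labels <- unlist(lapply(seq(0.05, 0.5, by = 0.05), function(p) {
    c(rep(1, round(20 * p)), rep(0, 20 - round(20 * p)))
  }))
  hl <- hosmer_lemeshow(probs, labels)
  expect_equal(hl$statistic, 0, tolerance = 1e-12)
  expect_equal(hl$p, 1)
})

test_that("Hosmer-Lemeshow rejects gross miscalibration and bad input", {
  set.seed(7)
  probs <- runif(200, 0.85, 0.95)
  labels <- rbinom(200, 1, 0.1)
  expect_lt(hosmer_lemeshow(probs, labels)$p, 0.001)
  expect_error(hosmer_lemeshow(rep(c(0.4, 0.6), 50), rbinom(100, 1, 0.5)),
               "distinct")
  expect_error(hosmer_lemeshow(runif(10), rbinom(10, 1, 0.5), groups = 10),
               "n >= 2")
  expect_error(hosmer_lemeshow(c(runif(99), 1), rbinom(100, 1, 0.5)),
               "\\(0, 1\\)")
})

test_that("well-calibrated probabilities usually pass Hosmer-Lemeshow", {
  passes <- 0
  for (s in 1:30) {
    set.seed(900 + s)
    probs <- plogis(rnorm(300))
    labels <- rbinom(300, 1, probs)
    if (hosmer_lemeshow(probs, labels)$p > 0.05) passes <- passes + 1
  }
  expect_gte(passes, 27)
})

test_that("D'Agostino-Pearson matches an independent reference implementation", {
  # values frozen from scipy.stats.normaltest on the same vectors
  r2 <- dagostino_pearson(exp(sin(1:30) * 2))
  expect_equal(r2$statistic, 5.6163051532744745, tolerance = 1e-10)
  expect_equal(r2$p, 0.060316319304180084, tolerance = 1e-10)
  r3 <- dagostino_pearson(sin(1:12))
  expect_equal(r3$statistic, 4.576914655774706, tolerance = 1e-10)
  expect_equal(r3$p, 0.10142280336136805, tolerance = 1e-10)
  # an exactly symmetric sample contributes no skewness term
  x <- as.numeric(1:20)
  n <- 20
  m2 <- mean((x - mean(x))^2); m4 <- mean((x - mean(x))^4)
  b2 <- m4 / m2^2
  xk <- (b2 - 3 * (n - 1) / (n + 1)) /
    sqrt(24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5)))
  expect_equal(dagostino_pearson(x)$statistic, (-1.7058104152122062)^2,
               tolerance = 1e-10)
  expect_error(dagostino_pearson(1:7), "n >= 8")
})

test_that("the normality gate routes to the right two-sample test", {
  set.seed(8)
  a <- rnorm(50); b <- rnorm(50)
  res <- univariate_compare(a, b)
  expect_equal(res$test_used, "t")
  # heavy lognormal data fails the gate
  res2 <- univariate_compare(exp(rnorm(50, 0, 1.5)), exp(rnorm(50, 0, 1.5)))
  expect_equal(res2$test_used, "mann_whitney")
  # identical groups: no evidence of a shift
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  res3 <- suppressWarnings(univariate_compare(x, x))
  expect_equal(res3$p, 1)
  expect_warning(univariate_compare(1:5, 6:10), "too small")
  expect_error(univariate_compare(1:2, 1:5), "n >= 3")
})

test_that("null p-values from the univariate screen are roughly uniform", {
  ps <- numeric(100)
  for (s in 1:100) {
    set.seed(4000 + s)
    ps[s] <- univariate_compare(rnorm(40), rnorm(40))$p
  }
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("a model compared with itself is a wash", {
  gen <- generate_cohort(sim_config(seed = 19, n_controls = 12, n_type1 = 0,
                                    n_type2 = 12, n_borderline = 0))
  ch <- log10_transform(suppressMessages(modelling_filter(gen$cohort)))
  fmt <- build_feature_matrix(ch, mode = "terminal")
  fmr <- build_feature_matrix(ch, mode = "rolling")
  ref <- fit_logistic(model_spec("CA125{5}"), fmt)
  ps <- evaluate_model(ref, ref, fmt, fmr, boot_B = 200, seed = 2)
  expect_equal(ps$mcnemar_p, 1.0)
  expect_equal(ps$mcnemar_b + ps$mcnemar_c, 0)
})

test_that("visit-level specificity uses control visits as the unit", {
  gen <- generate_cohort(sim_config(seed = 23, n_controls = 25, n_type1 = 0,
                                    n_type2 = 10, n_borderline = 0,
                                    visits_min = 7, visits_max = 7))
  ch <- log10_transform(suppressMessages(modelling_filter(gen$cohort)))
  fmt <- build_feature_matrix(ch, mode = "terminal")
  fmr <- build_feature_matrix(ch, mode = "rolling")
  ref <- fit_logistic(model_spec("CA125{5}"), fmt)
  ps <- evaluate_model(ref, ref, fmt, fmr, targets = c(0.954),
                       spec_unit = "visit", boot_B = 150, seed = 5)
  n_ctrl_visits <- sum(fmr$label == 0)
  expect_equal(ps$n_controls, n_ctrl_visits)
  scores <- predict(ref, fmr[fmr$label == 0, ])
  expect_lte(sum(scores >= ps$thresholds[1]),
             n_ctrl_visits - ceiling(0.954 * n_ctrl_visits))
  ps_sub <- evaluate_model(ref, ref, fmt, fmr, targets = c(0.954),
                           spec_unit = "subject", boot_B = 150, seed = 5)
  expect_equal(ps_sub$n_controls, 25)
})
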