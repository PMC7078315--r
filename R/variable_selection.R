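# Five-criterion variable-selection ensemble over trend-index features:
# AIC stepwise, lasso first-lambda rule, bootstrap lasso inclusion frequency,
# and random-forest permutation (mean accuracy decrease) and Gini importances.
# All operations canonicalise row order by unit id before touching the RNG,
# so results are invariant to the order units arrive in.

#' Configure the selection ensemble
#'
#' @param lambda_step grid step for the lasso penalty scan (default 0.01).
#' @param lasso_target_vars the lasso penalty is the first grid value leaving
#'   at most this many variables in the model (default 3).
#' @param bootstrap_B number of bootstrap resamples for the bootstrap lasso
#'   (default 200).
#' @param rf_trees random-forest size (default 500).
#' @param top_m how many top-ranked features each ranking criterion
#'   contributes to the consensus pool (default 5).
#' @param seed integer seed controlling the bootstrap and the forest.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(lambda_step = 0.01, lasso_target_vars = 3,
                             bootstrap_B = 200, rf_trees = 500,
                             top_m = 5, seed = 1L) {
  stopifnot(lambda_step > 0, bootstrap_B >= 1, lasso_target_vars >= 1,
            rf_trees >= 1, top_m >= 1)
  structure(list(lambda_step = lambda_step,
                 lasso_target_vars = lasso_target_vars,
                 bootstrap_B = bootstrap_B, rf_trees = rf_trees,
                 top_m = top_m, seed = as.integer(seed)),
            class = "selection_config")
}

canonical_fm <- function(fm, features = feature_names(fm)) {
  fm <- complete_units(fm, features, quiet = TRUE)
  fm <- fm[order(fm$unit_id), , drop = FALSE]
  rownames(fm) <- NULL
  fm
}

# Feature names contain braces, which are not syntactic; selection and model
# fitting map them to safe placeholders for formula interfaces.
safe_names <- function(features) {
  setNames(features, paste0("V", seq_along(features)))
}

#' AIC-guided bidirectional stepwise logistic selection
#'
#' Starts from the intercept-only logistic model and steps in both
#' directions over all candidate features, minimising AIC. Perfect
#' separation encountered along the path is flagged (the selection is still
#' recorded; coefficients of a separated model are unreliable).
#'
#' @param fm a `feature_matrix`; units with undefined features are dropped.
#' @param features candidate columns (default all).
#' @return List with `selected` (character vector, possibly empty),
#'   `aic` of the chosen model, and `separation` flag.
#' @export
aic_stepwise <- function(fm, features = feature_names(fm)) {
  fm <- canonical_fm(fm, features)
  if (length(unique(fm$label)) < 2 || min(table(fm$label)) < 2) {
    stop("aic_stepwise needs at least 2 units per class")
  }
  map <- safe_names(features)
  dat <- as.data.frame(fm[, features, drop = FALSE], check.names = FALSE)
  names(dat) <- names(map)
  dat$.y <- fm$label

  separated <- FALSE
  handler <- function(w) {
    msg <- conditionMessage(w)
    if (grepl("fitted probabilities numerically 0 or 1", msg)) {
      separated <<- TRUE
      invokeRestart("muffleWarning")
    } else if (grepl("algorithm did not converge", msg)) {
      # separable candidate models along the path; selection is still valid
      separated <<- TRUE
      invokeRestart("muffleWarning")
    }
  }
  fit0 <- withCallingHandlers(
    glm(.y ~ 1, data = dat, family = binomial()), warning = handler)
  upper <- as.formula(paste("~", paste(names(map), collapse = " + ")))
  best <- withCallingHandlers(
    MASS::stepAIC(fit0, scope = list(lower = ~1, upper = upper),
                  direction = "both", trace = 0),
    warning = handler)
  sel_safe <- setdiff(names(coef(best)), "(Intercept)")
  # the warning can be muffled upstream of stepAIC's refits; also detect
  # separation from the final model's degenerate fitted probabilities
  mu <- best$fitted.values
  if (!separated && length(sel_safe) > 0 &&
      all(mu[dat$.y == 1] > 1 - 1e-8) && all(mu[dat$.y == 0] < 1e-8)) {
    separated <- TRUE
  }
  list(selected = unname(map[sel_safe]), aic = best$aic,
       separation = separated)
}

standardize_features <- function(X) {
  mu <- colMeans(X)
  sdev <- apply(X, 2, sd)
  sdev[sdev == 0] <- 1  # constant columns carry no signal; leave centred at 0
  scale(X, center = mu, scale = sdev)
}

#' Lasso with the first-lambda-reaching-the-target rule
#'
#' Features are standardised (zero mean, unit variance), then an L1-penalised
#' logistic model is fitted along the grid lambda = 0, step, 2*step, ...; the
#' chosen penalty is the first grid value at which the active set has at most
#' `lasso_target_vars` features. Because the logistic lasso path can jump
#' straight past the target size, "at most" rather than "exactly" defines
#' the stopping rule. If even lambda = 0 already satisfies the rule it is
#' returned; if no grid value up to full shrinkage reaches the target (which
#' cannot happen, since the active set is empty at large lambda) the
#' full-shrinkage lambda is returned with an empty set and a warning.
#'
#' @param fm a `feature_matrix`.
#' @param cfg a [selection_config()].
#' @param features candidate columns (default all).
#' @return List with `lambda` and `selected`.
#' @export
lasso_first_lambda <- function(fm, cfg = selection_config(),
                               features = feature_names(fm)) {
  fm <- canonical_fm(fm, features)
  X <- standardize_features(as.matrix(fm[, features, drop = FALSE]))
  y <- fm$label
  if (length(unique(y)) < 2) stop("lasso needs both classes present")

  # lambda at which every coefficient is zero (glmnet convention: gradients
  # of the null model, with the 1/n loss scaling)
  lambda_max <- max(abs(crossprod(X, y - mean(y)))) / length(y)
  grid <- seq(0, ceiling(lambda_max / cfg$lambda_step + 1) * cfg$lambda_step,
              by = cfg$lambda_step)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        lambda = rev(grid), standardize = FALSE,
                        thresh = 1e-8)
  # the fitted path is exactly the requested (decreasing) grid; walk it from
  # lambda = 0 upward
  path_lambda <- fit$lambda
  nz <- fit$df
  ord <- order(path_lambda)  # ascending
  for (j in ord) {
    if (nz[j] <= cfg$lasso_target_vars) {
      active <- features[as.matrix(fit$beta)[, j] != 0]
      return(list(lambda = path_lambda[j], selected = active))
    }
  }
  warning("no grid lambda reached the target active-set size; returning full shrinkage")
  list(lambda = grid[length(grid)], selected = character(0))
}

#' Bootstrap lasso inclusion frequencies
#'
#' Draws `bootstrap_B` resamples of the units (with replacement, stratified
#' by label so every resample contains both classes), applies the
#' first-lambda lasso rule to each, and reports for every feature the
#' fraction of resamples in which it appeared in the returned (top-three)
#' active set. Deterministic given `cfg$seed`.
#'
#' @inheritParams lasso_first_lambda
#' @return Named numeric vector of inclusion frequencies in `[0, 1]`.
#' @export
bootstrap_lasso <- function(fm, cfg = selection_config(),
                            features = feature_names(fm)) {
  fm <- canonical_fm(fm, features)
  idx_case <- which(fm$label == 1)
  idx_ctrl <- which(fm$label == 0)
  if (length(idx_case) == 0 || length(idx_ctrl) == 0) {
    stop("bootstrap_lasso needs both classes present")
  }
  counts <- setNames(numeric(length(features)), features)
  set.seed(cfg$seed)
  for (b in seq_len(cfg$bootstrap_B)) {
    rows <- c(sample(idx_case, length(idx_case), replace = TRUE),
              sample(idx_ctrl, length(idx_ctrl), replace = TRUE))
    res <- suppressWarnings(
      lasso_first_lambda(fm[rows, , drop = FALSE], cfg, features))
    counts[res$selected] <- counts[res$selected] + 1
  }
  counts / cfg$bootstrap_B
}

#' Random-forest permutation and Gini importances
#'
#' Fits a classification random forest of `cfg$rf_trees` trees and returns
#' the out-of-bag permutation importance (mean decrease in accuracy) and the
#' total Gini impurity decrease per feature. Deterministic given `cfg$seed`.
#'
#' @inheritParams lasso_first_lambda
#' @return List with named numeric vectors `mda` and `gini`.
#' @export
rf_importance <- function(fm, cfg = selection_config(),
                          features = feature_names(fm)) {
  fm <- canonical_fm(fm, features)
  y <- factor(fm$label, levels = c(0, 1))
  if (length(unique(fm$label)) < 2) stop("rf_importance needs both classes present")
  X <- as.data.frame(fm[, features, drop = FALSE], check.names = FALSE)
  names(X) <- names(safe_names(features))
  set.seed(cfg$seed)
  rf <- randomForest::randomForest(x = X, y = y, ntree = cfg$rf_trees,
                                   importance = TRUE)
  imp <- randomForest::importance(rf)
  list(mda = setNames(imp[, "MeanDecreaseAccuracy"], features),
       gini = setNames(imp[, "MeanDecreaseGini"], features))
}

#' Run the full selection ensemble
#'
#' @inheritParams lasso_first_lambda
#' @return A `selection_report`: data.frame with one row per feature and
#'   columns `feature`, `aic_selected`, `lasso_selected`,
#'   `bootstrap_frequency`, `rf_mda`, `rf_gini`; the lasso penalty and config
#'   are attached as attributes.
#' @export
select_features <- function(fm, cfg = selection_config(),
                            features = feature_names(fm)) {
  aic <- aic_stepwise(fm, features)
  las <- lasso_first_lambda(fm, cfg, features)
  freq <- bootstrap_lasso(fm, cfg, features)
  rf <- rf_importance(fm, cfg, features)
  report <- data.frame(
    feature = features,
    aic_selected = features %in% aic$selected,
    lasso_selected = features %in% las$selected,
    bootstrap_frequency = unname(freq[features]),
    rf_mda = unname(rf$mda[features]),
    rf_gini = unname(rf$gini[features]),
    stringsAsFactors = FALSE
  )
  structure(report, class = c("selection_report", "data.frame"),
            lasso_lambda = las$lambda, aic_separation = aic$separation,
            config = cfg)
}

top_m_features <- function(score, names, m) {
  ord <- order(-score, names)
  names[ord][seq_len(min(m, length(names)))]
}

#' Consensus candidate pool from a selection report
#'
#' The pool is the union of: the AIC-selected set, the lasso-selected set,
#' and the top `top_m` features by bootstrap inclusion frequency, by
#' permutation importance, and by Gini importance. Ties within a ranking are
#' broken by feature name order, so the pool is deterministic.
#'
#' @param report a `selection_report` from [select_features()].
#' @param cfg a [selection_config()] (only `top_m` is used).
#' @return Character vector of pool features, sorted by name.
#' @export
consensus_pool <- function(report, cfg = selection_config()) {
  stopifnot(inherits(report, "selection_report"))
  m <- cfg$top_m
  pool <- union(report$feature[report$aic_selected],
                report$feature[report$lasso_selected])
  pool <- union(pool, top_m_features(report$bootstrap_frequency, report$feature, m))
  pool <- union(pool, top_m_features(report$rf_mda, report$feature, m))
  pool <- union(pool, top_m_features(report$rf_gini, report$feature, m))
  sort(pool)
}
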