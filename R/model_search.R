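# Exhaustive enumeration, maximum-likelihood fitting and leave-one-out
# cross-validation of all logistic models with 1-3 trend-index features.

#' Specify a 1-3 feature logistic model
#'
#' @param features 1 to 3 distinct feature names.
#' @return A `model_spec` with the conventional concatenated name, e.g.
#'   `"CA125{3}AGR2{3}CHI3L1{3}"`.
#' @export
model_spec <- function(features) {
  features <- as.character(features)
  if (length(features) < 1 || length(features) > 3) {
    stop("a model spec has 1 to 3 features")
  }
  if (anyDuplicated(features)) stop("duplicate features in model spec")
  structure(list(features = features, name = paste(features, collapse = "")),
            class = "model_spec")
}

#' Enumerate all models with up to three features from a pool
#'
#' @param pool non-empty character vector of candidate features.
#' @param max_size largest model size (default 3).
#' @return List of [model_spec()] objects: all subsets of size 1, 2, 3 in
#'   deterministic lexicographic order of the sorted pool.
#' @export
enumerate_models <- function(pool, max_size = 3) {
  pool <- sort(unique(as.character(pool)))
  if (length(pool) == 0) stop("empty candidate pool")
  specs <- list()
  for (size in seq_len(min(max_size, length(pool)))) {
    combs <- combn(pool, size, simplify = FALSE)
    specs <- c(specs, lapply(combs, model_spec))
  }
  specs
}

# IRLS logistic fit with an optional ridge penalty (intercept unpenalised).
# The tiny default ridge is a numerical-stability device for separated data,
# not a modelling choice.
ridge_logistic <- function(X, y, lambda = 0, start = NULL, maxit = 50,
                           tol = 1e-10) {
  p <- ncol(X)
  beta <- if (is.null(start)) rep(0, p) else start
  D <- diag(c(0, rep(lambda, p - 1)), p)
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    fit <- tryCatch(solve(crossprod(X, w * X) + D, crossprod(X, w * z)),
                    error = function(e) NULL)
    if (is.null(fit)) break
    beta <- drop(fit)
    mu2 <- plogis(pmin(pmax(drop(X %*% beta), -30), 30))
    dev <- -2 * sum(y * log(pmax(mu2, 1e-300)) +
                      (1 - y) * log(pmax(1 - mu2, 1e-300)))
    if (abs(dev - dev_old) < tol * (abs(dev) + 0.1)) { converged <- TRUE; break }
    dev_old <- dev
  }
  list(coefficients = beta, converged = converged)
}

logit_fit_matrix <- function(X, y, start = NULL) {
  separated <- FALSE
  fit <- withCallingHandlers(
    glm.fit(X, y, family = binomial(), start = start,
            control = glm.control(epsilon = 1e-9, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- coef(fit)
  # warning-independent separation check: degenerate fitted probabilities
  if (!separated && length(fit$fitted.values) > 0) {
    mu <- fit$fitted.values
    if (all(mu[y == 1] > 1 - 1e-8) && all(mu[y == 0] < 1e-8)) separated <- TRUE
  }
  if (any(!is.finite(beta))) {
    rfit <- ridge_logistic(X, y, lambda = 1e-6)
    beta <- rfit$coefficients
    separated <- TRUE
    converged <- rfit$converged
  } else {
    converged <- fit$converged
  }
  list(coefficients = beta, converged = converged, separated = separated)
}

#' Fit a logistic model on the whole data set
#'
#' Maximum-likelihood logistic (logit-link) fit of a [model_spec()] on the
#' complete-case units of a feature matrix. Perfect or quasi-complete
#' separation is detected and flagged; the reported coefficients then come
#' from a refit with a tiny ridge penalty (1e-6, intercept unpenalised) so
#' the returned model is still usable as a scoring rule.
#'
#' @param spec a [model_spec()].
#' @param fm a `feature_matrix` containing the spec's features.
#' @return A `fitted_model`: spec, intercept + coefficients, `n`,
#'   `converged` and `separated` flags.
#' @export
fit_logistic <- function(spec, fm) {
  stopifnot(inherits(spec, "model_spec"))
  missing_f <- setdiff(spec$features, names(fm))
  if (length(missing_f) > 0) {
    stop("feature matrix lacks feature(s): ", paste(missing_f, collapse = ", "))
  }
  fm <- canonical_fm(fm, spec$features)
  y <- fm$label
  if (length(y) == 0 || min(table(factor(y, levels = c(0, 1)))) < 2) {
    stop("fit_logistic needs at least 2 complete-case units per class")
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(fm[, spec$features, drop = FALSE]))
  fit <- logit_fit_matrix(X, y)
  mu <- plogis(pmin(pmax(drop(X %*% fit$coefficients), -30), 30))
  w <- pmax(mu * (1 - mu), 1e-12)
  se <- tryCatch(sqrt(diag(solve(crossprod(X, w * X)))),
                 error = function(e) rep(NA_real_, ncol(X)))
  structure(list(spec = spec,
                 coefficients = setNames(fit$coefficients, colnames(X)),
                 se = setNames(se, colnames(X)),
                 n = length(y), converged = fit$converged,
                 separated = fit$separated),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("fitted_model", x$spec$name, "(n =", x$n)
  if (x$separated) cat(", separated")
  cat(")\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Predicted probabilities from a fitted model
#'
#' @param object a `fitted_model`.
#' @param fm a `feature_matrix` (units with missing features get `NA`).
#' @param ... unused.
#' @return Numeric vector of probabilities aligned with `fm`'s rows.
#' @export
predict.fitted_model <- function(object, fm, ...) {
  X <- as.matrix(fm[, object$spec$features, drop = FALSE])
  eta <- object$coefficients[1] + drop(X %*% object$coefficients[-1])
  plogis(eta)
}

#' Leave-one-out cross-validated predictions for a model spec
#'
#' Each analysis unit (one subject in terminal mode) is held out in turn;
#' the model is refitted on the remaining units and the held-out unit's
#' probability predicted. A training fold that loses one class entirely
#' falls back to an intercept-only model predicting the fold prevalence
#' (counted and reported). Predictions are clamped to the open interval
#' (0, 1). Deterministic: no randomness is involved.
#'
#' @param spec a [model_spec()].
#' @param fm a `feature_matrix`.
#' @param targets specificities at which cross-validated sensitivity is
#'   summarised (default 0.903 and 0.954).
#' @return A `loocv_result`: data.frame of out-of-fold predictions
#'   (`unit_id`, `label`, `cv_prob`) plus summary attributes `cv_auc` and
#'   `cv_sens` (named by target).
#' @export
loocv_predict <- function(spec, fm, targets = c(0.903, 0.954)) {
  stopifnot(inherits(spec, "model_spec"))
  fm <- canonical_fm(fm, spec$features)
  n <- nrow(fm)
  if (n < 3) stop("leave-one-out cross-validation needs at least 3 units")
  y <- fm$label
  X <- cbind(`(Intercept)` = 1, as.matrix(fm[, spec$features, drop = FALSE]))
  full <- logit_fit_matrix(X, y)
  eps <- 1e-12
  preds <- numeric(n)
  single_class_folds <- 0L
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2) {
      single_class_folds <- single_class_folds + 1L
      preds[i] <- mean(ytr)
      next
    }
    fit <- tryCatch(
      logit_fit_matrix(X[-i, , drop = FALSE], ytr,
                       start = full$coefficients),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- ridge_logistic(X[-i, , drop = FALSE], ytr, lambda = 1e-6)
    }
    eta <- sum(X[i, ] * fit$coefficients)
    preds[i] <- plogis(eta)
  }
  preds <- pmin(pmax(preds, eps), 1 - eps)
  if (single_class_folds > 0) {
    message("loocv_predict: ", single_class_folds,
            " fold(s) fell back to the intercept (single-class training set)")
  }
  cv_sens <- vapply(targets, function(tg) {
    thr <- threshold_at_specificity(preds[y == 0], tg)
    mean(preds[y == 1] >= thr)
  }, numeric(1))
  structure(data.frame(unit_id = fm$unit_id, label = y, cv_prob = preds,
                       stringsAsFactors = FALSE),
            class = c("loocv_result", "data.frame"),
            spec = spec, cv_auc = auc_point(preds, y),
            cv_sens = setNames(cv_sens, format(targets)),
            targets = targets)
}

#' Rank cross-validated models
#'
#' Stable descending sort of [loocv_predict()] results by the chosen
#' criterion; ties are broken by fewer features, then by model name.
#'
#' @param results list of `loocv_result` objects.
#' @param criterion `"cv_sens_at_spec"` (default; uses `target`) or
#'   `"cv_auc"`.
#' @param target the fixed specificity used by `"cv_sens_at_spec"`
#'   (default 0.903).
#' @return data.frame with one row per model: `name`, `n_features`,
#'   `cv_auc`, one `cv_sens_*` column per target, and `score` (the ranking
#'   criterion), ordered best first.
#' @export
rank_models <- function(results, criterion = c("cv_sens_at_spec", "cv_auc"),
                        target = 0.903) {
  criterion <- match.arg(criterion)
  if (length(results) == 0) stop("no results to rank")
  tab <- do.call(rbind, lapply(results, function(r) {
    spec <- attr(r, "spec")
    sens <- attr(r, "cv_sens")
    row <- data.frame(name = spec$name, n_features = length(spec$features),
                      cv_auc = attr(r, "cv_auc"), stringsAsFactors = FALSE)
    for (j in seq_along(sens)) {
      row[[paste0("cv_sens_", names(sens)[j])]] <- sens[j]
    }
    row
  }))
  tab$score <- if (criterion == "cv_auc") {
    tab$cv_auc
  } else {
    col <- paste0("cv_sens_", format(target))
    if (!col %in% names(tab)) {
      stop("target specificity ", target, " was not computed in the results")
    }
    tab[[col]]
  }
  ord <- order(-tab$score, tab$n_features, tab$name)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Enumerate, cross-validate and rank all models over a pool
#'
#' @param fm a `feature_matrix`.
#' @param pool candidate features (e.g. from [consensus_pool()]).
#' @param targets fixed specificities to summarise at.
#' @param criterion,target passed to [rank_models()].
#' @param max_size largest model (default 3).
#' @return List with `table` (the ranked data.frame) and `results` (named
#'   list of `loocv_result`, keyed by model name).
#' @export
search_models <- function(fm, pool, targets = c(0.903, 0.954),
                          criterion = "cv_sens_at_spec", target = 0.903,
                          max_size = 3) {
  specs <- enumerate_models(pool, max_size)
  results <- lapply(specs, function(sp) {
    suppressMessages(loocv_predict(sp, fm, targets))
  })
  names(results) <- vapply(specs, `[[`, character(1), "name")
  list(table = rank_models(results, criterion, target), results = results)
}
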