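#' Cross-validation configuration
#'
#' Fivefold cross-validation with random assignment of genotypes to
#' folds, replicated many times, is the evaluation backbone of the
#' pipeline.  `ability_mode` controls how the per-replicate prediction
#' ability is formed: `"per_fold_mean"` correlates predicted and observed
#' values within each held-out fold and averages the five correlations;
#' `"pooled"` correlates all held-out predictions of a replicate at once.
#'
#' @param k folds (>= 2, default 5).
#' @param n_replicates repetitions (default 1000).
#' @param seed RNG seed for the fold assignments.
#' @param ability_mode `"per_fold_mean"` or `"pooled"`.
#' @return a `cv_config` list.
#' @export
cv_config <- function(k = 5, n_replicates = 1000, seed = 1,
                      ability_mode = c("per_fold_mean", "pooled")) {
  assert_that(k >= 2, "k must be >= 2")
  assert_that(n_replicates >= 1, "n_replicates must be >= 1")
  structure(list(k = as.integer(k), n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 ability_mode = match.arg(ability_mode)),
            class = "cv_config")
}

#' Prediction model specification
#'
#' @param method `"rrblup"` or `"plsr"`.
#' @param n_components PLSR components (default 12).
#' @param lambda optional fixed rrBLUP shrinkage.
#' @return a `prediction_model` list.
#' @export
prediction_model <- function(method = c("rrblup", "plsr"),
                             n_components = 12, lambda = NULL) {
  method <- match.arg(method)
  structure(list(method = method, n_components = n_components,
                 lambda = lambda),
            class = "prediction_model")
}

## fit on (Xtr, ytr), predict Xte
fit_predict <- function(model, Xtr, ytr, Xte) {
  fit <- switch(model$method,
    rrblup = fit_rrblup(Xtr, ytr, lambda = model$lambda),
    plsr = suppressWarnings(fit_plsr(Xtr, ytr, model$n_components)))
  predict(fit, Xte)
}

## fold labels 1..k, sizes differing by at most one, random assignment
make_folds <- function(n, k) sample(rep_len(seq_len(k), n))

#' Cross-validated prediction ability
#'
#' Repeated k-fold cross-validation of the Pearson correlation between
#' predicted and observed genotype values ("prediction ability").  When
#' the feature matrix is to be standardized (scaling scenarios), the
#' centering/scaling statistics are recomputed on the training folds of
#' every split and applied to the held-out rows, so no information leaks.
#'
#' @param X genotype x feature matrix, or an `fes_data` from
#'   [apply_fes()] (then `y` and the scaling flag are taken from it).
#' @param y observed genotype values (ignored for `fes_data` input).
#' @param model a [prediction_model()].
#' @param cv a [cv_config()].
#' @param scale_in_cv standardize features per training fold (forced by
#'   `fes_data` input with a scaling scenario).
#' @return a `cv_result`: `abilities` (one per replicate), `mean`, `sd`,
#'   and the configuration.  Held-out folds with zero response variance
#'   yield `NA` fold correlations, which are excluded with a warning.
#' @export
cv_prediction_ability <- function(X, y = NULL, model = prediction_model(),
                                  cv = cv_config(), scale_in_cv = FALSE) {
  if (inherits(X, "fes_data")) {
    scale_in_cv <- X$use_scaling
    y <- X$y
    X <- X$X_raw
  }
  X <- as.matrix(X)
  n <- nrow(X)
  assert_that(length(y) == n, "y must align with the rows of X")
  assert_that(n >= cv$k, "fewer genotypes than folds", "phenosel_config")
  had_na <- FALSE
  abilities <- with_seed(cv$seed, {
    vapply(seq_len(cv$n_replicates), function(r) {
      fold <- make_folds(n, cv$k)
      per_fold <- numeric(cv$k)
      pooled_pred <- pooled_obs <- numeric(0)
      for (f in seq_len(cv$k)) {
        te <- which(fold == f); tr <- which(fold != f)
        Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
        if (scale_in_cv) {
          Xtr <- suppressWarnings(scale_columns(Xtr))
          Xte <- scale_columns(Xte, center = attr(Xtr, "center"),
                               scale = attr(Xtr, "scale"))
        }
        pr <- fit_predict(model, Xtr, y[tr], Xte)
        if (cv$ability_mode == "per_fold_mean") {
          per_fold[f] <- safe_cor(pr, y[te])
        } else {
          pooled_pred <- c(pooled_pred, pr)
          pooled_obs <- c(pooled_obs, y[te])
        }
      }
      if (cv$ability_mode == "per_fold_mean") {
        if (anyNA(per_fold)) had_na <<- TRUE
        mean(per_fold, na.rm = TRUE)
      } else safe_cor(pooled_pred, pooled_obs)
    }, numeric(1))
  })
  if (had_na)
    warning("some held-out folds had zero response variance; their fold correlations were excluded")
  structure(list(abilities = abilities,
                 mean = mean(abilities, na.rm = TRUE),
                 sd = sd(abilities),
                 model = model, cv = cv),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV prediction ability (%s, %d-fold x %d): mean %.3f, sd %.3f\n",
              x$model$method, x$cv$k, x$cv$n_replicates, x$mean, x$sd))
  invisible(x)
}
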