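## The three breeding scenarios.
##
## Scenario 1: new genotypes, same environment -- within-environment
##   repeated CV of genotype-level data.
## Scenario 2: same genotypes, new environment -- train in environment A,
##   predict the shared genotypes from their spectra obtained in B.
## Scenario 3: new genotypes, performance across a series -- train on
##   series-level genotype BLUEs, predict from central-environment
##   spectra, correlate with the series trait BLUEs (phenomic estimated
##   performance, PEP).

scenario_result <- function(scenario, table) {
  structure(list(scenario = scenario, table = table,
                 mean = mean(table$ability, na.rm = TRUE),
                 sd = sd(table$ability)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario %d: %d unit(s), mean ability %.3f (sd %.3f)\n",
              x$scenario, nrow(x$table), x$mean, x$sd))
  invisible(x)
}

## align train/test feature matrices on shared columns, optionally scaling
## the test rows with training statistics
align_features <- function(train_raw, test_raw, use_scaling) {
  common <- intersect(colnames(train_raw), colnames(test_raw))
  assert_that(length(common) >= 1, "no shared wavelengths after reconciliation")
  tr <- train_raw[, common, drop = FALSE]
  te <- test_raw[, common, drop = FALSE]
  if (use_scaling) {
    tr <- suppressWarnings(scale_columns(tr))
    te <- scale_columns(te, center = attr(tr, "center"),
                        scale = attr(tr, "scale"))
  }
  list(train = tr, test = te)
}

#' Scenario 1: predict new genotypes within the training environment
#'
#' For every environment of the trial, builds genotype-level data with
#' the within-environment model (raw-spectrum fallback when the
#' environment is unreplicated) and evaluates repeated k-fold CV
#' prediction ability.
#'
#' @param trial a [pheno_trial()] with spectra and trait.
#' @param fes an [fes_config()].
#' @param sg an [sg_params()] when the FES filters.
#' @param model a [prediction_model()].
#' @param cv a [cv_config()].
#' @param trait trait column name.
#' @param environments subset of environments (default: all).
#' @return a `scenario_result` with one row per environment
#'   (`environment`, `n_genotypes`, `ability` = mean CV ability, `sd`);
#'   `$detail` holds the full `cv_result` per environment.
#' @export
scenario1_within_env <- function(trial, fes, sg = NULL,
                                 model = prediction_model(),
                                 cv = cv_config(), trait = NULL,
                                 environments = NULL) {
  envs <- environments %||% sort(unique(trial$plots$environment))
  detail <- list()
  rows <- lapply(envs, function(env) {
    sub <- subset_environment(trial, env)
    fd <- apply_fes(sub, fes, sg = sg, trait = trait)
    res <- cv_prediction_ability(fd, model = model, cv = cv)
    detail[[env]] <<- res
    data.frame(environment = env, n_genotypes = length(fd$y),
               ability = res$mean, sd = res$sd)
  })
  out <- scenario_result(1L, do.call(rbind, rows))
  out$detail <- detail
  out
}

#' Scenario 2: predict known genotypes in a new environment
#'
#' Trains on the genotype-level data of one environment and predicts the
#' performance of the same genotypes from the spectra obtained in
#' another environment.  One ability per ordered (train, test)
#' environment pair.  Wavelengths missing from either environment (e.g.
#' removed for singular fits) are dropped on both sides before fitting;
#' scaling statistics come from the training environment only.
#'
#' @inheritParams scenario1_within_env
#' @param pairs optional 2-column matrix/data.frame of (train, test)
#'   environment ids; default: all ordered pairs.
#' @param min_shared minimal number of shared genotypes per pair
#'   (default 3); pairs below it error.
#' @return a `scenario_result`, one row per pair (`train`, `test`,
#'   `n_shared`, `ability`).
#' @export
scenario2_cross_env <- function(trial, fes, sg = NULL,
                                model = prediction_model(), trait = NULL,
                                pairs = NULL, min_shared = 3) {
  envs <- sort(unique(trial$plots$environment))
  assert_that(length(envs) >= 2, "need at least two environments")
  if (is.null(pairs)) {
    pairs <- expand.grid(train = envs, test = envs,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$train != pairs$test, ]
  }
  fd <- lapply(setNames(envs, envs), function(env)
    apply_fes(subset_environment(trial, env), fes, sg = sg, trait = trait))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    shared <- intersect(fd[[a]]$genotypes, fd[[b]]$genotypes)
    assert_that(length(shared) >= min_shared,
                sprintf("environments %s and %s share %d genotype(s); need >= %d",
                        a, b, length(shared), min_shared),
                "phenosel_no_overlap")
    al <- align_features(fd[[a]]$X_raw, fd[[b]]$X_raw[shared, , drop = FALSE],
                         fes$use_scaling)
    pr <- fit_predict(model, al$train, fd[[a]]$y, al$test)
    data.frame(train = a, test = b, n_shared = length(shared),
               ability = safe_cor(pr, fd[[b]]$y[shared]))
  })
  scenario_result(2L, do.call(rbind, rows))
}

#' Scenario 3: predict new genotypes' series performance from one environment
#'
#' Trains on series-level genotype BLUEs (or means) of spectra and trait
#' from historical data, obtains the spectra of new genotypes in one
#' central environment, predicts their phenomic estimated performance
#' (PEP), and correlates the PEP with the new genotypes' series trait
#' BLUEs.  One ability per central environment.
#'
#' @param train_trial multi-environment [pheno_trial()] used for model
#'   training (series aggregation).
#' @param new_trial [pheno_trial()] of the new genotypes: spectra in the
#'   central environment(s) plus the trait observations from which their
#'   series BLUEs are computed.
#' @param central_env environment id(s) of `new_trial` serving as NIRS
#'   environment; default: all its environments in turn.
#' @inheritParams scenario1_within_env
#' @return a `scenario_result`, one row per central environment
#'   (`central_env`, `n_new`, `ability`).
#' @export
scenario3_series <- function(train_trial, new_trial, central_env = NULL,
                             fes = fes_config(8), sg = NULL,
                             model = prediction_model(), trait = NULL) {
  fd_tr <- apply_fes(train_trial, fes, sg = sg, trait = trait)
  trait <- fd_tr$trait
  overlap <- intersect(fd_tr$genotypes, unique(new_trial$plots$genotype))
  if (length(overlap))
    warning(sprintf("%d genotype(s) occur in both training and prediction sets",
                    length(overlap)))
  ## series trait BLUEs (or means) of the new genotypes
  unrep_series <- FALSE
  y_new <- if (fes$trait_aggregation == "blue" &&
               length(unique(new_trial$plots$environment)) >= 1) {
    variant <- if (length(unique(new_trial$plots$environment)) == 1)
      "within_environment" else "series"
    if (variant == "within_environment" &&
        max(table(new_trial$plots$genotype)) == 1) {
      unrep_series <- TRUE
      v <- setNames(new_trial$plots[[trait]], new_trial$plots$genotype)
      v[sort(names(v))]
    } else estimate_blues(new_trial$plots, trait, variant = variant,
                          compute_sed = FALSE)$blues
  } else {
    drop(genotype_mean(matrix(new_trial$plots[[trait]], ncol = 1),
                       new_trial$plots$genotype))
  }
  envs <- central_env %||% sort(unique(new_trial$plots$environment))
  rows <- lapply(envs, function(env) {
    sub <- subset_environment(new_trial, env)
    fd_new <- apply_fes(sub, fes, sg = sg, trait = trait)
    g <- intersect(fd_new$genotypes, names(y_new))
    assert_that(length(g) >= 3,
                "series trait BLUEs missing for the central-environment genotypes",
                "phenosel_missing_blues")
    al <- align_features(fd_tr$X_raw, fd_new$X_raw[g, , drop = FALSE],
                         fes$use_scaling)
    pep <- fit_predict(model, al$train, fd_tr$y, al$test)
    data.frame(central_env = env, n_new = length(g),
               ability = safe_cor(pep, y_new[g]))
  })
  scenario_result(3L, do.call(rbind, rows))
}
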