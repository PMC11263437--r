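## Genotype adjusted means (BLUEs), Cullis heritability and trait summaries.

## connectivity of the genotype x environment incidence (series model):
## environments are connected when they share at least one genotype
check_connected <- function(frame) {
  envs <- levels(frame$environment)
  if (length(envs) < 2) return(invisible(TRUE))
  parent <- seq_along(envs)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  tab <- table(frame$genotype, frame$environment) > 0
  for (g in seq_len(nrow(tab))) {
    idx <- which(tab[g, ])
    if (length(idx) > 1) {
      r <- find(idx[1])
      for (j in idx[-1]) parent[find(j)] <- r
    }
  }
  roots <- unique(vapply(seq_along(envs), find, integer(1)))
  assert_that(length(roots) == 1,
              "environments are disconnected: no genotype links them, genotype contrasts are inestimable",
              "phenosel_singular")
  invisible(TRUE)
}

## GLS genotype estimates at fixed variance components (cell-means X)
gls_blues <- function(frame, components, variant, compute_sed = TRUE) {
  X <- sparse.model.matrix(~ 0 + genotype, frame)
  n <- nrow(frame)
  V <- Diagonal(n, components[["sigma2_e"]])
  terms <- active_terms(frame, variant)
  keep <- names(terms)[components[names(terms)] > 0]
  for (nm in keep) {
    Z <- term_design(frame, terms[nm])[[1]]
    V <- V + components[[nm]] * tcrossprod(Z)
  }
  Vi_X <- solve(V, X)
  A <- as.matrix(crossprod(X, Vi_X))
  assert_that(kappa(A, exact = FALSE) < 1e10,
              "singular genotype fixed-effects system", "phenosel_singular")
  beta <- solve(A, as.numeric(crossprod(Vi_X, frame$.y)))
  C <- solve(A)
  list(blues = setNames(as.numeric(beta), levels(frame$genotype)),
       C = C, sed = if (compute_sed) mean_sed(C) else NA_real_)
}

#' Genotype BLUEs from the trial mixed model
#'
#' Estimates adjusted genotype means with genotype fixed and all design
#' effects random (REML variances via [fit_reml()] unless `varcomp`
#' supplies them), together with the mean standard error of a difference
#' (SED) across all pairwise genotype comparisons.
#'
#' When the response carries no within-genotype variation the model
#' degenerates and plain genotype means are returned with SED 0.
#'
#' @param records plot table or `pheno_trial`.
#' @param response response column name.
#' @param variant `"series"` (environment, replicate, block and GxE
#'   random) or `"within_environment"` (replicate and block random).
#' @param varcomp optional named variance components (`sigma2_*`); when
#'   given, BLUEs are a direct GLS solve at those variances and no REML
#'   fit is run.
#' @param compute_sed set `FALSE` to skip the pairwise SED (saves a dense
#'   covariance when only means are needed).
#' @return a `genotype_blues` list: `blues` (named vector), `sed`,
#'   `varcomp`, `converged`, `variant`.
#' @export
estimate_blues <- function(records, response,
                           variant = c("series", "within_environment"),
                           varcomp = NULL, compute_sed = TRUE) {
  variant <- match.arg(variant)
  d <- prepare_frame(records, response)
  if (variant == "series") check_connected(d)
  out <- structure(list(blues = NULL, sed = NA_real_, varcomp = NULL,
                        converged = TRUE, variant = variant,
                        dropped_wavelengths = character(0)),
                   class = "genotype_blues")
  ## degenerate noise-free case: response constant within genotype
  rng <- tapply(d$.y, d$genotype, function(v) diff(range(v)))
  if (all(rng <= 1e-10 * max(1, sd(d$.y)))) {
    mns <- tapply(d$.y, d$genotype, mean)[levels(d$genotype)]
    out$blues <- setNames(as.numeric(mns), levels(d$genotype))
    out$sed <- 0
    out$varcomp <- setNames(numeric(6), VC_NAMES)
    return(out)
  }
  if (!is.null(varcomp)) {
    comp <- setNames(numeric(6), VC_NAMES)
    comp[names(varcomp)] <- varcomp
    g <- gls_blues(d, comp, variant, compute_sed)
    out$blues <- g$blues; out$sed <- g$sed; out$varcomp <- comp
    return(out)
  }
  fit <- fit_reml(d, ".y", genotype_as = "fixed", variant = variant)
  assert_that(all(is.finite(fit$fixef)),
              "singular genotype fixed-effects system", "phenosel_singular")
  out$blues <- fit$fixef[levels(d$genotype)]
  out$varcomp <- fit$components
  out$converged <- fit$converged
  if (compute_sed) {
    C <- as.matrix(stats::vcov(fit$fit))
    assert_that(all(is.finite(C)) && kappa(C, exact = FALSE) < 1e10,
                "singular genotype fixed-effects system", "phenosel_singular")
    out$sed <- mean_sed(C)
  }
  out
}

#' Per-wavelength genotype BLUEs of plot spectra
#'
#' Applies the genotype-fixed mixed model of [estimate_blues()] to every
#' wavelength column.  The model structure is fitted once and refitted
#' per column for speed.  Wavelengths whose fit is singular or does not
#' converge are removed from the output entirely (for all environments),
#' and listed in `dropped_wavelengths`.
#'
#' For a single-environment table in which no genotype is replicated the
#' mixed model is unavailable and the raw plot spectra are passed through
#' as genotype rows (`fallback = TRUE`), matching the handling of
#' unreplicated yield-trial environments.
#'
#' @param spectra plot-level spectra matrix (row names = plot ids).
#' @param records plot table or `pheno_trial` (only design columns used).
#' @param variant as in [estimate_blues()].
#' @return list with `blues` (genotype x wavelength matrix),
#'   `dropped_wavelengths`, `fallback`.
#' @export
spectra_blues <- function(spectra, records,
                          variant = c("series", "within_environment")) {
  variant <- match.arg(variant)
  if (inherits(records, "pheno_trial")) records <- records$plots
  spectra <- as.matrix(spectra)
  assert_that(setequal(rownames(spectra), records$plot_id),
              "spectra rows must match the plot table")
  spectra <- spectra[records$plot_id, , drop = FALSE]
  d <- prepare_frame(cbind(records, .tmp = spectra[, 1]), ".tmp")
  if (variant == "series") check_connected(d)

  ## unreplicated single environment: raw spectra stand in for BLUEs
  if (variant == "within_environment" &&
      max(table(d$genotype)) == 1L) {
    out <- spectra
    rownames(out) <- as.character(d$genotype)
    out <- out[order(rownames(out)), , drop = FALSE]
    return(list(blues = out, dropped_wavelengths = character(0),
                fallback = TRUE))
  }

  gl <- levels(d$genotype)
  res <- matrix(NA_real_, length(gl), ncol(spectra),
                dimnames = list(gl, colnames(spectra)))
  dropped <- character(0)
  fit0 <- NULL
  fml <- NULL
  sdy_all <- apply(spectra, 2, sd)
  for (j in seq_len(ncol(spectra))) {
    y <- spectra[, j]
    rng <- tapply(y, d$genotype, function(v) diff(range(v)))
    if (all(rng <= 1e-10 * max(1, sdy_all[j]))) {
      res[, j] <- tapply(y, d$genotype, mean)[gl]
      next
    }
    d$.y <- y
    ok <- TRUE
    msgs <- character()
    fe <- tryCatch({
      if (is.null(fit0)) {
        terms <- active_terms(d, variant)
        fml <- stats::as.formula(paste(".y ~ 0 + genotype +",
          paste(sprintf("(1 | %s)", terms), collapse = " + ")))
        fr <- lmer_quiet(fml, d)
        msgs <- fr$messages
        fit0 <- fr$fit
        lme4::fixef(fit0)
      } else {
        f <- withCallingHandlers(lme4::refit(fit0, newresp = y),
          warning = function(w) {
            msgs <<- c(msgs, conditionMessage(w))
            invokeRestart("muffleWarning")
          },
          message = function(m) {
            msgs <<- c(msgs, conditionMessage(m))
            invokeRestart("muffleMessage")
          })
        lme4::fixef(f)
      }
    }, error = function(e) { ok <<- FALSE; NULL })
    if (!ok || any(!is.finite(fe)) ||
        any(grepl("failed to converge", msgs))) {
      dropped <- c(dropped, colnames(spectra)[j])
      next
    }
    res[, j] <- setNames(unname(fe), sub("^genotype", "", names(fe)))[gl]
  }
  keep <- setdiff(colnames(spectra), dropped)
  list(blues = res[, keep, drop = FALSE], dropped_wavelengths = dropped,
       fallback = FALSE)
}

#' Cullis heritability from an all-random fit
#'
#' Computes the broad-sense heritability suited to unbalanced trials,
#' \deqn{H^2 = 1 - \bar\vartheta_{BLUP} / (2\sigma^2_g),}
#' where \eqn{\bar\vartheta_{BLUP}} is the mean prediction-error variance
#' of a difference of two genotype BLUPs.  The PEV matrix is obtained
#' exactly from the mixed-model equations at the REML variance estimates.
#'
#' @param fit a `reml_fit` with `genotype_as = "random"`.
#' @return the heritability (scalar in \[0, 1\]); attributes
#'   `vartheta_bar` and `clamped`.  Values outside \[0, 1\] are clamped
#'   with a warning.
#' @export
cullis_h2 <- function(fit) {
  assert_that(inherits(fit, "reml_fit") && fit$genotype_as == "random",
              "fit must come from fit_reml(..., genotype_as = 'random')")
  assert_that(fit$components[["sigma2_g"]] > 0,
              "heritability undefined: sigma2_g = 0", "phenosel_undefined_h2")
  bp <- blup_pev(fit$frame, fit$components, fit$variant)
  vbar <- mean_pair_pev(bp$pev)
  h2 <- 1 - vbar / (2 * fit$components[["sigma2_g"]])
  clamped <- h2 < 0 || h2 > 1
  if (clamped) {
    warning("Cullis H2 outside [0, 1]; clamped")
    h2 <- min(max(h2, 0), 1)
  }
  structure(h2, vartheta_bar = vbar, clamped = clamped)
}

#' Summary statistics of a trait across a trial series
#'
#' Reports the descriptive statistics breeders tabulate per dataset:
#' minimum, mean and maximum of the genotype BLUEs, the mean SED, the
#' genotype / GxE / residual variance components of the all-random model
#' and the Cullis heritability.
#'
#' @param records plot table or `pheno_trial`.
#' @param response trait column name.
#' @return one-row data.frame with columns `trait`, `n_genotypes`,
#'   `n_environments`, `min`, `mean`, `max`, `sed`, `sigma2_g`,
#'   `sigma2_gl`, `sigma2_e`, `h2`.
#' @export
summarize_trait <- function(records, response) {
  d <- prepare_frame(records, response)
  bl <- estimate_blues(records, response, variant = "series")
  fr <- fit_reml(records, response, genotype_as = "random", variant = "series")
  h2 <- if (fr$components[["sigma2_g"]] > 0) as.numeric(cullis_h2(fr))
        else NA_real_
  data.frame(trait = response,
             n_genotypes = nlevels(d$genotype),
             n_environments = nlevels(d$environment),
             min = min(bl$blues), mean = mean(bl$blues), max = max(bl$blues),
             sed = bl$sed,
             sigma2_g = fr$components[["sigma2_g"]],
             sigma2_gl = fr$components[["sigma2_gl"]],
             sigma2_e = fr$components[["sigma2_e"]],
             h2 = h2, row.names = NULL)
}
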