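## REML machinery for the multi-environment trial model
##   y = mu + g + l + r(l) + b(r) + g:l + e
## Variance components are estimated with lme4 (the REML engine); GLS
## estimates with fixed variances, the restricted log-likelihood and BLUP
## prediction-error variances are computed directly in this file.

VC_NAMES <- c("sigma2_g", "sigma2_l", "sigma2_r", "sigma2_b",
              "sigma2_gl", "sigma2_e")

## records -> model frame with nested grouping factors
prepare_frame <- function(records, response) {
  if (inherits(records, "pheno_trial")) records <- records$plots
  assert_that(is.data.frame(records), "records must be a data.frame or pheno_trial")
  assert_that(response %in% names(records),
              paste("response column not found:", response))
  y <- records[[response]]
  assert_that(all(is.finite(y)), "response must be finite")
  d <- data.frame(.y = y,
                  genotype = factor(records$genotype),
                  environment = factor(records$environment),
                  stringsAsFactors = FALSE)
  rep0 <- if (is.null(records$replicate)) "R1" else records$replicate
  blk0 <- if (is.null(records$block)) "B1" else records$block
  d$env_rep <- factor(paste(d$environment, rep0, sep = "/"))
  d$env_rep_block <- factor(paste(d$environment, rep0, blk0, sep = "/"))
  d$gen_env <- factor(paste(d$genotype, d$environment, sep = "/"))
  assert_that(nlevels(d$genotype) >= 2, "need at least 2 genotypes")
  d
}

## which random terms are identifiable for a given variant
active_terms <- function(frame, variant) {
  nl <- function(f) nlevels(frame[[f]])
  if (variant == "series") {
    terms <- c(sigma2_l = "environment", sigma2_r = "env_rep",
               sigma2_b = "env_rep_block", sigma2_gl = "gen_env")
    keep <- c(nl("environment") >= 2,
              nl("env_rep") > nl("environment"),
              nl("env_rep_block") > nl("env_rep"),
              nl("environment") >= 2)
  } else {
    assert_that(nl("environment") == 1,
                "within_environment variant requires a single environment")
    terms <- c(sigma2_r = "env_rep", sigma2_b = "env_rep_block")
    keep <- c(nl("env_rep") >= 2, nl("env_rep_block") > nl("env_rep"))
  }
  terms[keep]
}

lmer_quiet <- function(formula, data) {
  ctrl <- lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.rankZ = "ignore",
                            check.nobs.vs.nRE = "ignore",
                            calc.derivs = FALSE)
  msgs <- character()
  fit <- withCallingHandlers(
    lme4::lmer(formula, data = data, REML = TRUE, control = ctrl),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
    },
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  list(fit = fit, messages = msgs)
}

#' Fit the trial linear mixed model by REML
#'
#' Fits the series model (genotype, environment, replicate-in-environment,
#' block-in-replicate, genotype-by-environment, residual) or its
#' within-environment reduction (replicate, block, residual) to a plot
#' table.  Genotype enters either as a random effect (variance
#' components, BLUPs, heritability) or as a fixed effect (BLUEs).  Terms
#' that are structurally unidentifiable for the given layout (e.g. a
#' replicate term when every environment has one replicate) are dropped
#' and reported with variance 0.
#'
#' @param records a `pheno_trial` or plot table data.frame.
#' @param response name of the response column.
#' @param genotype_as `"random"` or `"fixed"`.
#' @param variant `"series"` (the full model) or `"within_environment"`.
#' @return a `reml_fit` list with `components` (all six variances, zeros
#'   for dropped/boundary terms), `boundary` and `included` flags,
#'   `converged`, `loglik`, fixed-effect estimates and the fitted lme4
#'   model (when one was needed).
#' @export
fit_reml <- function(records, response, genotype_as = c("random", "fixed"),
                     variant = c("series", "within_environment")) {
  genotype_as <- match.arg(genotype_as)
  variant <- match.arg(variant)
  d <- prepare_frame(records, response)
  comp <- setNames(numeric(6), VC_NAMES)
  included <- setNames(logical(6), VC_NAMES)
  included["sigma2_e"] <- TRUE
  res <- list(components = comp, included = included,
              boundary = setNames(logical(6), VC_NAMES),
              converged = TRUE, loglik = NA_real_, messages = character(),
              frame = d, response = response, genotype_as = genotype_as,
              variant = variant, fit = NULL, fixef = NULL, mu = NA_real_)
  class(res) <- "reml_fit"

  sdy <- sd(d$.y)
  if (sdy == 0) {                     # constant response: everything zero
    res$mu <- d$.y[1]
    if (genotype_as == "fixed")
      res$fixef <- setNames(rep(d$.y[1], nlevels(d$genotype)),
                            levels(d$genotype))
    return(res)
  }

  terms <- active_terms(d, variant)
  if (genotype_as == "random") terms <- c(sigma2_g = "genotype", terms)
  res$included[names(terms)] <- TRUE
  fixed <- if (genotype_as == "fixed") ".y ~ 0 + genotype" else ".y ~ 1"

  if (length(terms) == 0) {           # no random terms left: plain LS
    fit <- lm(stats::as.formula(fixed), data = d)
    res$components["sigma2_e"] <- summary(fit)$sigma^2
    res$loglik <- as.numeric(stats::logLik(fit))
    if (genotype_as == "fixed") {
      res$fixef <- setNames(coef(fit), levels(d$genotype))
    } else res$mu <- coef(fit)[1]
    res$fit <- fit
    return(res)
  }

  fml <- stats::as.formula(paste(fixed, "+",
    paste(sprintf("(1 | %s)", terms), collapse = " + ")))
  fr <- lmer_quiet(fml, d)
  fit <- fr$fit
  vc <- as.data.frame(lme4::VarCorr(fit))
  est <- setNames(vc$vcov, vc$grp)
  for (nm in names(terms)) res$components[nm] <- est[[terms[nm]]]
  res$components["sigma2_e"] <- est[["Residual"]]
  tol <- (1e-6 * sdy)^2
  res$boundary[VC_NAMES] <- res$included & res$components < tol
  res$components[res$boundary] <- 0
  res$messages <- fr$messages
  res$converged <- !any(grepl("failed to converge", fr$messages))
  res$loglik <- as.numeric(stats::logLik(fit))
  if (genotype_as == "fixed") {
    fe <- lme4::fixef(fit)
    res$fixef <- setNames(unname(fe), sub("^genotype", "", names(fe)))
  } else {
    res$mu <- unname(lme4::fixef(fit)[1])
  }
  res$fit <- fit
  res
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("reml_fit (%s, genotype %s): logLik %.3f%s\n", x$variant,
              x$genotype_as, x$loglik,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(round(x$components[x$included], 6))
  invisible(x)
}

## design matrices (dense response order) for included random terms
term_design <- function(frame, terms) {
  lapply(terms, function(f)
    sparse.model.matrix(stats::as.formula(paste("~ 0 +", f)), frame))
}

## dense covariance matrix V for given components (small-data paths only)
build_V <- function(frame, components, variant) {
  terms <- active_terms(frame, variant)
  keep <- names(terms)[components[names(terms)] > 0]
  V <- diag(components[["sigma2_e"]], nrow(frame))
  for (nm in keep) {
    Z <- as.matrix(term_design(frame, terms[nm])[[1]])
    V <- V + components[[nm]] * tcrossprod(Z)
  }
  if (!is.null(components[["sigma2_g"]]) && components[["sigma2_g"]] > 0) {
    Zg <- model.matrix(~ 0 + genotype, frame)
    V <- V + components[["sigma2_g"]] * tcrossprod(Zg)
  }
  V
}

#' Restricted log-likelihood at fixed variance components
#'
#' Direct dense evaluation of the REML criterion
#' \deqn{\ell_R = -\tfrac12\{(n-p)\log 2\pi + \log|V| + \log|X'V^{-1}X| +
#'   r'V^{-1}r\}} for a given set of variance components, where `X` is the
#' fixed-effect design and `r` the GLS residual.  Intended for small data
#' (brute-force grid checks of the optimizer); O(n^3).
#'
#' @param records plot table or `pheno_trial`.
#' @param response response column name.
#' @param components named vector using the `sigma2_*` names; genotype is
#'   included via `sigma2_g` when `genotype_as = "random"`.
#' @param genotype_as,variant as in [fit_reml()].
#' @return the restricted log-likelihood (scalar).
#' @export
reml_loglik <- function(records, response, components,
                        genotype_as = c("random", "fixed"),
                        variant = c("series", "within_environment")) {
  genotype_as <- match.arg(genotype_as)
  variant <- match.arg(variant)
  d <- prepare_frame(records, response)
  full <- setNames(numeric(6), VC_NAMES)
  full[names(components)] <- components
  if (genotype_as == "fixed") full["sigma2_g"] <- 0
  V <- build_V(d, if (genotype_as == "fixed")
    full[setdiff(VC_NAMES, "sigma2_g")] else full, variant)
  X <- if (genotype_as == "fixed") model.matrix(~ 0 + genotype, d)
       else matrix(1, nrow(d), 1)
  y <- d$.y
  n <- length(y); p <- ncol(X)
  cV <- chol(V)
  Vi_y <- backsolve(cV, forwardsolve(t(cV), y))
  Vi_X <- backsolve(cV, forwardsolve(t(cV), X))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(X, Vi_y))
  r <- y - X %*% beta
  Vi_r <- backsolve(cV, forwardsolve(t(cV), r))
  ld_V <- 2 * sum(log(diag(cV)))
  ld_X <- determinant(XtViX, logarithm = TRUE)$modulus
  -0.5 * ((n - p) * log(2 * pi) + ld_V + as.numeric(ld_X) +
            sum(r * Vi_r))
}

## BLUPs of all random effects and the genotype prediction-error variance
## matrix, from the mixed-model equations at fixed variance components.
## Returns list(blup_g, pev) with pev the n_g x n_g PEV matrix.
blup_pev <- function(frame, components, variant = "series",
                     max_exact = 2000L) {
  assert_that(components[["sigma2_g"]] > 0,
              "sigma2_g must be > 0", "phenosel_undefined_h2")
  terms <- active_terms(frame, variant)
  keep <- names(terms)[components[names(terms)] > 0]
  Zg <- sparse.model.matrix(~ 0 + genotype, frame)
  Zs <- c(list(sigma2_g = Zg), term_design(frame, terms[keep]))
  vars <- components[names(Zs)]
  sig_e <- components[["sigma2_e"]]
  ng <- ncol(Zg)
  if (sig_e <= 1e-12 * components[["sigma2_g"]]) {
    ## noise-free limit: BLUPs exact, PEV -> 0
    return(list(blup_g = setNames(rep(NA_real_, ng), colnames(Zg)),
                pev = matrix(0, ng, ng)))
  }
  Z <- do.call(cbind, Zs)
  X <- Matrix(1, nrow(frame), 1)
  Ginv_d <- unlist(lapply(seq_along(Zs),
                          function(k) rep(sig_e / vars[k], ncol(Zs[[k]]))))
  M <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + Diagonal(x = Ginv_d)))
  y <- frame$.y
  rhs <- rbind(crossprod(X, y), crossprod(Z, y))
  sol <- solve(M, rhs)
  u_g <- as.numeric(sol[1 + seq_len(ng), 1])
  ## genotype block of sigma_e^2 * M^{-1}
  E <- Matrix(0, nrow(M), ng, sparse = TRUE)
  E[cbind(1 + seq_len(ng), seq_len(ng))] <- 1
  Minv_g <- solve(M, E)
  pev <- sig_e * as.matrix(Minv_g[1 + seq_len(ng), , drop = FALSE])
  pev <- (pev + t(pev)) / 2
  list(blup_g = setNames(u_g, sub("^genotype", "", colnames(Zg))), pev = pev)
}
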