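#' Fit ridge-regression BLUP with REML shrinkage
#'
#' Fits \eqn{y = 1\mu + Zu + \epsilon} with \eqn{u \sim N(0, I\sigma^2_u)}
#' and \eqn{\epsilon \sim N(0, I\sigma^2_\epsilon)}.  The two variances
#' are estimated by REML through a single spectral decomposition of the
#' feature kernel \eqn{ZZ'}, so the likelihood is maximized in one
#' dimension (Brent search on \eqn{\log\lambda}, tolerance 1e-8), and the
#' effects solve the ridge system
#' \deqn{\hat u = (Z'Z + \lambda I)^{-1} Z' (y - 1\hat\mu), \qquad
#'   \lambda = \hat\sigma^2_\epsilon / \hat\sigma^2_u.}
#' The kernel (dual) form is used throughout, which is identical to the
#' primal solution and cheap when features far outnumber samples.
#'
#' @param X genotype x feature matrix (the `Z` of the model).
#' @param y response vector (one value per row of `X`).
#' @param lambda optional fixed shrinkage; skips the REML search
#'   (`lambda = 0` gives the least-squares limit).
#' @return an `rrblup_model`: `intercept`, `u` (named effect vector),
#'   `lambda`, `sigma2_u`, `sigma2_e`, `features`, `degenerate` flag.
#' @export
fit_rrblup <- function(X, y, lambda = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- nrow(X)
  assert_that(n >= 3, "need at least 3 training rows")
  assert_that(length(y) == n, "y must match rows of X")
  assert_that(!anyNA(X) && !anyNA(y), "missing values are not allowed")
  mk <- function(intercept, u, lambda, s2u, s2e, degenerate = FALSE)
    structure(list(intercept = intercept,
                   u = setNames(as.numeric(u), colnames(X)),
                   lambda = lambda, sigma2_u = s2u, sigma2_e = s2e,
                   features = colnames(X), degenerate = degenerate),
              class = "rrblup_model")
  if (sd(y) == 0) {
    warning("response has zero variance: degenerate rrBLUP model (u = 0)")
    return(mk(y[1], numeric(ncol(X)), Inf, 0, 0, degenerate = TRUE))
  }
  K <- tcrossprod(X)
  if (is.null(lambda)) {
    ## REML profile over delta = sigma2_e / sigma2_u on the projected
    ## kernel (intercept swept out), EMMA-style
    yc <- y - mean(y)
    Kc <- sweep(K, 1, rowMeans(K))
    Kc <- sweep(Kc, 2, colMeans(Kc))
    e <- eigen(Kc, symmetric = TRUE)
    theta <- pmax(e$values[seq_len(n - 1)], 0)
    eta <- crossprod(e$vectors[, seq_len(n - 1), drop = FALSE], yc)[, 1]
    nll <- function(ldelta) {
      delta <- exp(ldelta)
      s2u <- sum(eta^2 / (theta + delta)) / (n - 1)
      (n - 1) * log(s2u) + sum(log(theta + delta))
    }
    opt <- optimize(nll, interval = c(-25, 25), tol = 1e-8)
    lambda <- exp(opt$minimum)
    s2u <- sum(eta^2 / (theta + lambda)) / (n - 1)
    s2e <- lambda * s2u
  } else {
    assert_that(lambda >= 0, "lambda must be >= 0")
    s2u <- NA_real_; s2e <- NA_real_
  }
  one <- rep(1, n)
  if (ncol(X) <= n) {
    ## primal: joint normal equations, intercept unpenalized
    p <- ncol(X)
    M <- rbind(c(n, colSums(X)),
               cbind(colSums(X), crossprod(X) + diag(lambda, p)))
    b <- solve(M, c(sum(y), crossprod(X, y)))
    mu <- unname(b[1]); u <- b[-1]
  } else {
    ## dual (kernel) form: identical solution, O(n^3)
    H <- K + diag(lambda, n)
    Hi_y <- solve(H, y)
    Hi_1 <- solve(H, one)
    mu <- sum(one * Hi_y) / sum(one * Hi_1)
    u <- crossprod(X, solve(H, y - mu * one))
  }
  mk(mu, u, lambda, s2u, s2e)
}

#' Predict from an rrBLUP model
#'
#' \eqn{\hat y = \mu + X_{new}\hat u}.  Feature columns are matched by
#' name: a permuted column order is realigned, a different feature set is
#' an error.
#'
#' @param object an `rrblup_model`.
#' @param newdata matrix of new feature rows.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.rrblup_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    assert_that(setequal(colnames(newdata), object$features),
                "feature set of newdata does not match the training features",
                "phenosel_feature_mismatch")
    newdata <- newdata[, object$features, drop = FALSE]
  } else {
    assert_that(ncol(newdata) == length(object$features),
                "newdata has the wrong number of features",
                "phenosel_feature_mismatch")
  }
  drop(object$intercept + newdata %*% object$u)
}

#' @export
print.rrblup_model <- function(x, ...) {
  cat(sprintf("rrBLUP model: %d features, lambda = %.4g%s\n",
              length(x$u), x$lambda,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
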