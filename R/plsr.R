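#' Fit univariate partial least squares regression (NIPALS)
#'
#' Deterministic NIPALS recursion on column-centered `X` and centered
#' `y`: each component's weight vector is the normalized covariance
#' `X'y`, scores are projected out of both `X` and `y`, and the
#' regression coefficients are assembled as
#' \eqn{\beta = W (P'W)^{-1} q}.  The requested number of components is
#' capped at the effective rank with a warning.
#'
#' @param X sample x feature matrix.
#' @param y response vector.
#' @param n_components latent components to extract (default 12, the
#'   usual choice for grain NIRS).
#' @return a `plsr_model`: coefficients, centering vectors, weight /
#'   loading matrices and `n_components` actually used.
#' @export
fit_plsr <- function(X, y, n_components = 12) {
  assert_that(n_components >= 1, "n_components must be >= 1")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  assert_that(length(y) == n, "y must match rows of X")
  A <- min(n_components, n - 1L, p)
  mx <- colMeans(X); my <- mean(y)
  E <- sweep(X, 2, mx); f <- y - my
  W <- P <- matrix(0, p, A)
  q <- numeric(A)
  tol <- 1e-12 * max(1, sum(E^2))
  a <- 0L
  for (k in seq_len(A)) {
    w <- crossprod(E, f)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw^2 <= tol) break
    w <- w / nw
    t_ <- E %*% w
    tt <- sum(t_^2)
    if (tt <= tol) break
    pk <- crossprod(E, t_)[, 1] / tt
    qk <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, pk)
    f <- f - qk * t_
    a <- k
    W[, k] <- w; P[, k] <- pk; q[k] <- qk
  }
  if (a < n_components)
    warning(sprintf("n_components capped at %d (rank / signal exhausted)", a))
  assert_that(a >= 1, "no usable PLS component (X'y is zero)")
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  q <- q[seq_len(a)]
  beta <- W %*% solve(crossprod(P, W), q)
  structure(list(coefficients = setNames(as.numeric(beta), colnames(X)),
                 intercept = my - sum(mx * beta),
                 x_center = mx, y_center = my,
                 weights = W, loadings = P, y_loadings = q,
                 n_components = a, features = colnames(X)),
            class = "plsr_model")
}

## coefficients truncated to the first `ncomp` components
plsr_coef <- function(model, ncomp) {
  ncomp <- min(ncomp, model$n_components)
  W <- model$weights[, seq_len(ncomp), drop = FALSE]
  P <- model$loadings[, seq_len(ncomp), drop = FALSE]
  beta <- W %*% solve(crossprod(P, W), model$y_loadings[seq_len(ncomp)])
  list(beta = as.numeric(beta),
       intercept = model$y_center - sum(model$x_center * beta))
}

#' Predict from a PLSR model
#'
#' @param object a `plsr_model`.
#' @param newdata matrix of new feature rows (matched to training
#'   features by name when named).
#' @param ncomp optionally predict with fewer components than fitted.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.plsr_model <- function(object, newdata, ncomp = NULL, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    assert_that(setequal(colnames(newdata), object$features),
                "feature set of newdata does not match the training features",
                "phenosel_feature_mismatch")
    newdata <- newdata[, object$features, drop = FALSE]
  }
  cf <- if (is.null(ncomp))
    list(beta = as.numeric(object$coefficients), intercept = object$intercept)
  else plsr_coef(object, ncomp)
  drop(cf$intercept + newdata %*% cf$beta)
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("PLSR model: %d features, %d components\n",
              length(x$coefficients), x$n_components))
  invisible(x)
}

#' Choose the PLSR component count by cross-validated RMSEP
#'
#' Repeated k-fold cross-validation of the root mean squared error of
#' prediction for 1..`max_components` components, then the one-standard-
#' error parsimony rule: the smallest count whose mean RMSEP is within
#' one standard error of the minimum.
#'
#' @param X,y training data.
#' @param max_components largest count to consider.
#' @param k folds (default 5).
#' @param n_replicates CV repetitions (default 10).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return the selected component count; attribute `rmsep` carries the
#'   mean/SE table.
#' @export
select_plsr_components <- function(X, y, max_components = 12, k = 5,
                                   n_replicates = 10, seed = 1) {
  assert_that(max_components >= 1, "max_components must be >= 1")
  X <- as.matrix(X); n <- nrow(X)
  assert_that(n >= k, "fewer samples than folds")
  with_seed(seed, {
    cells <- list()
    for (r in seq_len(n_replicates)) {
      fold <- make_folds(n, k)
      for (f in seq_len(k)) {
        te <- which(fold == f); tr <- setdiff(seq_len(n), te)
        m <- suppressWarnings(fit_plsr(X[tr, , drop = FALSE], y[tr],
                                       max_components))
        errs <- vapply(seq_len(m$n_components), function(a) {
          pr <- predict(m, X[te, , drop = FALSE], ncomp = a)
          sqrt(mean((pr - y[te])^2))
        }, numeric(1))
        cells[[length(cells) + 1L]] <-
          c(errs, rep(NA_real_, max_components - length(errs)))
      }
    }
    M <- do.call(rbind, cells)
    mean_r <- colMeans(M, na.rm = TRUE)
    se_r <- apply(M, 2, function(v) sd(v, na.rm = TRUE) /
                    sqrt(sum(is.finite(v))))
    ok <- which(is.finite(mean_r))
    amin <- ok[which.min(mean_r[ok])]
    thr <- mean_r[amin] + se_r[amin]
    sel <- min(ok[mean_r[ok] <= thr])
    structure(sel, rmsep = data.frame(ncomp = seq_len(max_components),
                                      rmsep = mean_r, se = se_r))
  })
}
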