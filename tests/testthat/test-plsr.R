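test_that("rank-1 signal is captured by one component", {
  set.seed(1)
  t_ <- rnorm(20)
  X <- outer(t_, rnorm(6))              # rank-1 predictor matrix
  y <- drop(X %*% rnorm(6))
  m <- suppressWarnings(fit_plsr(X, y, n_components = 1))
  expect_lt(max(abs(predict(m, X) - y)), 1e-10)
})

test_that("coefficients match an independently coded NIPALS oracle", {
  set.seed(2)
  X <- matrix(rnorm(9 * 6), 9, 6)
  y <- rnorm(9)
  for (A in c(1, 3, 5)) {
    m <- fit_plsr(X, y, n_components = A)
    # oracle: score/loading recursion accumulating T, then regression of y
    # on the orthogonal scores, mapped back through R = W(P'W)^-1
    E <- scale(X, scale = FALSE); f <- y - mean(y)
    Tm <- NULL; Wm <- NULL; Pm <- NULL
    for (a in seq_len(A)) {
      w <- drop(crossprod(E, f)); w <- w / sqrt(sum(w * w))
      t_ <- drop(E %*% w)
      p_ <- drop(crossprod(E, t_)) / sum(t_ * t_)
      Tm <- cbind(Tm, t_); Wm <- cbind(Wm, w); Pm <- cbind(Pm, p_)
      f <- f - t_ * sum(f * t_) / sum(t_ * t_)
      E <- E - tcrossprod(t_, p_)
    }
    q <- drop(solve(crossprod(Tm), crossprod(Tm, y - mean(y))))
    beta <- drop(Wm %*% solve(crossprod(Pm, Wm), q))
    expect_equal(unname(m$coefficients), beta, tolerance = 1e-8)
    expect_equal(m$n_components, A)
  }
})

test_that("component count is capped at the rank with a warning", {
  set.seed(3)
  X <- matrix(rnorm(6 * 10), 6, 10)
  y <- rnorm(6)
  expect_warning(m <- fit_plsr(X, y, n_components = 12), "capped")
  expect_lte(m$n_components, 5)
})

test_that("full-component PLSR reproduces OLS on tall full-rank X", {
  set.seed(4)
  X <- matrix(rnorm(40 * 5), 40, 5)
  y <- rnorm(40)
  m <- fit_plsr(X, y, n_components = 5)
  ols <- lm(y ~ X)
  expect_equal(unname(predict(m, X)), unname(fitted(ols)), tolerance = 1e-8)
})

test_that("component selection: parsimony under noise, recovery of signal", {
  set.seed(5)
  # pure noise: the one-sigma rule picks the most parsimonious model
  Xn <- matrix(rnorm(60 * 30), 60, 30)
  yn <- rnorm(60)
  sel_n <- select_plsr_components(Xn, yn, max_components = 8, seed = 11)
  expect_equal(as.integer(sel_n), 1L)
  # strong 3-factor signal: about 3 components chosen (within +-1)
  hits <- vapply(1:5, function(s) {
    set.seed(100 + s)
    Tm <- matrix(rnorm(200 * 3), 200, 3)
    X <- Tm %*% matrix(rnorm(3 * 40), 3, 40) +
      matrix(rnorm(200 * 40, sd = 0.1), 200, 40)
    y <- drop(Tm %*% c(2, -1.5, 1)) + rnorm(200, sd = 0.3)
    as.integer(select_plsr_components(X, y, max_components = 8, seed = s))
  }, integer(1))
  expect_true(all(abs(hits - 3) <= 1))
  # deterministic given the seed
  expect_identical(as.integer(select_plsr_components(Xn, yn, 6, seed = 2)),
                   as.integer(select_plsr_components(Xn, yn, 6, seed = 2)))
})
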