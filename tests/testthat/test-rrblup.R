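test_that("degenerate and limiting cases", {
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_warning(m <- fit_rrblup(X, rep(2, 10)), "zero variance")
  expect_true(m$degenerate)
  expect_equal(unname(m$u), c(0, 0, 0))
  expect_equal(m$intercept, 2)
  # single feature, lambda forced to 0: OLS limit
  z <- matrix(c(-1, 0, 1), dimnames = list(NULL, "z"))
  m0 <- fit_rrblup(z, c(-1, 0, 1), lambda = 0)
  expect_equal(unname(m0$u), 1, tolerance = 1e-12)
  expect_equal(m0$intercept, 0, tolerance = 1e-12)
})

test_that("primal and dual ridge solutions are identical", {
  set.seed(4)
  for (dims in list(c(8, 50), c(12, 120))) {
    Z <- matrix(rnorm(prod(dims)), dims[1])
    colnames(Z) <- paste0("f", seq_len(dims[2]))
    y <- rnorm(dims[1])
    m <- fit_rrblup(Z, y)                       # dual path (p > n)
    u_primal <- solve(crossprod(Z) + diag(m$lambda, ncol(Z)),
                      crossprod(Z, y - m$intercept))
    expect_equal(unname(m$u), unname(drop(u_primal)), tolerance = 1e-10)
  }
})

test_that("predictions respect feature alignment and affine structure", {
  set.seed(5)
  X <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("f", 1:10)))
  y <- drop(X %*% rnorm(10)) + rnorm(20, sd = 0.1)
  m <- fit_rrblup(X, y)
  # training rows reproduce the fitted values; zero row gives the intercept
  expect_equal(predict(m, X), drop(m$intercept + X %*% m$u))
  expect_equal(unname(predict(m, matrix(0, 1, 10,
                                        dimnames = list(NULL, paste0("f", 1:10))))),
               m$intercept)
  # permuted feature columns are realigned by name
  perm <- sample(10)
  expect_equal(predict(m, X[, perm]), predict(m, X))
  # wrong feature set errors
  X2 <- X; colnames(X2)[1] <- "other"
  expect_error(predict(m, X2), class = "phenosel_feature_mismatch")
  # adding a constant to y shifts predictions by the same constant
  m2 <- fit_rrblup(X, y + 7)
  expect_equal(predict(m2, X), predict(m, X) + 7, tolerance = 1e-6)
})

test_that("effect norm decreases monotonically in lambda", {
  set.seed(6)
  X <- matrix(rnorm(15 * 40), 15)
  y <- rnorm(15)
  norms <- vapply(c(0.01, 1, 100, 1e4), function(l)
    sqrt(sum(fit_rrblup(X, y, lambda = l)$u^2)), numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("REML lambda matches a dense grid-search oracle", {
  set.seed(9)
  Z <- matrix(rnorm(30 * 200), 30)
  u <- rnorm(200, sd = 0.1)
  y <- drop(Z %*% u) + rnorm(30, sd = 0.5)
  m <- fit_rrblup(Z, y)
  # oracle: restricted likelihood of (mu, delta) from first principles
  ll <- function(delta) {
    V <- tcrossprod(Z) + diag(delta, 30)   # proportional to the true V
    X <- matrix(1, 30, 1)
    Vi <- solve(V)
    A <- drop(t(X) %*% Vi %*% X)
    mu <- drop(t(X) %*% Vi %*% y) / A
    r <- y - mu
    s2u <- drop(t(r) %*% Vi %*% r) / (30 - 1)
    -0.5 * ((30 - 1) * log(s2u) + determinant(V)$modulus + log(A))
  }
  lgrid <- exp(seq(log(m$lambda) - 3, log(m$lambda) + 3, length.out = 400))
  best <- lgrid[which.max(vapply(lgrid, ll, numeric(1)))]
  expect_equal(m$lambda, best, tolerance = 0.02)
})
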