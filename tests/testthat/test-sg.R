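test_that("parameter validation", {
  expect_error(sg_params(2, 1, 28), class = "phenosel_sg_params")
  expect_error(sg_params(2, 3, 29), class = "phenosel_sg_params")
  expect_error(sg_params(31, 1, 29), class = "phenosel_sg_params")
  expect_error(savitzky_golay(matrix(rnorm(20), 1), sg_params(2, 1, 29)),
               class = "phenosel_sg_params")
})

test_that("the default grid enumerates all 42 combinations, parsimony-ordered", {
  g <- sg_grid()
  expect_length(g, 42)
  key <- vapply(g, format, character(1))
  expect_false(anyDuplicated(key) > 0)
  expect_identical(unclass(g[[1]])[c("p", "d", "w")],
                   list(p = 2L, d = 1L, w = 29L))
  d_seq <- vapply(g, `[[`, integer(1), "d")
  expect_true(!is.unsorted(d_seq))
})

test_that("polynomial inputs are differentiated exactly", {
  wl <- 1300:1400
  # constant, derivative 1 -> zero
  expect_equal(max(abs(savitzky_golay(rep(5, 101), sg_params(2, 1, 29),
                                      wavelengths = wl))), 0)
  # linear slope 2, derivative 1 -> exactly 2 everywhere retained
  expect_equal(as.numeric(savitzky_golay(2 * wl, sg_params(2, 1, 29),
                                          wavelengths = wl)),
               rep(2, 101 - 28), tolerance = 1e-10)
  # degree-p polynomial: d-th analytic derivative recovered
  for (prm in list(sg_params(3, 1, 15), sg_params(4, 2, 21))) {
    cf <- c(1, -2, 0.5, 0.03, -0.001)[seq_len(prm$p + 1)]
    x <- (wl - 1350) / 10
    y <- drop(outer(x, seq_along(cf) - 1, `^`) %*% cf)
    out <- savitzky_golay(y, prm, wavelengths = wl)
    dcf <- cf
    for (k in seq_len(prm$d)) dcf <- dcf[-1] * seq_along(dcf[-1])
    h <- (prm$w - 1) / 2
    xr <- x[(h + 1):(101 - h)]
    truth <- drop(outer(xr, seq_along(dcf) - 1, `^`) %*% dcf) / 10^prm$d
    expect_equal(as.numeric(out), truth, tolerance = 1e-8)
  }
})

test_that("filter agrees with a per-window least-squares oracle", {
  set.seed(3)
  wl <- seq(1300, 1398, by = 2)   # 2 nm grid: checks derivative units
  X <- matrix(rnorm(5 * 50), 5, 50)
  prm <- sg_params(3, 2, 11)
  out <- savitzky_golay(X, prm, wavelengths = wl)
  h <- (prm$w - 1) / 2
  for (i in seq_len(nrow(X))) {
    for (jj in c(1, 10, 40 - 2 * h)) {
      j <- jj + h
      win <- (j - h):(j + h)
      fit <- lm(X[i, win] ~ poly(wl[win] - wl[j], prm$p, raw = TRUE))
      truth <- coef(fit)[[prm$d + 1]] * factorial(prm$d)
      expect_equal(unname(out[i, jj]), truth, tolerance = 1e-8)
    }
  }
})

test_that("the filter is linear and trims the grid", {
  set.seed(8)
  s1 <- rnorm(60); s2 <- rnorm(60)
  prm <- sg_params(2, 1, 9)
  f <- function(x) savitzky_golay(x, prm, wavelengths = 1:60)
  expect_equal(f(3 * s1 - 2 * s2), 3 * f(s1) - 2 * f(s2), tolerance = 1e-10)
  expect_length(f(s1), 60 - 8)
})
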