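test_that("zero-noise balanced BLUEs are the genotype plot means", {
  tr <- balanced_design(8, n_rep = 2)
  g <- setNames(rnorm(8), sort(unique(tr$plots$genotype)))
  tr$plots$y <- 5 + g[tr$plots$genotype]
  bl <- estimate_blues(tr, "y", variant = "within_environment")
  expect_equal(bl$blues, 5 + g, tolerance = 1e-10)
  expect_equal(bl$sed, 0)
})

test_that("fixed-variance BLUEs match a dense GLS solve", {
  # unbalanced toy: 6 plots, 3 genotypes, 2 environments
  d <- data.frame(plot_id = as.character(1:6),
                  genotype = c("A", "A", "B", "B", "C", "A"),
                  environment = c("E1", "E2", "E1", "E2", "E1", "E1"),
                  replicate = "R1", block = "B1")
  set.seed(7)
  d$y <- rnorm(6, 10)
  comp <- c(sigma2_l = 0.5, sigma2_gl = 0.3, sigma2_e = 0.7)
  bl <- estimate_blues(d, "y", variant = "series", varcomp = comp)
  # oracle: dense V and (X'V^-1 X)^-1 X'V^-1 y
  Xl <- model.matrix(~ 0 + environment, d)
  Xgl <- model.matrix(~ 0 + interaction(genotype, environment, drop = TRUE), d)
  V <- 0.7 * diag(6) + 0.5 * tcrossprod(Xl) + 0.3 * tcrossprod(Xgl)
  X <- model.matrix(~ 0 + genotype, d)
  or <- dense_gls(d$y, X, V)
  expect_equal(unname(bl$blues), unname(or$beta), tolerance = 1e-8)
  expect_equal(bl$sed, mean(sqrt(c(
    or$C[1, 1] + or$C[2, 2] - 2 * or$C[1, 2],
    or$C[1, 1] + or$C[3, 3] - 2 * or$C[1, 3],
    or$C[2, 2] + or$C[3, 3] - 2 * or$C[2, 3]))), tolerance = 1e-8)
})

test_that("REML-estimated and fixed-variance GLS paths agree", {
  s <- quick_sim(n_geno = 30, seed = 9)
  b1 <- estimate_blues(s$trial, "GY")
  b2 <- estimate_blues(s$trial, "GY", varcomp = b1$varcomp)
  expect_equal(b1$blues, b2$blues, tolerance = 1e-6)
  expect_equal(b1$sed, b2$sed, tolerance = 1e-6)
})

test_that("disconnected environments raise a singularity error", {
  d <- data.frame(plot_id = as.character(1:8),
                  genotype = rep(c("A", "B", "C", "D"), each = 2),
                  environment = rep(c("E1", "E2"), each = 4),
                  replicate = rep(c("R1", "R2"), 4), block = "B1",
                  y = rnorm(8))
  expect_error(estimate_blues(d, "y", variant = "series"),
               class = "phenosel_singular")
})

test_that("spectra BLUEs: copies, noise-free recovery, unreplicated fallback", {
  s <- quick_sim(n_geno = 20, n_env = 1, seed = 4, p_e = 0, p_gl = 0,
                 p_g = 1, wavelengths = seq(1300, 1340, by = 4))
  sp <- s$trial$spectra
  # exact copy columns give identical BLUE columns
  sp2 <- cbind(sp, wl_9999 = sp[, 3])
  sb <- spectra_blues(sp2, s$trial$plots, variant = "within_environment")
  expect_equal(unname(sb$blues[, "wl_9999"]), unname(sb$blues[, 3]))
  # noise-free: BLUEs reproduce the genotype spectral values exactly
  truth <- s$effects$scores_g %*% t(s$effects$loadings_g)
  rownames(truth) <- rownames(s$effects$scores_g)
  base_env <- s$effects$base +
    drop(s$effects$loadings_env %*% s$effects$scores_env["E1", ])
  recon <- sweep(sb$blues[, seq_len(ncol(sp)), drop = FALSE], 2, base_env)
  expect_equal(unname(recon), unname(truth[rownames(sb$blues), ]),
               tolerance = 1e-8)
  # unreplicated single environment falls back to raw spectra
  tr1 <- generate_design(design_config(12, 1, "single_rep", seed = 2))
  s1 <- simulate_dataset(tr1, variance_config(),
                         wavelengths = seq(1300, 1320, by = 4), seed = 3)
  fb <- spectra_blues(s1$trial$spectra, s1$trial$plots,
                      variant = "within_environment")
  expect_true(fb$fallback)
  expect_equal(sort(rownames(fb$blues)), sort(unique(s1$trial$plots$genotype)))
})

test_that("Cullis H2 matches the brute-force PEV-matrix oracle", {
  tr <- balanced_response(balanced_design(40, n_rep = 2),
                          sigma2_g = 1, sigma2_e = 2, seed = 5)$trial
  fit <- fit_reml(tr, "y", genotype_as = "random",
                  variant = "within_environment")
  h2 <- cullis_h2(fit)
  # oracle: PEV = G - G Z' P Z G with P = Vi - Vi X (X'Vi X)^-1 X'Vi
  comp <- fit$components
  d <- tr$plots
  Z <- model.matrix(~ 0 + genotype, d)
  n <- nrow(d); ng <- ncol(Z)
  V <- comp[["sigma2_e"]] * diag(n) +
    comp[["sigma2_g"]] * tcrossprod(Z)
  if (comp[["sigma2_r"]] > 0) {
    Zr <- model.matrix(~ 0 + replicate, d)
    V <- V + comp[["sigma2_r"]] * tcrossprod(Zr)
  }
  X <- matrix(1, n, 1)
  Vi <- solve(V)
  P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X, t(X) %*% Vi)
  G <- comp[["sigma2_g"]] * diag(ng)
  PEV <- G - G %*% t(Z) %*% P %*% Z %*% G
  vbar <- (2 / (ng * (ng - 1))) * (ng * sum(diag(PEV)) - sum(PEV))
  expect_equal(as.numeric(h2), 1 - vbar / (2 * comp[["sigma2_g"]]),
               tolerance = 1e-8)
  expect_equal(attr(h2, "vartheta_bar"), vbar, tolerance = 1e-8)
})

test_that("Cullis H2 edge cases", {
  # vanishing PEV (noise-free limit) gives H2 = 1
  d <- phenosel:::prepare_frame(balanced_response(balanced_design(10),
                                                  seed = 1)$trial$plots, "y")
  fit <- list(frame = d,
              components = setNames(c(1, 0, 0, 0, 0, 1e-14),
                                    phenosel:::VC_NAMES),
              genotype_as = "random", variant = "within_environment")
  class(fit) <- "reml_fit"
  expect_equal(as.numeric(cullis_h2(fit)), 1)
  # sigma2_g = 0 is undefined
  fit$components[["sigma2_g"]] <- 0
  expect_error(cullis_h2(fit), class = "phenosel_undefined_h2")
})

test_that("summarize_trait reports the documented schema", {
  tr <- balanced_design(6)
  tr$plots$y <- 2
  out <- summarize_trait(tr, "y")
  expect_identical(names(out),
                   c("trait", "n_genotypes", "n_environments", "min", "mean",
                     "max", "sed", "sigma2_g", "sigma2_gl", "sigma2_e", "h2"))
  expect_equal(out$min, out$max)
  expect_equal(out$mean, 2)
})
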