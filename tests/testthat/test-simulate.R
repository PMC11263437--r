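test_that("simulation is deterministic and carries truth effects", {
  s1 <- quick_sim(seed = 5)
  s2 <- quick_sim(seed = 5)
  expect_identical(s1$trial$plots, s2$trial$plots)
  expect_identical(s1$trial$spectra, s2$trial$spectra)
  expect_named(s1$effects$genotype)
  # trait decomposition reproduces the plot values exactly
  p <- s1$trial$plots
  ef <- s1$effects
  y_re <- s1$var_config$trait_mean + ef$genotype[p$genotype] +
    ef$environment[p$environment] +
    ef$replicate[paste(p$environment, p$replicate, sep = "||")] +
    ef$block[paste(p$environment, p$replicate, p$block, sep = "||")] +
    ef$gxe[paste(p$genotype, p$environment, sep = "||")] + ef$residual
  expect_equal(unname(y_re), p$GY, tolerance = 1e-12)
})

test_that("p_e = 0 makes duplicate plots of a genotype spectrally identical", {
  s <- quick_sim(n_geno = 30, n_env = 1, seed = 2, p_g = 0.5, p_gl = 0.5,
                 p_e = 0)
  p <- s$trial$plots
  dup <- names(which(table(p$genotype) == 2))[1]
  idx <- which(p$genotype == dup)
  expect_equal(s$trial$spectra[idx[1], ], s$trial$spectra[idx[2], ],
               tolerance = 1e-12)
})

test_that("per-wavelength variance calibration matches the configured proportions", {
  # check the generative components directly against p_g / p_gl / p_e
  s <- quick_sim(n_geno = 300, n_env = 3, seed = 11,
                 p_g = 0.4, p_gl = 0.5, p_e = 0.1)
  tau2 <- s$var_config$spectra_total_sd^2
  gen_part <- s$effects$scores_g %*% t(s$effects$loadings_g)
  v_g <- apply(gen_part, 2, var)
  expect_equal(mean(v_g) / tau2, 0.4, tolerance = 0.05)
  ge_part <- s$effects$scores_gl %*% t(s$effects$loadings_gl)
  v_ge <- apply(ge_part, 2, var)
  expect_equal(mean(v_ge) / tau2, 0.5, tolerance = 0.06)
})

test_that("invalid variance configurations error", {
  expect_error(variance_config(sigma2_g = -1), class = "phenosel_not_pd")
  expect_error(variance_config(p_g = 0.5, p_gl = 0.5, p_e = 0.5),
               class = "phenosel_not_pd")
  expect_error(variance_config(link_strength = 1.5), "link_strength")
})

test_that("technical replicates behave like repeated measurements", {
  s <- quick_sim(n_geno = 10, n_env = 1, seed = 3)
  sp <- s$trial$spectra
  r0 <- simulate_technical_replicates(sp, n_rep = 3, noise_sd = 0, seed = 1)
  expect_equal(nrow(r0), 3 * nrow(sp))
  expect_equal(unname(r0[1, ]), unname(r0[2, ]))
  expect_equal(unname(average_technical_replicates(r0)), unname(sp),
               tolerance = 1e-12)
  # noisy: averaging is within a CLT-style bound of the truth
  sdn <- 0.01
  rn <- simulate_technical_replicates(sp, n_rep = 3, noise_sd = sdn, seed = 4)
  avg <- average_technical_replicates(rn)
  dev <- abs(avg - sp)
  expect_lt(quantile(dev, 0.99), 3 * sdn / sqrt(3))
  # n_rep = 1 with zero noise is a pass-through
  r1 <- simulate_technical_replicates(sp, n_rep = 1, noise_sd = 0)
  expect_equal(unname(r1), unname(sp), ignore_attr = TRUE)
  expect_error(simulate_technical_replicates(sp, 3, noise_sd = -1),
               "noise_sd")
})
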