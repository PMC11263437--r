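# shared small world: strong link, modest noise
scen_sim <- function(seed = 1, ...) {
  quick_sim(n_geno = 40, n_env = 3, seed = seed,
            wavelengths = seq(1300, 1420, by = 2), ...)
}

test_that("scenario 1 evaluates every environment and is deterministic", {
  s <- scen_sim(seed = 31, link_strength = 1, sigma2_e = 1e-4, sigma2_b = 1e-4,
                sigma2_r = 1e-4, sigma2_gl = 1e-4, p_e = 0, p_g = 1,
                p_gl = 0)
  cv <- cv_config(n_replicates = 5, seed = 9)
  r <- scenario1_within_env(s$trial, fes_config(1), model = prediction_model(),
                            cv = cv)
  expect_equal(nrow(r$table), 3)
  expect_true(all(abs(r$table$ability) <= 1))
  expect_gt(r$mean, 0.8)   # near-noise-free, fully linked world
  r2 <- scenario1_within_env(s$trial, fes_config(1),
                             model = prediction_model(), cv = cv)
  expect_identical(r$table, r2$table)
})

test_that("scenario 2: degenerate identical pair gives the in-sample correlation", {
  s <- scen_sim(seed = 32)
  one <- subset_environment(s$trial, "E1")
  p2 <- one$plots; p2$environment <- "E2"
  p2$plot_id <- paste0(p2$plot_id, "b")
  sp2 <- one$spectra; rownames(sp2) <- p2$plot_id
  both <- pheno_trial(rbind(one$plots, p2), rbind(one$spectra, sp2))
  r <- scenario2_cross_env(both, fes_config(1), model = prediction_model())
  fd <- apply_fes(one, fes_config(1))
  m <- fit_rrblup(fd$X, fd$y)
  in_sample <- cor(predict(m, fd$X), fd$y)
  expect_equal(r$table$ability, rep(in_sample, 2), tolerance = 1e-8)
})

test_that("scenario 2 requires genotype overlap", {
  s <- scen_sim(seed = 33)
  p <- s$trial$plots
  keep <- !(p$environment == "E2" &
              p$genotype %in% unique(p$genotype)[1:35])
  # E2 keeps only 5 genotypes; pairing E1 -> E2 still works, but a
  # fully disjoint split must error
  g <- unique(p$genotype)
  pa <- p[p$environment == "E1" & p$genotype %in% g[1:20], ]
  pb <- p[p$environment == "E2" & p$genotype %in% g[21:40], ]
  tr <- pheno_trial(rbind(pa, pb),
                    s$trial$spectra[c(pa$plot_id, pb$plot_id), ])
  expect_error(scenario2_cross_env(tr, fes_config(1)),
               class = "phenosel_no_overlap")
})

test_that("scenario 3: no-GxE noise-free world is predicted almost perfectly", {
  s <- scen_sim(seed = 34, link_strength = 1, sigma2_e = 1e-4,
                sigma2_gl = 1e-4, sigma2_b = 1e-4, sigma2_r = 1e-4,
                p_g = 0.999998, p_gl = 1e-6, p_e = 1e-6)
  g <- sort(unique(s$trial$plots$genotype))
  tr_g <- g[1:20]; new_g <- g[21:40]
  sel <- s$trial$plots$genotype %in% tr_g
  train <- pheno_trial(s$trial$plots[sel, ], s$trial$spectra[sel, ])
  new <- pheno_trial(s$trial$plots[!sel, ], s$trial$spectra[!sel, ])
  r <- scenario3_series(train, new, central_env = "E1", fes = fes_config(2),
                        model = prediction_model())
  expect_gt(r$table$ability, 0.99)
  # shuffled training trait: ability near zero
  train_sh <- train
  set.seed(1)
  gy <- train_sh$plots$GY
  perm <- setNames(sample(tapply(gy, train_sh$plots$genotype, mean)),
                   sort(unique(train_sh$plots$genotype)))
  train_sh$plots$GY <- perm[train_sh$plots$genotype]
  r0 <- scenario3_series(train_sh, new, central_env = "E1",
                         fes = fes_config(2), model = prediction_model())
  expect_lt(abs(r0$table$ability), 0.5)
  # overlap between training and prediction genotypes warns
  expect_warning(scenario3_series(train, s$trial, central_env = "E1",
                                  fes = fes_config(2)), "both training")
})
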