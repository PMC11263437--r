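# fixtures are built in code at test time; nothing is read from disk

# small simulated trial: n_geno genotypes x n_env environments, short
# wavelength grid so the suite stays fast
quick_sim <- function(n_geno = 60, n_env = 3, seed = 1,
                      wavelengths = seq(1300, 1500, by = 2),
                      design_kind = "p_rep", ...) {
  dc <- design_config(n_geno, n_env, design_kind = design_kind,
                      rep_fraction = 0.2, block_size = 10, seed = seed)
  simulate_dataset(generate_design(dc), variance_config(...),
                   wavelengths = wavelengths, seed = seed + 1000L)
}

# balanced single-environment layout: every genotype in every replicate
balanced_design <- function(n_geno, n_rep = 2, block_size = n_geno) {
  g <- sprintf("G%03d", seq_len(n_geno))
  plots <- do.call(rbind, lapply(seq_len(n_rep), function(r)
    data.frame(genotype = g, environment = "E1",
               replicate = paste0("R", r), block = "B1")))
  plots$plot_id <- sprintf("P%04d", seq_len(nrow(plots)))
  pheno_trial(plots)
}

# deterministic response on a balanced design with known components
balanced_response <- function(trial, sigma2_g = 1, sigma2_e = 1, mu = 10,
                              seed = 1) {
  p <- trial$plots
  set.seed(seed)
  g <- setNames(rnorm(length(unique(p$genotype)), 0, sqrt(sigma2_g)),
                sort(unique(p$genotype)))
  p$y <- mu + g[p$genotype] + rnorm(nrow(p), 0, sqrt(sigma2_e))
  trial$plots <- p
  list(trial = trial, g = g)
}

# dense generalized-least-squares oracle used by several tests
dense_gls <- function(y, X, V) {
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  beta <- solve(A, t(X) %*% Vi %*% y)
  list(beta = drop(beta), C = solve(A))
}
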