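#' Configure variance structure for trial simulation
#'
#' Defines the stochastic world that [simulate_dataset()] draws from.  The
#' trait follows the standard multi-environment trial model
#' \deqn{y = \mu + g_i + l_j + r_{js} + b_{jsh} + gl_{ij} + \epsilon,}
#' all effects independent mean-zero normals with the configured
#' variances.  Spectra are a fixed smooth base curve plus smooth
#' environment offsets plus genotype and genotype-by-environment
#' components built from low-rank smooth wavelength loadings, plus white
#' measurement noise; per wavelength the genotype / GxE / residual
#' variances are calibrated exactly to the proportions `p_g`, `p_gl`,
#' `p_e`.  A fraction `link_strength` of the trait genotype variance (and
#' `link_strength_ge` of the trait GxE variance) is linearly explained by
#' the genotype (pair) spectral scores, so downstream prediction ability
#' is controllable.
#'
#' @param sigma2_g,sigma2_l,sigma2_r,sigma2_b,sigma2_gl,sigma2_e trait
#'   variance components (squared trait units).  Defaults follow a
#'   grain-yield-like multi-environment panel (genotype 0.19, GxE 0.36,
#'   residual 0.24 t^2 ha^-2).
#' @param p_g,p_gl,p_e per-wavelength spectral variance proportions for
#'   genotype, GxE and residual; must be >= 0 and sum to 1 (defaults
#'   0.40 / 0.50 / 0.10).
#' @param link_strength fraction of trait genotype variance explained by
#'   the genotype spectral scores, in \[0, 1\].
#' @param link_strength_ge same for the GxE level; defaults to
#'   `link_strength`.
#' @param trait_mean general mean of the trait (default 6.6).
#' @param trait_name name of the trait column (default `"GY"`).
#' @param spectra_total_sd total standard deviation per wavelength of the
#'   genotype + GxE + noise part (reflectance units, default 0.05).
#' @param spectra_env_sd standard deviation of the smooth environment
#'   offset curves, as a multiple of `spectra_total_sd` (default 1).
#' @param spectra_origin_sd standard deviation of smooth origin-group
#'   offsets, same scale (default 0: origins are labels only).
#' @param n_loadings rank of the smooth loading bases (default 8).
#' @param loading_width_factor width of the Gaussian loading bumps
#'   relative to their spacing (default 1.2).
#' @return a `variance_config` list.
#' @export
variance_config <- function(sigma2_g = 0.19, sigma2_l = 0.50, sigma2_r = 0.02,
                            sigma2_b = 0.05, sigma2_gl = 0.36, sigma2_e = 0.24,
                            p_g = 0.40, p_gl = 0.50, p_e = 0.10,
                            link_strength = 0.5, link_strength_ge = link_strength,
                            trait_mean = 6.6, trait_name = "GY",
                            spectra_total_sd = 0.05, spectra_env_sd = 1,
                            spectra_origin_sd = 0,
                            n_loadings = 8, loading_width_factor = 1.2) {
  v <- c(sigma2_g = sigma2_g, sigma2_l = sigma2_l, sigma2_r = sigma2_r,
         sigma2_b = sigma2_b, sigma2_gl = sigma2_gl, sigma2_e = sigma2_e)
  assert_that(all(v >= 0), "variance components must be >= 0",
              "phenosel_not_pd")
  p <- c(p_g, p_gl, p_e)
  assert_that(all(p >= 0) && abs(sum(p) - 1) < 1e-12,
              "p_g + p_gl + p_e must equal 1 with all parts >= 0",
              "phenosel_not_pd")
  assert_that(link_strength >= 0 && link_strength <= 1,
              "link_strength must be in [0, 1]")
  assert_that(link_strength_ge >= 0 && link_strength_ge <= 1,
              "link_strength_ge must be in [0, 1]")
  structure(list(trait = as.list(v), p_g = p_g, p_gl = p_gl, p_e = p_e,
                 link_strength = link_strength,
                 link_strength_ge = link_strength_ge,
                 trait_mean = trait_mean, trait_name = trait_name,
                 spectra_total_sd = spectra_total_sd,
                 spectra_env_sd = spectra_env_sd,
                 spectra_origin_sd = spectra_origin_sd,
                 n_loadings = as.integer(n_loadings),
                 loading_width_factor = loading_width_factor),
            class = "variance_config")
}

## smooth Gaussian-bump loading matrix (n_wl x r), per-wavelength variance
## of (loadings %*% iid scores) normalized exactly to `target_var`
smooth_loadings <- function(wl, r, width_factor, target_var) {
  span <- diff(range(wl))
  spacing <- if (r > 1) span / (r - 1) else span
  centers <- seq(min(wl), max(wl), length.out = r) +
    runif(r, -0.25, 0.25) * spacing
  widths <- pmax(spacing * width_factor * runif(r, 0.8, 1.5), 1e-8)
  L <- vapply(seq_len(r),
              function(k) exp(-((wl - centers[k]) / widths[k])^2),
              numeric(length(wl)))
  L <- matrix(L, nrow = length(wl))
  v <- rowSums(L^2)
  v[v < 1e-12] <- 1e-12
  L * sqrt(target_var / v)
}

## fixed smooth base reflectance curve over the wavelength grid
base_spectrum <- function(wl) {
  x <- (wl - min(wl)) / max(diff(range(wl)), 1)
  0.55 + 0.12 * sin(2 * pi * x * 0.9) + 0.05 * x -
    0.08 * exp(-((wl - 1930) / 45)^2) - 0.05 * exp(-((wl - 1450) / 35)^2)
}

## unit-norm random vector
unit_vec <- function(r) { b <- rnorm(r); b / sqrt(sum(b^2)) }

#' Simulate traits and spectra for a trial design
#'
#' Draws one realization of the world described by a [variance_config()]
#' on the plots of a [generate_design()] layout.  The full effect set
#' (truth) is returned so recovery of variance components, heritability
#' and prediction ability can be tested against known values.
#'
#' @param design a `pheno_trial` from [generate_design()] (or any plot
#'   table wrapped in [pheno_trial()]).
#' @param var_config a [variance_config()].
#' @param wavelengths strictly increasing wavelength grid in nm (default
#'   1300:2300, the instrument range at 1 nm steps).
#' @param seed integer seed.
#' @return a `pheno_sim` list: `trial` (plots with the trait column plus
#'   the spectra), `effects` (all drawn effects, scores and loadings) and
#'   the configuration.
#' @export
simulate_dataset <- function(design, var_config, wavelengths = 1300:2300,
                             seed = 1) {
  assert_that(inherits(design, "pheno_trial"), "design must be a pheno_trial")
  assert_that(inherits(var_config, "variance_config"),
              "var_config must be a variance_config")
  assert_that(all(diff(wavelengths) > 0),
              "wavelength grid must be strictly increasing")
  p <- design$plots
  vc <- var_config
  tv <- vc$trait
  gids <- sort(unique(p$genotype))
  envs <- sort(unique(p$environment))
  reps <- unique(p[, c("environment", "replicate")])
  blks <- unique(p[, c("environment", "replicate", "block")])
  pair_key <- function(g, e) paste(g, e, sep = "||")
  pairs <- unique(pair_key(p$genotype, p$environment))
  r <- vc$n_loadings
  tau2 <- vc$spectra_total_sd^2

  with_seed(seed, {
    ## loading bases (each draw consumes RNG, order fixed for determinism)
    Lg <- smooth_loadings(wavelengths, r, vc$loading_width_factor, vc$p_g * tau2)
    Lgl <- smooth_loadings(wavelengths, r, vc$loading_width_factor, vc$p_gl * tau2)
    Lenv <- smooth_loadings(wavelengths, r, vc$loading_width_factor,
                            (vc$spectra_env_sd * vc$spectra_total_sd)^2)
    Lori <- smooth_loadings(wavelengths, r, vc$loading_width_factor,
                            (vc$spectra_origin_sd * vc$spectra_total_sd)^2)
    beta_g <- unit_vec(r)
    ## trait GxE decodes the spectral GxE scores through an
    ## environment-specific direction: which spectral features matter for
    ## the trait differs between environments, so the GxE link does not
    ## transfer across environments.  Directions are mutually orthogonal
    ## (exact zero expected transfer) while n_env <= n_loadings.
    beta_gl <- qr.Q(qr(matrix(rnorm(r * min(r, length(envs))), r)))
    if (length(envs) > r)
      beta_gl <- cbind(beta_gl,
                       vapply(seq_len(length(envs) - r),
                              function(i) unit_vec(r), numeric(r)))
    colnames(beta_gl) <- envs

    ## spectral scores
    s_g <- matrix(rnorm(length(gids) * r), length(gids), r,
                  dimnames = list(gids, NULL))
    s_gl <- matrix(rnorm(length(pairs) * r), length(pairs), r,
                   dimnames = list(pairs, NULL))
    s_env <- matrix(rnorm(length(envs) * r), length(envs), r,
                    dimnames = list(envs, NULL))
    oris <- sort(unique(p$origin %||% "O1"))
    s_ori <- matrix(rnorm(length(oris) * r), length(oris), r,
                    dimnames = list(oris, NULL))

    ## trait effects; the genotype and GxE parts are split into a piece
    ## linearly predictable from the spectral scores and an orthogonal piece
    ls <- vc$link_strength; lge <- vc$link_strength_ge
    g_eff <- sqrt(ls * tv$sigma2_g) * drop(s_g %*% beta_g) +
      sqrt((1 - ls) * tv$sigma2_g) * rnorm(length(gids))
    names(g_eff) <- gids
    l_eff <- setNames(rnorm(length(envs), 0, sqrt(tv$sigma2_l)), envs)
    r_eff <- setNames(rnorm(nrow(reps), 0, sqrt(tv$sigma2_r)),
                      paste(reps$environment, reps$replicate, sep = "||"))
    b_eff <- setNames(rnorm(nrow(blks), 0, sqrt(tv$sigma2_b)),
                      paste(blks$environment, blks$replicate, blks$block,
                            sep = "||"))
    pair_env <- sub("^.*\\|\\|", "", pairs)
    gl_link <- vapply(seq_along(pairs), function(i)
      sum(s_gl[i, ] * beta_gl[, pair_env[i]]), numeric(1))
    gl_eff <- sqrt(lge * tv$sigma2_gl) * gl_link +
      sqrt((1 - lge) * tv$sigma2_gl) * rnorm(length(pairs))
    names(gl_eff) <- pairs
    eps <- rnorm(nrow(p), 0, sqrt(tv$sigma2_e))

    pk <- pair_key(p$genotype, p$environment)
    y <- vc$trait_mean + g_eff[p$genotype] + l_eff[p$environment] +
      r_eff[paste(p$environment, p$replicate, sep = "||")] +
      b_eff[paste(p$environment, p$replicate, p$block, sep = "||")] +
      gl_eff[pk] + eps

    ## spectra: base + env offset (+ origin offset) + genotype + GxE + noise
    base <- base_spectrum(wavelengths)
    S <- matrix(rep(base, each = nrow(p)), nrow = nrow(p))
    S <- S + s_env[p$environment, , drop = FALSE] %*% t(Lenv)
    if (vc$spectra_origin_sd > 0)
      S <- S + s_ori[p$origin, , drop = FALSE] %*% t(Lori)
    S <- S + s_g[p$genotype, , drop = FALSE] %*% t(Lg)
    S <- S + s_gl[pk, , drop = FALSE] %*% t(Lgl)
    noise_sd <- sqrt(vc$p_e * tau2)
    if (noise_sd > 0)
      S <- S + matrix(rnorm(length(S), 0, noise_sd), nrow = nrow(S))
    rownames(S) <- p$plot_id
    colnames(S) <- paste0("wl_", wavelengths)

    plots <- p
    plots[[vc$trait_name]] <- unname(y)
    trial <- pheno_trial(plots, S, wavelengths)
    effects <- list(genotype = g_eff, environment = l_eff, replicate = r_eff,
                    block = b_eff, gxe = gl_eff, residual = eps,
                    scores_g = s_g, scores_gl = s_gl, scores_env = s_env,
                    loadings_g = Lg, loadings_gl = Lgl, loadings_env = Lenv,
                    beta_g = beta_g, beta_gl = beta_gl, base = base)
    structure(list(trial = trial, effects = effects, var_config = vc,
                   wavelengths = wavelengths, seed = seed),
              class = "pheno_sim")
  })
}

#' Simulate technical measurement replicates of plot spectra
#'
#' Emulates repeated spectrometer measurements of the same grain sample:
#' each plot spectrum is copied `n_rep` times with independent white noise.
#'
#' @param spectra plot-level spectra matrix (row names = plot ids).
#' @param n_rep replicates per plot (>= 1; instrument protocol uses 3).
#' @param noise_sd measurement noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return a matrix with `n_rep` rows per plot; the originating plot id of
#'   every row is stored in `attr(, "plot_id")`.
#' @export
simulate_technical_replicates <- function(spectra, n_rep = 3, noise_sd = 0.001,
                                          seed = 1) {
  assert_that(n_rep >= 1, "n_rep must be >= 1")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  spectra <- as.matrix(spectra)
  n <- nrow(spectra)
  idx <- rep(seq_len(n), each = n_rep)
  out <- spectra[idx, , drop = FALSE]
  if (noise_sd > 0)
    out <- out + with_seed(seed,
      matrix(rnorm(length(out), 0, noise_sd), nrow = nrow(out)))
  pid <- rownames(spectra)[idx]
  rownames(out) <- paste0(pid, ".", rep(seq_len(n_rep), times = n))
  attr(out, "plot_id") <- pid
  out
}
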