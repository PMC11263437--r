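## End-to-end runs from a single configuration object, with provenance.

## canonical md5 of a configuration (ignores volatile fields)
config_hash <- function(config) {
  config$out_dir <- NULL
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

#' Build a pipeline run configuration
#'
#' @param seed global RNG seed, recorded in every output.
#' @param out_dir output directory (created if needed).
#' @param simulate list of arguments for the simulation stage
#'   (`n_genotypes`, `environments`, `design_kind`, ... as in
#'   [design_config()], plus optional `variance` overrides for
#'   [variance_config()] and `wavelengths`), or `NULL` when reading
#'   files.
#' @param plots_csv,spectra_csv input paths used when `simulate` is
#'   `NULL`.
#' @param fes_id feature-engineering scenario (default 8).
#' @param sg fixed Savitzky-Golay parameters `list(p, d, w)`, or `NULL`.
#' @param sg_grid_search run the grid search (`TRUE`/`FALSE`); mutually
#'   exclusive with a fixed `sg`.
#' @param sg_grid_levels optional list of levels `list(p=, d=, w=)` passed
#'   to [sg_grid()] (default: the full 42-combination grid).
#' @param model list: `method` ("rrblup"/"plsr"), `n_components`.
#' @param cv list: `k`, `n_replicates`.
#' @param scenario `NULL` or one of 1, 2, 3.
#' @param dapc run a DAPC on the plot spectra labelled by environment.
#' @param trait trait column name.
#' @return a validated `run_config` list.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("phenosel_run_"),
                       simulate = list(n_genotypes = 150, environments = 3,
                                       design_kind = "p_rep"),
                       plots_csv = NULL, spectra_csv = NULL,
                       fes_id = 8, sg = NULL, sg_grid_search = FALSE,
                       sg_grid_levels = NULL,
                       model = list(method = "rrblup"),
                       cv = list(k = 5, n_replicates = 50),
                       scenario = NULL, dapc = FALSE, trait = NULL) {
  assert_that(!(sg_grid_search && !is.null(sg)),
              "give either fixed sg parameters or sg_grid_search, not both",
              "phenosel_config")
  if (is.null(simulate)) {
    assert_that(!is.null(plots_csv) && file.exists(plots_csv),
                "plots_csv not found", "phenosel_config")
    assert_that(!is.null(spectra_csv) && file.exists(spectra_csv),
                "spectra_csv not found", "phenosel_config")
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulate = simulate, plots_csv = plots_csv,
                 spectra_csv = spectra_csv, fes_id = fes_id, sg = sg,
                 sg_grid_search = sg_grid_search,
                 sg_grid_levels = sg_grid_levels, model = model, cv = cv,
                 scenario = scenario, dapc = dapc, trait = trait),
            class = "run_config")
}

#' Execute a configured pipeline run
#'
#' Runs simulate (or load) -> preprocess -> tune / cross-validate /
#' scenario / DAPC as configured, writing a `results.json` (with the
#' seed and configuration hash embedded), tidy CSV tables and a plain
#' text log into `out_dir`.  Re-running the same configuration and seed
#' reproduces the numbers.
#'
#' @param config a [run_config()].
#' @return the results list, invisibly; side effect: files in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "run_config"), "config must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(fmt, ...) cat(sprintf(paste0(fmt, "\n"), ...),
                                 file = log_path, append = TRUE)
  t0 <- Sys.time()
  hash <- config_hash(unclass(config))
  logf("phenosel run, seed %d, config hash %s", config$seed, hash)
  results <- list(seed = config$seed, config_hash = hash)

  ## stage: data
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  trial <- stage("data", {
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      var_args <- sim_args$variance %||% list()
      wl <- sim_args$wavelengths %||% 1300:2300
      sim_args$variance <- NULL; sim_args$wavelengths <- NULL
      dc <- do.call(design_config, c(sim_args, list(seed = config$seed)))
      sim <- simulate_dataset(generate_design(dc),
                              do.call(variance_config, var_args),
                              wavelengths = wl, seed = config$seed + 1L)
      write_plot_table(sim$trial, file.path(config$out_dir, "plots.csv"))
      logf("simulated %d plots", nrow(sim$trial$plots))
      sim$trial
    } else {
      plots <- read_plot_table(config$plots_csv)
      spec <- read_spectra_table(config$spectra_csv)
      pheno_trial(plots, spec)
    }
  })
  trait <- config$trait %||% trait_columns(trial$plots)[1]
  fes <- fes_config(config$fes_id)
  model <- do.call(prediction_model, config$model)
  cvc <- do.call(cv_config, c(config$cv, list(seed = config$seed + 2L)))
  sg <- if (!is.null(config$sg)) do.call(sg_params, config$sg)

  if (config$sg_grid_search) {
    grid <- if (is.null(config$sg_grid_levels)) sg_grid()
            else do.call(sg_grid, config$sg_grid_levels)
    gs <- stage("tune-sg", grid_search_sg(trial, fes, grid = grid,
                                          model = model, cv = cvc,
                                          trait = trait))
    write.csv(gs$table, file.path(config$out_dir, "sg_tuning.csv"),
              row.names = FALSE)
    results$grid_search <- list(best = unclass(gs$best),
                                highest = gs$highest, lowest = gs$lowest)
    sg <- gs$best
    logf("grid search best: %s", format(sg))
  }

  if (is.null(config$scenario)) {
    fd <- stage("preprocess", apply_fes(trial, fes, sg = sg, trait = trait))
    res <- stage("cv", cv_prediction_ability(fd, model = model, cv = cvc))
    results$cv <- list(mean = res$mean, sd = res$sd,
                       n_replicates = cvc$n_replicates)
    logf("CV ability %.4f (sd %.4f)", res$mean, res$sd)
  } else {
    sc <- stage("scenario", switch(as.character(config$scenario),
      "1" = scenario1_within_env(trial, fes, sg, model, cvc, trait),
      "2" = scenario2_cross_env(trial, fes, sg, model, trait),
      "3" = {
        envs <- sort(unique(trial$plots$environment))
        gs2 <- unique(trial$plots$genotype)
        half <- gs2[seq_len(length(gs2) %/% 2)]
        tr <- trial$plots$genotype %in% half
        scenario3_series(pheno_trial(trial$plots[tr, ],
                                     trial$spectra[tr, , drop = FALSE]),
                         pheno_trial(trial$plots[!tr, ],
                                     trial$spectra[!tr, , drop = FALSE]),
                         central_env = envs[1], fes = fes, sg = sg,
                         model = model, trait = trait)
      },
      stop("scenario must be 1, 2 or 3")))
    write.csv(sc$table, file.path(config$out_dir, "scenario.csv"),
              row.names = FALSE)
    results$scenario <- list(id = sc$scenario, mean = sc$mean, sd = sc$sd)
    logf("scenario %d mean ability %.4f", sc$scenario, sc$mean)
  }

  if (isTRUE(config$dapc)) {
    dp <- stage("dapc", dapc_fit(trial$spectra,
                                 labels = trial$plots$environment,
                                 seed = config$seed + 3L))
    write.csv(data.frame(plot_id = trial$plots$plot_id,
                         group = dp$groups, dp$ld[, seq_len(min(2, ncol(dp$ld))),
                                                 drop = FALSE]),
              file.path(config$out_dir, "dapc_ld.csv"), row.names = FALSE)
    results$dapc <- list(n_pcs = dp$n_pcs, cv_accuracy = dp$cv_accuracy,
                         ld_variance = dp$ld_variance)
  }

  results$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  out <- results
  out$elapsed_s <- NULL   # timings excluded so reruns are byte-identical
  jsonlite::write_json(out, file.path(config$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("done in %.1f s", results$elapsed_s)
  invisible(results)
}
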