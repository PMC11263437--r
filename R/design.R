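#' Configure a multi-environment trial design
#'
#' Describes how genotypes are laid out in each environment
#' (location-year).  Three layouts are supported: `p_rep`, a partially
#' replicated design where a fraction of the genotypes is grown twice;
#' `alpha_lattice`, a resolvable incomplete-block design with `n_reps`
#' complete replicates split into blocks of at most `block_size` plots; and
#' `single_rep`, one plot per genotype.
#'
#' @param n_genotypes number of genotypes (>= 2).
#' @param environments character vector of environment ids, or a count.
#' @param design_kind one of `"p_rep"`, `"alpha_lattice"`, `"single_rep"`.
#' @param rep_fraction for `p_rep`: fraction of genotypes duplicated per
#'   environment (the duplicated set is the first `round(rep_fraction *
#'   n_genotypes)` genotypes after one seeded shuffle, shared across
#'   environments).
#' @param n_reps for `alpha_lattice`: complete replicates per environment.
#' @param block_size plots per incomplete block (>= 2); realized block
#'   sizes within a replicate differ by at most one.
#' @param n_origins genotypes are tagged with this many origin groups
#'   (round-robin); purely a label, no effect on simulation unless the
#'   variance configuration gives origins a spectral offset.
#' @param seed integer seed making the layout reproducible.
#' @return a `design_config` list.
#' @export
design_config <- function(n_genotypes, environments = 3,
                          design_kind = c("p_rep", "alpha_lattice", "single_rep"),
                          rep_fraction = 0.2, n_reps = 2, block_size = 10,
                          n_origins = 2, seed = 1) {
  design_kind <- match.arg(design_kind)
  if (is.numeric(environments) && length(environments) == 1)
    environments <- paste0("E", seq_len(environments))
  assert_that(n_genotypes >= 2, "n_genotypes must be >= 2")
  assert_that(block_size >= 2, "block_size must be >= 2")
  assert_that(rep_fraction >= 0 && rep_fraction <= 1,
              "rep_fraction must be in [0, 1]")
  assert_that(n_reps >= 1, "n_reps must be >= 1")
  structure(list(n_genotypes = as.integer(n_genotypes),
                 environments = as.character(environments),
                 design_kind = design_kind,
                 rep_fraction = rep_fraction, n_reps = as.integer(n_reps),
                 block_size = as.integer(block_size),
                 n_origins = as.integer(n_origins),
                 seed = as.integer(seed)),
            class = "design_config")
}

## split n plots into blocks of <= block_size with sizes differing by <= 1
block_sizes <- function(n, block_size) {
  nb <- ceiling(n / block_size)
  sz <- rep(floor(n / nb), nb)
  extra <- n - sum(sz)
  if (extra > 0) sz[seq_len(extra)] <- sz[seq_len(extra)] + 1L
  sz
}

#' Generate a trial design (plot table)
#'
#' Lays out the plots of every environment according to a
#' [design_config()].  Blocks are nested in replicates and replicates in
#' environments; every genotype appears at least once per environment.
#'
#' @param config a [design_config()].
#' @return a [pheno_trial()] without spectra; `$plots` has columns
#'   `plot_id`, `genotype`, `environment`, `replicate`, `block`, `origin`.
#' @export
generate_design <- function(config) {
  assert_that(inherits(config, "design_config"), "config must be a design_config")
  gids <- sprintf("G%03d", seq_len(config$n_genotypes))
  origin <- setNames(paste0("O", ((seq_along(gids) - 1L) %% config$n_origins) + 1L),
                     gids)
  with_seed(config$seed, {
    rows <- list()
    dup_set <- NULL
    if (config$design_kind == "p_rep") {
      n_dup <- round(config$rep_fraction * config$n_genotypes)
      dup_set <- head(sample(gids), n_dup)
    }
    for (env in config$environments) {
      if (config$design_kind == "alpha_lattice") {
        per_rep <- config$n_genotypes
        assert_that(config$block_size <= per_rep,
                    "block_size exceeds plots per replicate",
                    "phenosel_invalid_design")
        for (rep_i in seq_len(config$n_reps)) {
          g <- sample(gids)
          sz <- block_sizes(per_rep, config$block_size)
          blk <- rep(paste0("B", seq_along(sz)), sz)
          rows[[length(rows) + 1L]] <-
            data.frame(genotype = g, environment = env,
                       replicate = paste0("R", rep_i), block = blk)
        }
      } else {
        g <- gids
        if (config$design_kind == "p_rep") g <- c(gids, dup_set)
        g <- sample(g)
        assert_that(config$block_size <= length(g),
                    "block_size exceeds plots per replicate",
                    "phenosel_invalid_design")
        sz <- block_sizes(length(g), config$block_size)
        blk <- rep(paste0("B", seq_along(sz)), sz)
        rows[[length(rows) + 1L]] <-
          data.frame(genotype = g, environment = env,
                     replicate = "R1", block = blk)
      }
    }
    plots <- do.call(rbind, rows)
    plots$plot_id <- sprintf("P%05d", seq_len(nrow(plots)))
    plots$origin <- unname(origin[plots$genotype])
    plots <- plots[, c("plot_id", "genotype", "environment",
                       "replicate", "block", "origin")]
    trial <- pheno_trial(plots)
    trial$design_config <- config
    trial
  })
}

#' Check the nesting structure of a plot table
#'
#' Asserts that every block maps to exactly one replicate and every
#' replicate to exactly one environment (given the nested labelling), and
#' that each genotype appears at least once per environment.
#'
#' @param trial a [pheno_trial()].
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_design <- function(trial) {
  p <- trial$plots
  be <- unique(p[, c("environment", "replicate", "block")])
  ## nested labels: a (env, rep, block) triple is one physical block
  assert_that(!anyDuplicated(be), "malformed block table")
  tab <- table(p$genotype, p$environment)
  assert_that(all(tab >= 1),
              "some genotype is missing from an environment",
              "phenosel_invalid_design")
  invisible(TRUE)
}
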