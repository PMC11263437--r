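## The eight feature-engineering scenarios (FES): every combination of
##   - Savitzky-Golay filtering of the plot spectra (ids 5-8),
##   - aggregation to genotype level by arithmetic mean (odd ids) or by
##     mixed-model BLUEs (even ids), applied to spectra and trait alike,
##   - centering and scaling of the genotype spectra (ids 3,4,7,8).
FES_TABLE <- data.frame(
  fes_id = 1:8,
  use_sg = rep(c(FALSE, TRUE), each = 4),
  nirs_aggregation = rep(c("mean", "blue"), 4),
  trait_aggregation = rep(c("mean", "blue"), 4),
  use_scaling = rep(rep(c(FALSE, TRUE), each = 2), 2))

#' Feature-engineering scenario configuration
#'
#' Returns the recipe of one of the eight feature-engineering scenarios:
#' whether the spectra are Savitzky-Golay filtered, whether spectra and
#' trait are aggregated to genotype level by arithmetic means or by
#' mixed-model BLUEs, and whether the genotype spectra are centered and
#' scaled.  The trait itself is never scaled.
#'
#' @param fes_id scenario id, 1 to 8.
#' @return an `fes_config` list with fields `fes_id`, `use_sg`,
#'   `nirs_aggregation`, `trait_aggregation`, `use_scaling`.
#' @export
fes_config <- function(fes_id) {
  assert_that(length(fes_id) == 1 && fes_id %in% 1:8,
              "fes_id must be in 1..8", "phenosel_config")
  structure(as.list(FES_TABLE[FES_TABLE$fes_id == fes_id, ]),
            class = "fes_config")
}

#' @export
print.fes_config <- function(x, ...) {
  cat(sprintf("FES %d: %s%s aggregation%s, trait %s\n", x$fes_id,
              if (x$use_sg) "SG-filtered, " else "", x$nirs_aggregation,
              if (x$use_scaling) ", scaled" else "", x$trait_aggregation))
  invisible(x)
}

#' Build the genotype-level predictor matrix and trait vector of a FES
#'
#' Runs the fixed preprocessing order of a feature-engineering scenario
#' on plot-level data: optional Savitzky-Golay filtering of the plot
#' spectra, then aggregation to genotype level (arithmetic mean or
#' mixed-model BLUEs), then optional centering/scaling of the spectra.
#' The trait is aggregated per `trait_aggregation` and aligned with the
#' spectra rows on genotype id.
#'
#' For a single-environment table the within-environment BLUE model is
#' used; if no genotype is replicated there, raw spectra / plot values
#' are passed through (the unreplicated-trial fallback).
#'
#' @param trial a [pheno_trial()] with spectra and the trait column.
#' @param fes an [fes_config()].
#' @param sg an [sg_params()]; required iff the scenario filters.
#' @param trait trait column name; defaults to the first trait column.
#' @return an `fes_data` list: `X` (genotype x feature matrix after all
#'   configured steps), `X_raw` (before scaling; what cross-validation
#'   should rescale per training fold), `y` (named trait vector),
#'   `genotypes`, `use_scaling`, `dropped_wavelengths`.
#' @export
apply_fes <- function(trial, fes, sg = NULL, trait = NULL) {
  assert_that(inherits(trial, "pheno_trial"), "trial must be a pheno_trial")
  assert_that(inherits(fes, "fes_config"), "fes must be an fes_config")
  assert_that(!is.null(trial$spectra), "trial carries no spectra")
  trait <- trait %||% trait_columns(trial$plots)[1]
  assert_that(!is.na(trait) && trait %in% names(trial$plots),
              "trait column not found")
  if (fes$use_sg)
    assert_that(inherits(sg, "sg_params"),
                "this FES filters: sg parameters are required",
                "phenosel_config")

  plots <- trial$plots
  spec <- trial$spectra
  if (fes$use_sg) spec <- savitzky_golay(spec, sg, trial$wavelengths)

  single_env <- length(unique(plots$environment)) == 1
  variant <- if (single_env) "within_environment" else "series"
  dropped <- character(0)
  if (fes$nirs_aggregation == "blue") {
    sb <- spectra_blues(spec, plots, variant = variant)
    X <- sb$blues
    dropped <- sb$dropped_wavelengths
  } else {
    X <- genotype_mean(spec, plots$genotype)
  }

  if (fes$trait_aggregation == "blue") {
    unrep <- single_env && max(table(plots$genotype)) == 1
    y <- if (unrep) {
      v <- setNames(plots[[trait]], plots$genotype); v[sort(names(v))]
    } else estimate_blues(plots, trait, variant = variant,
                          compute_sed = FALSE)$blues
  } else {
    y <- drop(genotype_mean(matrix(plots[[trait]], ncol = 1), plots$genotype))
  }

  g <- intersect(rownames(X), names(y))
  X <- X[g, , drop = FALSE]
  y <- y[g]
  X_final <- if (fes$use_scaling) scale_columns(X) else X
  structure(list(X = X_final, X_raw = X, y = y, genotypes = g,
                 use_scaling = fes$use_scaling,
                 dropped_wavelengths = dropped, fes = fes, sg = sg,
                 trait = trait),
            class = "fes_data")
}
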