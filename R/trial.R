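#' Bundle a plot table with plot-level spectra
#'
#' The basic data container of the package: one row of `plots` per field
#' plot (columns `plot_id`, `genotype`, `environment`, `replicate`, `block`
#' plus trait columns) and a numeric spectra matrix whose rows are aligned
#' with the plot table via `plot_id` row names.
#'
#' @param plots data.frame with at least `plot_id`, `genotype`,
#'   `environment`; `replicate`/`block` default to a single level.
#' @param spectra numeric matrix (plots x wavelengths) or `NULL`; row names
#'   must be the plot ids, column names `wl_<nm>`.
#' @param wavelengths numeric wavelength grid (nm); derived from the
#'   spectra column names when omitted.
#' @return an object of class `pheno_trial`.
#' @export
pheno_trial <- function(plots, spectra = NULL, wavelengths = NULL) {
  assert_that(is.data.frame(plots), "plots must be a data.frame")
  need <- c("plot_id", "genotype", "environment")
  miss <- setdiff(need, names(plots))
  assert_that(length(miss) == 0,
              paste("plot table misses column(s):", paste(miss, collapse = ", ")),
              "phenosel_missing_column")
  plots$plot_id <- as.character(plots$plot_id)
  assert_that(!anyDuplicated(plots$plot_id),
              "duplicated plot_id in plot table", "phenosel_duplicate_plot")
  if (is.null(plots$replicate)) plots$replicate <- "R1"
  if (is.null(plots$block)) plots$block <- "B1"
  for (cl in c("genotype", "environment", "replicate", "block"))
    plots[[cl]] <- as.character(plots[[cl]])
  if (!is.null(spectra)) {
    spectra <- as.matrix(spectra)
    assert_that(!is.null(rownames(spectra)) &&
                  setequal(rownames(spectra), plots$plot_id),
                "spectra row names must match plot ids")
    spectra <- spectra[plots$plot_id, , drop = FALSE]
    if (is.null(wavelengths)) {
      wavelengths <- wl_from_names(colnames(spectra))
    }
    assert_that(length(wavelengths) == ncol(spectra),
                "wavelength grid length must equal spectra columns")
    assert_that(all(diff(wavelengths) > 0), "wavelength grid must be strictly increasing")
    colnames(spectra) <- paste0("wl_", wavelengths)
  }
  structure(list(plots = plots, spectra = spectra,
                 wavelengths = wavelengths),
            class = "pheno_trial")
}

wl_from_names <- function(nm) {
  assert_that(!is.null(nm) && all(grepl("^wl_", nm)),
              "spectra columns must be named wl_<nm>")
  as.numeric(sub("^wl_", "", nm))
}

#' @export
print.pheno_trial <- function(x, ...) {
  cat(sprintf("pheno_trial: %d plots, %d genotypes, %d environment(s)",
              nrow(x$plots), length(unique(x$plots$genotype)),
              length(unique(x$plots$environment))))
  if (!is.null(x$spectra))
    cat(sprintf(", spectra %d-%d nm (%d points)",
                min(x$wavelengths), max(x$wavelengths), ncol(x$spectra)))
  cat("\n")
  invisible(x)
}

#' Subset a trial to one or more environments
#'
#' @param trial a [pheno_trial()].
#' @param environments character vector of environment ids to keep.
#' @return a `pheno_trial` restricted to those environments.
#' @export
subset_environment <- function(trial, environments) {
  keep <- trial$plots$environment %in% environments
  assert_that(any(keep), "no plots in the requested environment(s)")
  pheno_trial(trial$plots[keep, , drop = FALSE],
              if (!is.null(trial$spectra)) trial$spectra[keep, , drop = FALSE],
              trial$wavelengths)
}

## trait columns = everything that is not a design column
trait_columns <- function(plots) {
  setdiff(names(plots), c("plot_id", "genotype", "environment",
                          "replicate", "block", "origin"))
}
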