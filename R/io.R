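## CSV dialect: UTF-8, comma separator, header row, '.' decimal.

#' Read a plot table CSV
#'
#' Expects columns `plot_id`, `genotype`, `environment`; optional
#' `replicate` and `block` (missing ones imply a single replicate /
#' one implicit block, with a warning) plus any trait columns.
#'
#' @param path file path.
#' @return a data.frame of typed plot records.
#' @export
read_plot_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("plot_id", "genotype", "environment")
  miss <- setdiff(need, names(d))
  assert_that(length(miss) == 0,
              paste("missing required column(s):", paste(miss, collapse = ", ")),
              "phenosel_missing_column")
  d$plot_id <- as.character(d$plot_id)
  assert_that(!anyDuplicated(d$plot_id), "duplicated plot_id",
              "phenosel_duplicate_plot")
  if (is.null(d$replicate)) {
    warning("no replicate column: assuming a single replicate")
    d$replicate <- "R1"
  }
  if (is.null(d$block)) {
    warning("no block column: assuming one implicit block")
    d$block <- "B1"
  }
  d
}

#' Write a plot table CSV
#' @param records plot table data.frame or `pheno_trial`.
#' @param path output file path.
#' @export
write_plot_table <- function(records, path) {
  if (inherits(records, "pheno_trial")) records <- records$plots
  write.csv(records, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a spectra matrix CSV
#'
#' First column `plot_id`, remaining columns `wl_<nm>` on a strictly
#' increasing uniform grid.
#'
#' @param path file path.
#' @return numeric matrix with plot-id row names; attribute
#'   `wavelengths`.
#' @export
read_spectra_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  assert_that(names(d)[1] == "plot_id", "first column must be plot_id")
  wl <- wl_from_names(names(d)[-1])
  if (any(diff(wl) <= 0)) {
    bad <- names(d)[-1][which(diff(wl) <= 0)[1] + 1L]
    stop_phenosel(paste("wavelength columns not strictly increasing at", bad),
                  "phenosel_bad_grid")
  }
  m <- as.matrix(d[, -1, drop = FALSE])
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop_phenosel(sprintf("NaN/NA cell at row %d (plot %s), column %s",
                          idx[1], d$plot_id[idx[1]], colnames(m)[idx[2]]),
                  "phenosel_bad_cell")
  }
  rownames(m) <- as.character(d$plot_id)
  attr(m, "wavelengths") <- wl
  m
}

#' Write a spectra matrix CSV
#' @param spectra matrix with plot-id row names and `wl_*` columns.
#' @param path output file path.
#' @export
write_spectra_table <- function(spectra, path) {
  d <- data.frame(plot_id = rownames(spectra), as.data.frame(spectra),
                  check.names = FALSE)
  write.csv(d, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize simulation truth effects to JSON
#' @param sim a `pheno_sim`.
#' @param path output path.
#' @export
write_effects_json <- function(sim, path) {
  ef <- sim$effects
  jsonlite::write_json(list(
    genotype = as.list(ef$genotype), environment = as.list(ef$environment),
    gxe = as.list(ef$gxe)), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
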