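#' Center and scale matrix columns
#'
#' Subtracts the column mean and divides by the column standard deviation
#' (n - 1 denominator), as done by `scale()`.  Zero-variance columns are
#' dropped with a warning; the applied statistics are attached so they
#' can be reused on held-out rows.
#'
#' @param x numeric matrix with >= 2 rows.
#' @param center,scale optional statistics to apply instead of computing
#'   them from `x` (training-set reuse in cross-validation).
#' @return the standardized matrix; attributes `center`, `scale`,
#'   `dropped` (names of removed columns).
#' @export
scale_columns <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(center)) {
    assert_that(nrow(x) >= 2, "need at least 2 rows to scale")
    center <- colMeans(x)
    scale <- apply(x, 2, sd)
    drop_cols <- colnames(x)[scale < 1e-12]
    if (length(drop_cols) == ncol(x))
      stop_phenosel("all columns have zero variance", "phenosel_empty_output")
    if (length(drop_cols))
      warning(sprintf("dropping %d zero-variance column(s)", length(drop_cols)))
  } else {
    ## reuse training statistics: keep exactly the training columns
    assert_that(all(names(center) %in% colnames(x)),
                "columns of x must cover the training columns")
    drop_cols <- setdiff(colnames(x), names(center))
  }
  keep <- setdiff(colnames(x), drop_cols)
  out <- sweep(sweep(x[, keep, drop = FALSE], 2, center[keep]), 2,
               scale[keep], "/")
  attr(out, "center") <- center[keep]
  attr(out, "scale") <- scale[keep]
  attr(out, "dropped") <- drop_cols
  out
}

#' Average technical measurement replicates
#'
#' Collapses repeated spectrometer measurements of the same plot to their
#' arithmetic mean, the final spectrum used for analysis.
#'
#' @param spectra matrix of replicate rows.
#' @param plot_ids plot id of each row; defaults to the `plot_id`
#'   attribute written by [simulate_technical_replicates()].
#' @return one-row-per-plot matrix (rows ordered by first appearance).
#' @export
average_technical_replicates <- function(spectra,
                                         plot_ids = attr(spectra, "plot_id")) {
  assert_that(!is.null(plot_ids) && length(plot_ids) == nrow(spectra),
              "plot_ids must label every replicate row")
  ids <- unique(plot_ids)
  out <- rowsum(spectra, group = factor(plot_ids, levels = ids),
                reorder = FALSE) / as.vector(table(factor(plot_ids, levels = ids)))
  rownames(out) <- ids
  out
}

#' Genotype-wise arithmetic mean of a plot-level matrix
#'
#' @param x plot-level matrix.
#' @param genotypes genotype of each row.
#' @return genotype x column matrix (rows sorted by genotype id).
#' @export
genotype_mean <- function(x, genotypes) {
  assert_that(length(genotypes) == nrow(x) && !anyNA(genotypes),
              "every row must map to a genotype")
  g <- factor(genotypes)
  out <- rowsum(as.matrix(x), group = g) / as.vector(table(g))
  out[order(rownames(out)), , drop = FALSE]
}
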