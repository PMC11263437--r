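#' Pick the best row of a tuning table with the parsimony tie-break
#'
#' The best Savitzky-Golay combination maximizes the mean CV prediction
#' ability; among exact ties the least complex combination wins, with
#' complexity ordered lexicographically smallest-first on (derivative
#' order, polynomial order, window size).
#'
#' @param table data.frame with columns `p`, `d`, `w`, `mean_ability`.
#' @return the index of the winning row.
#' @export
select_best_sg <- function(table) {
  assert_that(all(c("p", "d", "w", "mean_ability") %in% names(table)),
              "tuning table misses required columns")
  best <- max(table$mean_ability)
  tied <- which(table$mean_ability == best)
  tied[order(table$d[tied], table$p[tied], table$w[tied])][1]
}

#' Grid-search tuning of the Savitzky-Golay parameters
#'
#' Runs the full preprocessing + repeated-CV pipeline for every
#' parameter combination of the grid (filtering happens at plot level,
#' so any BLUE aggregation is recomputed per combination) and reports
#' the mean and standard deviation of the CV prediction ability per
#' combination, the winning combination under the parsimony tie-break,
#' and the highest and lowest abilities observed.
#'
#' @param trial a [pheno_trial()] with spectra and trait.
#' @param fes an [fes_config()] with `use_sg = TRUE`.
#' @param grid list of [sg_params()] (default [sg_grid()], 42
#'   combinations).
#' @param model a [prediction_model()].
#' @param cv a [cv_config()]; every combination reuses the same seed so
#'   fold assignments are shared.
#' @param trait trait column name.
#' @return a `grid_search_result`: `table` (one row per combination),
#'   `best` (an `sg_params`), `highest`, `lowest`.
#' @export
grid_search_sg <- function(trial, fes, grid = sg_grid(),
                           model = prediction_model(), cv = cv_config(),
                           trait = NULL) {
  assert_that(inherits(fes, "fes_config") && fes$use_sg,
              "grid search requires a filtering FES (use_sg = TRUE)",
              "phenosel_config")
  assert_that(length(grid) >= 1, "empty grid", "phenosel_config")
  rows <- lapply(grid, function(sg) {
    fd <- apply_fes(trial, fes, sg = sg, trait = trait)
    res <- cv_prediction_ability(fd, model = model, cv = cv)
    data.frame(p = sg$p, d = sg$d, w = sg$w,
               mean_ability = res$mean, sd_ability = res$sd)
  })
  tab <- do.call(rbind, rows)
  i <- select_best_sg(tab)
  structure(list(table = tab,
                 best = sg_params(tab$p[i], tab$d[i], tab$w[i]),
                 highest = tab$mean_ability[i],
                 lowest = min(tab$mean_ability)),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf(
    "SG grid search over %d combinations: best p=%d d=%d w=%d (ability %.3f; lowest %.3f)\n",
    nrow(x$table), x$best$p, x$best$d, x$best$w, x$highest, x$lowest))
  invisible(x)
}
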