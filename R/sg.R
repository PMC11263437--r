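#' Savitzky-Golay filter parameters
#'
#' The filter fits a degree-`p` polynomial by least squares inside a
#' moving window of `w` points and returns the `d`-th derivative of that
#' local fit at the window centre.  Tuning ranges follow common NIRS
#' practice: `p` in 2-4, `d` in 1-2, `w` in 29-89 nm.
#'
#' @param p polynomial order (>= 1).
#' @param d derivative order (1 <= d <= p).
#' @param w window size in grid points; odd, > p.
#' @return an `sg_params` list.
#' @export
sg_params <- function(p, d, w) {
  assert_that(w %% 2 == 1, "window size w must be odd", "phenosel_sg_params")
  assert_that(d >= 1 && d <= p, "need 1 <= d <= p", "phenosel_sg_params")
  assert_that(p < w, "polynomial order must be < window size",
              "phenosel_sg_params")
  structure(list(p = as.integer(p), d = as.integer(d), w = as.integer(w)),
            class = "sg_params")
}

#' @export
format.sg_params <- function(x, ...) sprintf("p%d_d%d_w%d", x$p, x$d, x$w)

#' @export
print.sg_params <- function(x, ...) {
  cat(sprintf("Savitzky-Golay: polynomial %d, derivative %d, window %d\n",
              x$p, x$d, x$w)); invisible(x)
}

#' The default Savitzky-Golay tuning grid
#'
#' All 42 combinations of polynomial order 2/3/4, derivative order 1/2
#' and window size 29-89 in steps of 10.
#'
#' @param p,d,w candidate levels for each parameter.
#' @return list of [sg_params()], ordered by (d, p, w) so that earlier
#'   entries are less complex (the parsimony order).
#' @export
sg_grid <- function(p = c(2, 3, 4), d = c(1, 2), w = seq(29, 89, by = 10)) {
  g <- expand.grid(w = w, p = p, d = d)
  g <- g[g$d <= g$p, ]
  g <- g[order(g$d, g$p, g$w), ]
  lapply(seq_len(nrow(g)), function(i) sg_params(g$p[i], g$d[i], g$w[i]))
}

## convolution weights: row of (A'A)^-1 A' for the d-th derivative at the
## window centre, A = [(-h:h)^j], scaled by d! / delta^d
sg_weights <- function(p, d, w, delta = 1) {
  h <- (w - 1L) / 2L
  A <- outer(seq(-h, h), 0:p, `^`)
  G <- solve(crossprod(A), t(A))
  G[d + 1L, ] * factorial(d) / delta^d
}

#' Apply the Savitzky-Golay derivative filter to spectra
#'
#' Filters every row of a spectra matrix.  Derivatives are taken with
#' respect to wavelength (per nm), so the grid must be uniform.  The
#' `(w-1)/2` points at each edge, where no full window exists, are
#' trimmed from the output grid (no polynomial extrapolation).
#'
#' @param spectra matrix (rows = samples, columns = `wl_<nm>` wavelengths)
#'   or a numeric vector.
#' @param params an [sg_params()].
#' @param wavelengths optional numeric grid; parsed from column names when
#'   omitted.
#' @return filtered matrix on the trimmed wavelength grid.
#' @export
savitzky_golay <- function(spectra, params, wavelengths = NULL) {
  assert_that(inherits(params, "sg_params"), "params must be sg_params")
  vec <- is.null(dim(spectra))
  X <- if (vec) matrix(spectra, nrow = 1) else as.matrix(spectra)
  if (is.null(wavelengths)) {
    wavelengths <- if (!is.null(colnames(X)) && all(grepl("^wl_", colnames(X))))
      wl_from_names(colnames(X)) else seq_len(ncol(X))
  }
  assert_that(length(wavelengths) == ncol(X), "grid length mismatch")
  steps <- diff(wavelengths)
  assert_that(all(abs(steps - steps[1]) < 1e-8 * max(abs(steps))),
              "wavelength grid must be uniform for filtering")
  assert_that(params$w <= ncol(X),
              "window size exceeds the number of wavelengths",
              "phenosel_sg_params")
  wts <- sg_weights(params$p, params$d, params$w, delta = steps[1])
  h <- (params$w - 1L) / 2L
  keep <- (h + 1L):(ncol(X) - h)
  ## filtering = banded matrix multiply; build the (n_out x n_in) operator
  out <- matrix(0, nrow(X), length(keep))
  for (k in seq_along(wts)) {
    cols <- keep - h - 1L + k
    out <- out + wts[k] * X[, cols, drop = FALSE]
  }
  rownames(out) <- rownames(X)
  colnames(out) <- paste0("wl_", wavelengths[keep])
  attr(out, "wavelengths") <- wavelengths[keep]
  if (vec) drop(out) else out
}
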