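## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded operations do not disturb the global stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_phenosel <- function(msg, class) {
  stop(structure(class = c(class, "phenosel_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(ok, msg, class = "phenosel_invalid") {
  if (!isTRUE(ok)) stop_phenosel(msg, class)
  invisible(TRUE)
}

## Pearson correlation that tolerates degenerate inputs (returns NA).
safe_cor <- function(x, y) {
  if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

## mean standard error of a difference across all pairwise comparisons,
## from the covariance matrix C of the estimates (exact when n <= max_exact,
## otherwise a seeded sample of pairs).
mean_sed <- function(C, max_exact = 2000L, n_pairs = 10000L, seed = 1L) {
  n <- nrow(C)
  if (n < 2L) return(NA_real_)
  d <- diag(C)
  if (n <= max_exact) {
    vd <- outer(d, d, "+") - 2 * C
    mean(sqrt(pmax(vd[upper.tri(vd)], 0)))
  } else {
    with_seed(seed, {
      i <- sample.int(n, n_pairs, replace = TRUE)
      j <- sample.int(n, n_pairs, replace = TRUE)
      keep <- i != j
      i <- i[keep]; j <- j[keep]
      mean(sqrt(pmax(d[i] + d[j] - 2 * C[cbind(i, j)], 0)))
    })
  }
}

## mean prediction-error variance of a pairwise difference from a PEV matrix
mean_pair_pev <- function(P) {
  n <- nrow(P)
  (2 / (n * (n - 1))) * (n * sum(diag(P)) - sum(P))
}
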