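## Discriminant analysis of principal components (DAPC): PCA reduction,
## optional k-means group inference (k by BIC), then linear discriminant
## analysis on the retained PCs.

## BIC of a k-means solution on the PC scores (the criterion of the
## standard DAPC group-inference procedure)
kmeans_bic <- function(wss, n, k) n * log(wss / n) + k * log(n)

## stratified train/test split indices (test fraction per group)
stratified_split <- function(labels, test_frac = 0.1) {
  te <- unlist(lapply(split(seq_along(labels), labels), function(idx) {
    n_te <- max(1L, round(length(idx) * test_frac))
    if (length(idx) <= n_te) return(integer(0))  # keep group in training
    sample(idx, n_te)
  }))
  sort(te)
}

#' Fit a DAPC on spectra
#'
#' Reduces the (column-centered) spectra with PCA, infers groups by
#' k-means when no labels are given (k chosen by BIC over `k_range`,
#' clustering on all PCs, 20 seeded restarts), and runs linear
#' discriminant analysis on the retained PCs.  The cross-validated
#' assignment accuracy is estimated by repeated stratified 90/10 splits.
#'
#' @param x samples x wavelengths matrix.
#' @param labels optional group labels (>= 2 groups, each >= 2 members);
#'   when `NULL`, groups are inferred.
#' @param n_pcs PCs retained for the discriminant step; `NULL` selects
#'   by [cv_select_npcs()] over a small candidate set.
#' @param k_range candidate group numbers for the unsupervised case.
#' @param cv_reps repetitions of the stratified accuracy CV.
#' @param seed RNG seed.
#' @return a `dapc_result`: `n_pcs`, `k`, `assignments`, `ld` (sample
#'   LD coordinates), `ld_variance` (percent of discriminant variance
#'   per LD, sums to 100), `cv_accuracy`, `groups`, `lda` (the
#'   underlying MASS fit).
#' @export
dapc_fit <- function(x, labels = NULL, n_pcs = NULL, k_range = 2:6,
                     cv_reps = 100, seed = 1) {
  x <- as.matrix(x)
  assert_that(nrow(x) >= 3, "need at least 3 rows")
  pca <- prcomp(x, center = TRUE, scale. = FALSE)
  keep <- which(pca$sdev > 1e-10 * pca$sdev[1])
  scores <- pca$x[, keep, drop = FALSE]
  with_seed(seed, {
    if (is.null(labels)) {
      fits <- lapply(k_range, function(k)
        kmeans(scores, centers = k, nstart = 20, iter.max = 50))
      bic <- vapply(seq_along(k_range), function(i)
        kmeans_bic(fits[[i]]$tot.withinss, nrow(x), k_range[i]), numeric(1))
      k <- k_range[which.min(bic)]
      labels <- factor(fits[[which.min(bic)]]$cluster)
      inferred <- TRUE
    } else {
      labels <- factor(labels)
      inferred <- FALSE
      k <- nlevels(labels)
    }
    assert_that(nlevels(labels) >= 2,
                "need at least 2 groups for a discriminant analysis",
                "phenosel_no_discriminant")
    assert_that(all(table(labels) >= 2), "every group needs >= 2 members")
    if (is.null(n_pcs)) {
      cand <- unique(pmin(c(2L, 5L, 10L, 20L), ncol(scores)))
      n_pcs <- as.integer(cv_select_npcs(x, labels, candidates = cand,
                                         reps = max(20L, cv_reps %/% 5L),
                                         seed = seed + 1L))
    }
    n_pcs <- min(n_pcs, ncol(scores))
    S <- scores[, seq_len(n_pcs), drop = FALSE]
    fit <- MASS::lda(S, grouping = labels)
    pr <- predict(fit)
    ldvar <- 100 * fit$svd^2 / sum(fit$svd^2)
    ## repeated stratified 90/10 CV of the assignment accuracy
    acc <- vapply(seq_len(cv_reps), function(r) {
      te <- stratified_split(labels, 0.1)
      tr <- setdiff(seq_len(nrow(S)), te)
      f <- MASS::lda(S[tr, , drop = FALSE], grouping = labels[tr])
      mean(predict(f, S[te, , drop = FALSE])$class == labels[te])
    }, numeric(1))
    structure(list(n_pcs = n_pcs, k = k, inferred_groups = inferred,
                   assignments = pr$class, ld = pr$x,
                   ld_variance = ldvar, cv_accuracy = mean(acc),
                   groups = labels, lda = fit),
              class = "dapc_result")
  })
}

#' @export
print.dapc_result <- function(x, ...) {
  cat(sprintf(
    "DAPC: %d PCs, %d groups%s; LD1 %.1f%% of discriminant variance; CV accuracy %.3f\n",
    x$n_pcs, x$k, if (x$inferred_groups) " (inferred)" else "",
    x$ld_variance[1], x$cv_accuracy))
  invisible(x)
}

#' Cross-validated choice of the retained PC count
#'
#' For each candidate PC count, estimates the held-out assignment
#' accuracy of an LDA on that many PCs via repeated stratified 90/10
#' splits; returns the candidate maximizing mean accuracy, ties broken
#' toward fewer PCs.  Candidates exceeding the data rank are skipped
#' with a warning.
#'
#' @param x samples x wavelengths matrix.
#' @param labels group labels.
#' @param candidates PC counts to compare.
#' @param reps split repetitions (default 100).
#' @param seed RNG seed.
#' @return the selected count; attribute `accuracy` holds the table.
#' @export
cv_select_npcs <- function(x, labels, candidates = c(2, 5, 10, 20),
                           reps = 100, seed = 1) {
  x <- as.matrix(x)
  labels <- factor(labels)
  assert_that(nlevels(labels) >= 2, "need at least 2 groups")
  pca <- prcomp(x, center = TRUE, scale. = FALSE)
  keep <- which(pca$sdev > 1e-10 * pca$sdev[1])
  scores <- pca$x[, keep, drop = FALSE]
  cand <- sort(unique(as.integer(candidates)))
  bad <- cand > ncol(scores)
  if (any(bad)) {
    warning(sprintf("skipping candidate PC count(s) beyond rank: %s",
                    paste(cand[bad], collapse = ", ")))
    cand <- cand[!bad]
  }
  assert_that(length(cand) >= 1, "no usable candidate PC count")
  with_seed(seed, {
    splits <- lapply(seq_len(reps), function(r) stratified_split(labels, 0.1))
    acc <- vapply(cand, function(np) {
      S <- scores[, seq_len(np), drop = FALSE]
      mean(vapply(splits, function(te) {
        tr <- setdiff(seq_len(nrow(S)), te)
        f <- MASS::lda(S[tr, , drop = FALSE], grouping = labels[tr])
        mean(predict(f, S[te, , drop = FALSE])$class == labels[te])
      }, numeric(1)))
    }, numeric(1))
    structure(cand[which.max(acc)],
              accuracy = data.frame(n_pcs = cand, accuracy = acc))
  })
}
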