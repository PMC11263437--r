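# two well-separated synthetic spectral groups
two_groups <- function(n_per = 15, p = 40, sep_sd = 10, seed = 1) {
  set.seed(seed)
  base <- sin(seq(0, 3, length.out = p))
  shift <- sep_sd * 0.02 * cos(seq(0, 5, length.out = p))
  x <- rbind(
    matrix(rnorm(n_per * p, sd = 0.02), n_per, p, byrow = TRUE) +
      rep(base, each = n_per),
    matrix(rnorm(n_per * p, sd = 0.02), n_per, p, byrow = TRUE) +
      rep(base + shift, each = n_per))
  colnames(x) <- paste0("wl_", seq_len(p))
  list(x = x, labels = rep(c("g1", "g2"), each = n_per))
}

test_that("well-separated groups are assigned perfectly", {
  tg <- two_groups()
  r <- dapc_fit(tg$x, labels = tg$labels, n_pcs = 5, seed = 2)
  expect_equal(mean(r$assignments == tg$labels), 1)
  expect_equal(r$cv_accuracy, 1)
  # two groups: exactly one discriminant function carrying 100%
  expect_length(r$ld_variance, 1)
  expect_equal(sum(r$ld_variance), 100, tolerance = 1e-6)
})

test_that("degenerate labellings error", {
  tg <- two_groups()
  expect_error(dapc_fit(tg$x, labels = rep("a", nrow(tg$x)), n_pcs = 3),
               class = "phenosel_no_discriminant")
})

test_that("unsupervised grouping recovers the separated clusters", {
  tg <- two_groups(sep_sd = 12, seed = 3)
  r <- dapc_fit(tg$x, n_pcs = 5, k_range = 2:4, seed = 4)
  expect_true(r$inferred_groups)
  expect_equal(r$k, 2)
  # inferred clusters coincide with the truth up to label switching
  conf <- table(r$groups, tg$labels)
  expect_equal(max(sum(diag(conf)), conf[1, 2] + conf[2, 1]), nrow(tg$x))
})

test_that("DAPC is invariant to wavelength-wise constant offsets", {
  tg <- two_groups(seed = 5)
  r1 <- dapc_fit(tg$x, labels = tg$labels, n_pcs = 4, seed = 6)
  r2 <- dapc_fit(sweep(tg$x, 2, runif(ncol(tg$x), -5, 5), `+`),
                 labels = tg$labels, n_pcs = 4, seed = 6)
  expect_equal(r1$cv_accuracy, r2$cv_accuracy)
  expect_equal(as.character(r1$assignments), as.character(r2$assignments))
})

test_that("PC-count selection behaves on separable and random labels", {
  tg <- two_groups(seed = 7)
  sel <- cv_select_npcs(tg$x, tg$labels, candidates = c(2, 5, 10), reps = 30,
                        seed = 8)
  acc <- attr(sel, "accuracy")
  expect_equal(acc$accuracy[acc$n_pcs == as.integer(sel)], 1)
  expect_equal(as.integer(sel), min(acc$n_pcs[acc$accuracy >= max(acc$accuracy)]))
  # random labels: accuracy near chance (1/2)
  set.seed(9)
  rl <- sample(rep(c("a", "b"), each = 15))
  sel0 <- cv_select_npcs(tg$x, rl, candidates = c(2, 5), reps = 50, seed = 10)
  expect_lt(max(attr(sel0, "accuracy")$accuracy), 0.75)
  # candidates beyond the rank are skipped with a warning
  expect_warning(cv_select_npcs(tg$x, tg$labels, candidates = c(2, 500),
                                reps = 5, seed = 1), "beyond rank")
  # deterministic under seed
  expect_identical(as.integer(cv_select_npcs(tg$x, tg$labels, c(2, 5),
                                             reps = 10, seed = 3)),
                   as.integer(cv_select_npcs(tg$x, tg$labels, c(2, 5),
                                             reps = 10, seed = 3)))
})
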