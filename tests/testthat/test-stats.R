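test_that("the Bonferroni threshold divides the base level by the family size", {
  expect_equal(bonferroni_alpha(6, 0.05), 0.0083)
  expect_equal(bonferroni_alpha(1, 0.05), 0.05)
  expect_equal(bonferroni_alpha(2, 0.05), 0.025)
  expect_error(bonferroni_alpha(0), "count")
  expect_error(bonferroni_alpha(6, 1.2), "\\(0, 1\\)")
})

test_that("Mann-Whitney matches exact enumeration on small tie-free samples", {
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$p_value, 1 / 3)
  expect_equal(mann_whitney(1:3, 4:6)$p_value, 0.1)

  set.seed(14)
  for (k in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    a <- rnorm(n1); b <- rnorm(n2, 0.5)
    got <- mann_whitney(a, b)
    expect_equal(got$p_value, enum_mwu_p(a, b))
    # symmetry: swapping samples flips U to n1*n2 - U, same p
    rev <- mann_whitney(b, a)
    expect_equal(rev$statistic, n1 * n2 - got$statistic)
    expect_equal(rev$p_value, got$p_value)
  }
})

test_that("Mann-Whitney handles ties, identical samples and degenerate input", {
  same <- mann_whitney(c(5, 6, 7), c(5, 6, 7))
  expect_gte(same$p_value, 0.99)
  flat <- mann_whitney(rep(1, 4), rep(1, 5))
  expect_equal(flat$p_value, 1)
  # tie-corrected approximation agrees with the established implementation
  set.seed(15)
  a <- sample(1:5, 30, TRUE); b <- sample(2:6, 25, TRUE)
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  expect_equal(mann_whitney(a, b)$p_value, unname(ref$p.value))
  expect_error(mann_whitney(numeric(0), 1:3), "at least 2")
})

test_that("the Kruskal-Wallis H statistic matches its tie-corrected closed form", {
  set.seed(16)
  for (k in 1:10) {
    groups <- list(a = sample(1:8, 6, TRUE), b = sample(2:9, 5, TRUE),
                   c = sample(3:10, 7, TRUE))
    res <- kruskal_dunn(groups, alpha = 0.9)
    expect_equal(unname(res$statistic), direct_kw_h(groups))
    ref <- stats::kruskal.test(unlist(groups),
                               factor(rep(1:3, lengths(groups))))
    expect_equal(res$p_value, unname(ref$p.value))
  }
})

test_that("Kruskal-Wallis agrees with a permutation oracle and Dunn localises the shift", {
  set.seed(17)
  groups <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30, 5))
  res <- kruskal_dunn(groups, alpha = 0.0083)
  expect_true(res$significant)
  ph <- res$posthoc
  involving_c <- ph$group1 == "c" | ph$group2 == "c"
  expect_true(all(ph$p_value[involving_c] < 0.0083))
  expect_gte(min(ph$p_value[!involving_c]), 0.0083)

  # permutation oracle for the observed H on a small sample
  small <- list(a = rnorm(5), b = rnorm(5), c = rnorm(5, 3))
  h_obs <- direct_kw_h(small)
  values <- unlist(small)
  g <- rep(1:3, each = 5)
  perm <- replicate(10000, direct_kw_h(split(sample(values), g)))
  p_perm <- mean(perm >= h_obs - 1e-9)
  p_got <- kruskal_dunn(small, alpha = 1 - 1e-9)$p_value
  expect_lt(abs(p_perm - p_got), 0.05) # chi-square approx vs exact permutation
})

test_that("identical groups and all-tied data take the null path without post-hoc", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  res <- kruskal_dunn(g, alpha = 0.05)
  expect_false(res$significant)
  expect_null(res$posthoc)
  flat <- kruskal_dunn(list(a = rep(2, 3), b = rep(2, 4), c = rep(2, 5)))
  expect_equal(flat$p_value, 1)
  expect_false(flat$overridden)
})

test_that("a Kruskal-Wallis rejection with no significant Dunn pair is overridden", {
  # frozen case: KW p = 0.00850 but the smallest Dunn pairwise p is 0.01008
  g <- list(
    a = c(-0.51, -1.22, -0.61, -0.51, -0.74, 2.37),
    b = c(1.84, 1.66, 1.17, 0.24, 0.98, 1.39),
    c = c(1.19, 1.48, 1.19, 2.51, 1.32, 0.95),
    d = c(0.72, -0.27, -0.44, -0.62, -1.35, 0.25)
  )
  res <- kruskal_dunn(g, alpha = 0.009)
  expect_lt(res$p_value, 0.009)
  expect_gte(min(res$posthoc$p_value), 0.009)
  expect_true(res$overridden)
  expect_false(res$significant)
})

test_that("surrogate reports are deterministic, rank-invariant and null-calibrated", {
  set.seed(18)
  x <- rnorm(180)
  rep1 <- surrogate_null(x, c(90, 90), "mwu", n_iter = 400, alpha = 0.0083, seed = 9)
  rep2 <- surrogate_null(x, c(90, 90), "mwu", n_iter = 400, alpha = 0.0083, seed = 9)
  expect_identical(rep1, rep2)
  # rank test: any monotone transform gives the identical report
  rep3 <- surrogate_null(exp(x), c(90, 90), "mwu", n_iter = 400,
                         alpha = 0.0083, seed = 9)
  expect_equal(rep3$significant_fraction, rep1$significant_fraction)
  expect_equal(rep3$median_p, rep1$median_p)

  flat <- surrogate_null(rep(3, 60), c(30, 30), "mwu", n_iter = 100, seed = 2)
  expect_equal(flat$significant_fraction, 0)
  expect_true(flat$passed)

  expect_error(surrogate_null(1:10, c(4, 4), "mwu"), "sum")
})

test_that("the fast surrogate statistics agree with the reference tests", {
  set.seed(19)
  x <- c(rnorm(25), rnorm(30, 0.4))
  sizes <- c(25, 30)
  rep_m <- surrogate_null(x, sizes, "mwu", n_iter = 50, alpha = 0.5, seed = 4)
  # recompute one surrogate split by hand through wilcox.test
  r <- rank(x)
  ps <- with(list(), {
    set.seed(4L)
    vapply(1:50, function(b) {
      idx <- sample.int(55, 25)
      suppressWarnings(stats::wilcox.test(x[idx], x[-idx], exact = FALSE,
                                          correct = TRUE)$p.value)
    }, 1)
  })
  expect_equal(rep_m$significant_fraction, mean(ps < 0.5), tolerance = 1e-12)
  expect_equal(rep_m$median_p, stats::median(ps), tolerance = 1e-12)

  rep_k <- surrogate_null(x, c(20, 17, 18), "kw", n_iter = 50, alpha = 0.5, seed = 6)
  ps_k <- with(list(), {
    set.seed(6L)
    g <- rep(1:3, c(20, 17, 18))
    vapply(1:50, function(b) {
      stats::kruskal.test(x, factor(g[sample.int(55)]))$p.value
    }, 1)
  })
  expect_equal(rep_k$significant_fraction, mean(ps_k < 0.5), tolerance = 1e-12)
  expect_equal(rep_k$median_p, stats::median(ps_k), tolerance = 1e-12)
})

test_that("the full battery wires tests, override flags and surrogates together", {
  sim <- quick_cohort(n_per_group = 4L, seed = 37L)
  summ <- summarize_cohort(sim)
  ds <- build_comparison_datasets(summ, scaled_catalog())
  res <- run_full_battery(ds, n_surrogates = 30, seed = 1)
  expect_equal(nrow(res), nrow(ds))
  expect_true(all(res$test %in% c("mwu", "kw")))
  expect_true(all(!res$significant | res$p_value < res$alpha))
  expect_true(all(!res$overridden | !res$significant))
  expect_true(all(res$surrogate_fraction >= 0 & res$surrogate_fraction <= 1))
  # determinism of the whole battery
  res2 <- run_full_battery(ds, n_surrogates = 30, seed = 1)
  expect_equal(res[setdiff(names(res), "posthoc")],
               res2[setdiff(names(res2), "posthoc")])
  expect_error(run_full_battery(ds[0, ]), "no datasets")
})
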