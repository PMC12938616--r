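test_that("exact signed-rank p-values match hand-enumerable cases", {
  expect_equal(wilcoxon_exact(c(1, 2, 3))$p_two_sided, 0.25)
  expect_equal(wilcoxon_exact(c(1, 2, 3, 4, 5))$p_two_sided, 0.0625)

  degenerate <- wilcoxon_exact(c(0, 0, 0))
  expect_equal(degenerate$p_two_sided, 1.0)
  expect_true(degenerate$degenerate)
  expect_equal(degenerate$n_effective, 0)

  # agreement with the base-R exact test on tie-free data
  set.seed(14)
  for (i in 1:25) {
    d <- rnorm(sample(4:11, 1), 0.3, 1)   # continuous: tie-free
    ref <- stats::wilcox.test(d, exact = TRUE)$p.value
    expect_equal(wilcoxon_exact(d)$p_two_sided, ref, tolerance = 1e-12)
  }
})

test_that("exact signed-rank p equals full enumeration, with ties and invariances", {
  set.seed(15)
  for (i in 1:150) {
    n <- sample(2:12, 1)
    d <- sample(c(-3:3), n, replace = TRUE)  # many zeros and ties
    if (all(d == 0)) d[1] <- 1
    got <- wilcoxon_exact(d)
    expect_equal(got$p_two_sided, oracle_wilcoxon_p(d))
    # invariant to positive scaling and to a global sign flip
    expect_equal(wilcoxon_exact(2.5 * d)$p_two_sided, got$p_two_sided)
    expect_equal(wilcoxon_exact(-d)$p_two_sided, got$p_two_sided)
  }
})

test_that("the normal approximation engages above the cutoff and tracks the exact p", {
  set.seed(16)
  d <- rnorm(21, 0.4, 1)
  approx <- wilcoxon_exact(d, exact_cutoff = 20)
  exact <- wilcoxon_exact(d, exact_cutoff = 25)
  expect_equal(approx$method, "normal_approx")
  expect_equal(exact$method, "exact")
  expect_lt(abs(approx$p_two_sided - exact$p_two_sided), 0.01)
})

test_that("Cohen's dz follows the paired-effect definition", {
  expect_equal(cohens_dz(c(2, 0, 2, 0)), 1 / (2 / sqrt(3)), tolerance = 1e-12)
  expect_equal(round(cohens_dz(c(2, 0, 2, 0)), 3), 0.866)
  expect_equal(cohens_dz(c(-2, -1, 1, 2)), 0)
  expect_error(cohens_dz(c(1, 1, 1, 1)), "zero SD")
})

test_that("Friedman statistic matches the hand formula and a reference implementation", {
  same <- matrix(rep(c(1, 2, 3), each = 4), nrow = 4)
  same[, 1] <- same[, 2] <- same[, 3] <- 5
  res_same <- friedman_rank_test(same)
  expect_equal(res_same$chi2, 0)
  expect_equal(res_same$p, 1)

  ident <- rbind(c(1, 5, 9), c(2, 6, 10))
  res <- friedman_rank_test(ident)
  expect_equal(res$chi2, 4.0)
  expect_equal(res$df, 2)
  expect_false(res$tie_corrected)

  set.seed(17)
  for (i in 1:20) {
    m <- matrix(rnorm(8 * 4), 8, 4)  # continuous: tie-free
    got <- friedman_rank_test(m)
    ref <- stats::friedman.test(m)
    expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    # invariant to per-subject shifts
    shifted <- m + rnorm(8)
    expect_equal(friedman_rank_test(shifted)$chi2, got$chi2, tolerance = 1e-10)
  }
  expect_error(friedman_rank_test(matrix(1:3, 3, 1)), "conditions")
})

test_that("the modality learning report reproduces its inputs", {
  fx <- make_fixtures(tempfile())
  oc <- read.delim(fx["outcomes"])
  summaries <- aggregate_performance(oc)
  rep_tab <- modality_learning_report(summaries)
  expect_setequal(rep_tab$modality, c("cFB", "aFB", "noFB", "overall"))

  cfb <- rep_tab[rep_tab$modality == "cFB", ]
  ld <- learning_delta(summaries)
  expect_equal(cfb$mean_delta_pp,
               ld$group$mean_delta_pp[ld$group$modality == "cFB"])
  expect_equal(cfb$mean_run2 - cfb$mean_run1, cfb$mean_delta_pp)

  # identical runs: all deltas zero, all p = 1
  s2 <- summaries
  key <- paste(s2$participant_id, s2$modality)
  s2$success_rate[s2$run_id == 2] <-
    s2$success_rate[s2$run_id == 1][match(key[s2$run_id == 2], key[s2$run_id == 1])]
  flat <- modality_learning_report(s2)
  expect_true(all(flat$mean_delta_pp == 0))
  expect_true(all(flat$p_wilcoxon == 1))
})
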