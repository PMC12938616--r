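test_that("streaming GLM reproduces batch least squares", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(30:80, 1)
    n_vox <- sample(5:20, 1)
    labels <- rep(c("rest", "task"), length.out = n)
    X <- localizer_design_matrix(labels)
    Y <- matrix(rnorm(n * n_vox, 100, 2), n, n_vox)
    state <- glm_init(X, n_vox)
    for (t in seq_len(n)) state <- glm_update(state, Y[t, ])
    map <- glm_t_map(state)
    want <- oracle_batch_t(X, Y, c(1, 0, 0))
    expect_equal(map$t, want$t, tolerance = 1e-8)
    expect_equal(map$beta, want$beta, tolerance = 1e-8)
    expect_equal(map$df, want$df)
  }
})

test_that("intercept-only streaming GLM is a running mean", {
  Y <- matrix(rnorm(60, 50, 5), 20, 3)
  state <- glm_init(matrix(1, 20, 1), 3)
  for (t in 1:20) state <- glm_update(state, Y[t, ])
  map <- glm_t_map(state, contrast = 1)
  expect_equal(map$beta, colMeans(Y), tolerance = 1e-10)
})

test_that("degenerate GLM states are rejected", {
  state <- glm_init(cbind(1, 1:10), 4)
  expect_error(glm_t_map(state), "no volumes")
  state <- glm_update(state, rep(1, 4))
  expect_error(glm_t_map(state), "more volumes than design rank")
  sing <- glm_init(cbind(1, 2, (1:10) * 0), 2)
  for (t in 1:5) sing <- glm_update(sing, rnorm(2))
  expect_error(glm_t_map(sing), "singular")
  expect_error(glm_update(glm_init(cbind(1, 1:3), 2), rep(0, 3)), "voxels")
})

test_that("t statistics are affine-invariant and finite on perfect fits", {
  set.seed(31)
  labels <- make_localizer_design(localizer_design(task_blocks = 3))
  X <- localizer_design_matrix(labels)
  n <- nrow(X)
  y <- rnorm(n, 100, 1)
  fit_t <- function(y) {
    st <- glm_init(X, 1)
    for (t in seq_len(n)) st <- glm_update(st, y[t])
    glm_t_map(st)$t
  }
  expect_equal(fit_t(3.7 * y + 11), fit_t(y), tolerance = 1e-6)

  perfect <- 100 + 5 * X[, "task"]
  t_perfect <- fit_t(perfect)
  expect_true(is.finite(t_perfect))
  expect_gt(t_perfect, 1e4)
})

test_that("ROI selection picks the cluster holding the peak t", {
  tm <- array(0, c(4, 4, 3))
  tm[2, 2, 2] <- 8
  roi1 <- select_roi(tm, 5)
  expect_equal(roi1$size_voxels, 1)
  expect_equal(roi1$size_cm3, 0.012)
  expect_equal(unname(roi1$peak_coord), c(2, 2, 2))

  # two disjoint clusters: the one with the higher peak wins even if smaller
  tm2 <- array(0, c(6, 4, 3))
  tm2[1:2, 1:2, 1] <- 6
  tm2[5, 4, 3] <- 9
  roi2 <- select_roi(tm2, 4)
  expect_equal(roi2$peak_t, 9)
  expect_equal(roi2$size_voxels, 1)

  # diagonal neighbors are not face-adjacent
  tm3 <- array(0, c(3, 3, 1))
  tm3[1, 1, 1] <- 5; tm3[2, 2, 1] <- 6
  roi3 <- select_roi(tm3, 4)
  expect_equal(roi3$size_voxels, 1)
  expect_equal(unname(roi3$peak_coord), c(2, 2, 1))

  expect_error(select_roi(array(0, c(3, 3, 3)), 2), "suprathreshold")
  expect_error(select_roi(tm, 0), "positive")
})

test_that("a planted active block is recovered exactly at separable thresholds", {
  model <- participant_model(gain = 4, noise_sd = 0.3, ar_phi = 0.2)
  design <- localizer_design()
  active <- as.matrix(expand.grid(2:3, 2:3, 2:3))
  sim <- simulate_localizer_grid(model, design, c(4, 4, 4), active, seed = 99)
  X <- localizer_design_matrix(sim$labels)
  map <- localize_grid(sim$grid, X)
  t_active <- map$t[sim$truth_mask]
  t_null <- map$t[!sim$truth_mask]
  expect_gt(min(t_active), max(t_null))  # separable
  thr <- (min(t_active) + max(t_null)) / 2
  roi <- select_roi(map, thr)
  expect_equal(roi$mask, sim$truth_mask)
  expect_equal(roi$size_cm3, 0.012 * 8)

  series <- roi_mean_series(sim$grid, roi)
  expect_equal(length(series), length(sim$labels))
})

test_that("calibration takes the maximum block-mean signal change", {
  design <- localizer_design(task_blocks = 3, task_trs = 5, rest_trs = 10)
  labels <- make_localizer_design(design)
  base <- rep(100, length(labels))
  plateaus <- c(2, 3, 4)
  series <- base
  runs <- rle(labels)
  ends <- cumsum(runs$lengths)
  task_i <- which(runs$values == "task")
  for (k in seq_along(task_i)) {
    idx <- (ends[task_i[k]] - runs$lengths[task_i[k]] + 1):ends[task_i[k]]
    series[idx] <- 100 * (1 + plateaus[k] / 100)
  }
  expect_equal(calibrate_max(series, design)$localizer_max_percent, 4)

  flat4 <- base
  for (k in seq_along(task_i)) {
    idx <- (ends[task_i[k]] - runs$lengths[task_i[k]] + 1):ends[task_i[k]]
    flat4[idx] <- 104
  }
  expect_equal(calibrate_max(flat4, design)$localizer_max_percent, 4)

  # noisy trace equals a brute-force recomputation
  set.seed(12)
  noisy <- series + rnorm(length(series), 0, 0.5)
  got <- calibrate_max(noisy, design)$localizer_max_percent
  want <- max(vapply(seq_along(task_i), function(k) {
    ti <- (ends[task_i[k]] - runs$lengths[task_i[k]] + 1):ends[task_i[k]]
    ri <- (ends[task_i[k] - 1] - runs$lengths[task_i[k] - 1] + 1):ends[task_i[k] - 1]
    100 * (mean(noisy[ti]) - mean(noisy[ri])) / mean(noisy[ri])
  }, 0))
  expect_equal(got, want, tolerance = 1e-12)

  expect_error(calibrate_max(rep(100, 10), design), "does not match")
  expect_error(calibrate_max(100 - series + 100, design), "non-positive")
})
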