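test_that("cohort sampling respects field assignment, seeds and ranges", {
  spec <- cohort_spec()
  models <- sample_cohort(spec)
  expect_length(models, 9)
  expect_equal(sum(vapply(models, function(m) m$field_strength, "") == "7T"), 3)
  gains <- vapply(models, function(m) m$gain, 0)
  expect_true(all(gains >= 1.5 & gains <= 4.5))
  expect_identical(models, sample_cohort(spec))

  point <- cohort_spec(n_participants = 3, field_assignment = rep("3T", 3),
                       model_ranges = list(gain = 2.5, effort_noise_sd = c(0.1, 0.1)))
  pm <- sample_cohort(point)
  expect_equal(vapply(pm, function(m) m$gain, 0), rep(2.5, 3),
               ignore_attr = TRUE)
  expect_error(cohort_spec(model_ranges = list(gain = c(3, 1))), "ordered")
  expect_error(cohort_spec(n_participants = 4, field_assignment = rep("3T", 3)))
})

test_that("participant model invariants are enforced", {
  expect_error(participant_model(gain = 0), "gain")
  expect_error(participant_model(ar_phi = 1), "ar_phi")
  expect_error(participant_model(tracking_rate_cFB = 1.5), "rates")
})

test_that("BOLD forward model has unit-area kernel and clean limits", {
  k <- hrf_kernel()
  expect_equal(sum(k), 1, tolerance = 1e-12)
  expect_equal(which.max(k), 4)  # peak at 6 s with a 2 s TR (lag 0 first)

  quiet <- participant_model(noise_sd = 0, drift_slope = 0)
  expect_equal(simulate_bold(rep(0, 50), quiet), rep(0, 50))

  # sustained unit effort converges to gain exactly (area-normalized kernel)
  plateau <- simulate_bold(rep(1, 60), quiet)
  expect_equal(plateau[60], quiet$gain, tolerance = 1e-9)

  noisy <- participant_model()
  expect_identical(simulate_bold(rep(1, 40), noisy, seed = 5),
                   simulate_bold(rep(1, 40), noisy, seed = 5))
})

test_that("with zero gain the trace is AR(1) noise with the configured phi", {
  m <- participant_model(gain = 1e-12, ar_phi = 0.5, noise_sd = 1,
                         drift_slope = 0)
  x <- simulate_bold(rep(0, 4000), m, seed = 11)
  r1 <- stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]
  expect_equal(r1, 0.5, tolerance = 0.06)
})

test_that("effort tracking corrects toward the cued target and is inert at zero rates", {
  m0 <- participant_model(tracking_rate_cFB = 0)
  eff <- effort_trace(m0, "cFB", 2, feedback = runif(12, 0, 100),
                      n_trs = 12, start_effort = 0.4)
  expect_equal(eff, rep(0.4, 12))

  m <- participant_model(tracking_rate_cFB = 0.2)
  mid <- 55  # level-2 band midpoint
  pinned <- effort_trace(m, "cFB", 2, feedback = rep(mid, 12),
                         n_trs = 12, start_effort = 0.4)
  expect_equal(pinned, rep(0.4, 12))
  low <- effort_trace(m, "cFB", 2, feedback = rep(0, 12),
                      n_trs = 12, start_effort = 0.4)
  expect_true(all(diff(low) > 0))

  ma <- participant_model(tracking_rate_aFB = 0.1)
  on_target <- effort_trace(ma, "aFB", 2, feedback = rep(2, 12),
                            n_trs = 12, start_effort = 0.4)
  expect_equal(on_target, rep(0.4, 12))
  no_fb <- effort_trace(ma, "noFB", 2, feedback = rep(0, 12),
                        n_trs = 12, start_effort = 0.4)
  expect_equal(no_fb, rep(0.4, 12))
})

test_that("latency generator matches its configured distribution", {
  m <- latency_model(transfer_log_sigma = 1e-9, outlier_prob = 0)
  log0 <- simulate_latency_log(m, 100, seed = 1)
  expect_equal(log0$transfer_ms, rep(454, 100), tolerance = 1e-6)
  expect_true(all(log0$processing_ms >= 0))

  big <- simulate_latency_log(latency_model(outlier_prob = 0), 12000, seed = 2)
  expect_equal(median(big$transfer_ms), 454, tolerance = 0.05 * 454)

  # tail events: binomial expectation ~ 44 of 12276 at p = 0.36%
  tail7 <- simulate_latency_log(latency_model(), 12276, seed = 3,
                                field_strength = "7T")
  n_tail <- sum(tail7$transfer_ms > 2000)
  expect_true(abs(n_tail - 44) < 3 * sqrt(44))

  # 3T sessions draw no tail events under the default model
  tail3 <- simulate_latency_log(latency_model(), 12276, seed = 3,
                                field_strength = "3T")
  expect_equal(sum(tail3$transfer_ms > 2000), 0)

  expect_identical(simulate_latency_log(latency_model(), 50, seed = 9),
                   simulate_latency_log(latency_model(), 50, seed = 9))
})

test_that("expected regulation signal is non-decreasing in cued level", {
  m <- participant_model(effort_noise_sd = 0, noise_sd = 0,
                         tracking_rate_cFB = 0, tracking_rate_aFB = 0,
                         learning_rate_cFB = 0)
  cfg <- session_config()
  sched <- make_schedule(cfg, "S01", 1)
  res <- run_closed_loop(m, sched, calibration_info(m$gain), cfg, seed = 1)
  by_level <- tapply(res$samples$psc, res$samples$cued_level, mean)
  expect_true(all(diff(by_level) > 0))
})
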