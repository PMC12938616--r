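test_that("distance to range follows the nearest-boundary definition", {
  expect_equal(distance_to_range(35, 1), 0)
  expect_equal(distance_to_range(50, 1), 10)
  expect_equal(distance_to_range(5, 2), 35)
  # top band has no active upper boundary on the clipped scale
  expect_equal(distance_to_range(c(70, 100), 3), c(0, 0))
  expect_equal(distance_to_range(50, 3), 20)
  # band membership is left-closed, right-open
  expect_equal(distance_to_range(c(10, 40), 1), c(0, 0))
  expect_true(all(distance_to_range(runif(500, 0, 100), 2) >= 0))
})

test_that("block metrics summarize occupancy and distances correctly", {
  all_in <- rep(50, 12)
  bm <- block_metrics(all_in, 2)
  expect_equal(bm$occupancy, 1)
  expect_equal(bm$dist_median, 0)
  expect_equal(bm$dist_sd, 0)

  mixed <- c(rep(50, 3), rep(5, 9))
  expect_equal(block_metrics(mixed, 2)$occupancy, 0.25)

  set.seed(3)
  for (i in 1:200) {
    s <- runif(12, 0, 100)
    lv <- sample(1:3, 1)
    got <- block_metrics(s, lv)
    want <- oracle_metrics(s, lv)
    expect_equal(got$occupancy, want$occupancy)
    expect_equal(got$dist_median, want$dist_median)
    expect_equal(got$dist_sd, want$dist_sd)
    expect_true(got$occupancy >= 0 && got$occupancy <= 1)
    if (got$occupancy == 1) expect_equal(got$dist_median + got$dist_sd, 0)
  }
  expect_error(block_metrics(rep(0, 5), 1), "expected 12")
})

test_that("aggregation reproduces worked-example rates and is order-invariant", {
  fx <- make_fixtures(tempfile())
  oc <- read.delim(fx["outcomes"])

  overall <- aggregate_performance(cbind(oc, all = "all"), by = "all")
  expect_equal(overall$n_blocks, 486)
  expect_equal(overall$n_success, 216)
  expect_equal(round(overall$success_rate, 1), 44.4)

  by_run <- aggregate_performance(oc, by = c("participant_id", "run_id"))
  expect_equal(round(min(by_run$success_rate), 1), 18.5)
  weakest <- by_run[which.min(by_run$success_rate), ]
  expect_equal(weakest$n_success, 5)

  by_pm <- aggregate_performance(oc, by = c("participant_id", "modality"))
  expect_true(all(by_pm$n_blocks == 18))

  shuffled <- oc[sample(nrow(oc)), ]
  expect_equal(aggregate_performance(shuffled, by = c("participant_id", "run_id")),
               by_run, ignore_attr = TRUE)

  # pooled rate equals the block-weighted mean of cell rates
  cells <- aggregate_performance(oc, by = c("participant_id", "run_id", "modality"))
  expect_equal(sum(cells$success_rate * cells$n_blocks) / sum(cells$n_blocks),
               overall$success_rate)

  expect_error(aggregate_performance(oc[, 1:3], by = "participant_id"), "lack")
})

test_that("learning deltas pair runs per participant and modality", {
  fx <- make_fixtures(tempfile())
  oc <- read.delim(fx["outcomes"])
  summaries <- aggregate_performance(oc)
  ld <- learning_delta(summaries)
  cfb <- ld$group[ld$group$modality == "cFB", ]
  expect_equal(round(cfb$mean_delta_pp, 1), 14.8)
  expect_equal(nrow(ld$deltas), 27)  # 9 participants x 3 modalities

  # brute-force recomputation
  set.seed(9)
  ids <- sprintf("P%d", 1:5)
  tab <- expand.grid(participant_id = ids, run_id = 1:2,
                     modality = c("a", "b"), stringsAsFactors = FALSE)
  tab$success_rate <- runif(nrow(tab), 0, 100)
  got <- learning_delta(tab)$deltas
  for (i in seq_len(nrow(got))) {
    r1 <- tab$success_rate[tab$participant_id == got$participant_id[i] &
                             tab$run_id == 1 & tab$modality == got$modality[i]]
    r2 <- tab$success_rate[tab$participant_id == got$participant_id[i] &
                             tab$run_id == 2 & tab$modality == got$modality[i]]
    expect_equal(got$delta_pp[i], r2 - r1)
  }

  same <- tab; same$success_rate[same$run_id == 2] <-
    same$success_rate[same$run_id == 1][match(
      paste(same$participant_id, same$modality)[same$run_id == 2],
      paste(same$participant_id, same$modality)[same$run_id == 1])]
  expect_true(all(learning_delta(same)$deltas$delta_pp == 0))

  expect_warning(learning_delta(tab[-1, ]), "excluded")
})
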