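test_that("default schedule draws the full crossed cell set without replacement", {
  cfg <- session_config()
  s <- make_schedule(cfg, "S01", 1)
  expect_equal(nrow(s$blocks), 27)
  expect_equal(as.vector(table(s$blocks$modality)), rep(9L, 3))
  expect_equal(as.vector(table(s$blocks$cued_level)), rep(9L, 3))
  tab <- table(s$blocks$modality, s$blocks$cued_level)
  expect_true(all(tab == 3))

  cfg1 <- session_config(blocks_per_run = 9, repeats_per_cell = 1)
  s1 <- make_schedule(cfg1, "S01", 1)
  expect_equal(nrow(s1$blocks), 9)
  expect_true(all(table(s1$blocks$modality, s1$blocks$cued_level) == 1))

  again <- make_schedule(cfg, "S01", 1)
  expect_identical(s$blocks, again$blocks)
  other <- make_schedule(cfg, "S02", 1)
  expect_false(identical(s$blocks$modality, other$blocks$modality) &&
                 identical(s$blocks$cued_level, other$blocks$cued_level))
})

test_that("block windows tile the run contiguously after stabilization", {
  cfg <- session_config()
  s <- make_schedule(cfg, "S01", 1)
  b0 <- s$blocks[1, ]
  expect_equal(c(b0$baseline_start, b0$baseline_end), c(8, 16))
  expect_equal(c(b0$regulation_start, b0$regulation_end), c(16, 28))
  expect_equal(c(b0$outcome_start, b0$outcome_end), c(28, 30))
  expect_equal(s$total_trs, 8 + 27 * 22)

  tiny <- session_config(stabilization_trs = 0, baseline_trs = 1,
                         regulation_trs = 1, outcome_trs = 1,
                         blocks_per_run = 1, modalities = "cFB",
                         levels = 1, repeats_per_cell = 1)
  st <- make_schedule(tiny, "S01", 1)
  expect_equal(st$total_trs, 3)

  # window partition: stabilization plus all phases tile [0, total) exactly
  for (cfg_i in list(cfg, session_config(baseline_trs = 3, regulation_trs = 5,
                                         outcome_trs = 1))) {
    si <- make_schedule(cfg_i, "P", 2)
    covered <- c(seq_len(cfg_i$stabilization_trs) - 1,
                 unlist(lapply(seq_len(nrow(si$blocks)), function(i) {
                   b <- si$blocks[i, ]
                   b$baseline_start:(b$outcome_end - 1)
                 })))
    expect_equal(sort(covered), 0:(si$total_trs - 1))
    expect_false(any(duplicated(covered)))
  }
})

test_that("a two-run session yields 18 blocks per modality per participant", {
  cfg <- session_config()
  blocks <- do.call(rbind, lapply(1:2, function(r) make_schedule(cfg, "S03", r)$blocks))
  expect_equal(as.vector(table(blocks$modality)),
               rep(cfg$runs_per_session * length(cfg$levels) * cfg$repeats_per_cell, 3))
})

test_that("localizer design labels alternate rest and task", {
  lab <- make_localizer_design(localizer_design())
  expect_equal(length(lab), 10 * 5 + 11 * 10)
  expect_equal(sum(lab == "task"), 50)
  runs <- rle(lab)
  expect_equal(sum(runs$values == "task"), 10)
  expect_true(all(runs$lengths[runs$values == "task"] == 5))
  expect_equal(runs$values[1], "rest")
  expect_equal(runs$values[length(runs$values)], "rest")

  expect_equal(make_localizer_design(localizer_design(1, 1, 1)),
               c("rest", "task", "rest"))
})

test_that("events table uses second-based onsets in phase order", {
  cfg <- session_config()
  s <- make_schedule(cfg, "S01", 1)
  ev <- events_table(s, cfg)
  expect_equal(nrow(ev), 27 * 3)
  expect_equal(ev$onset[1], 8 * 2)
  expect_equal(ev$trial_type[1:3], c("baseline", "regulation", "outcome"))
  expect_equal(ev$duration[ev$trial_type == "regulation"], rep(24, 27))
  expect_true(!is.unsorted(ev$onset))
  path <- tempfile(fileext = ".tsv")
  write_events(s, cfg, path)
  expect_equal(read_events(path), ev, ignore_attr = TRUE)
})

test_that("inconsistent configurations are rejected", {
  expect_error(session_config(blocks_per_run = 26), "blocks_per_run")
  expect_error(session_config(tr_seconds = 0), "tr_seconds")
  expect_error(session_config(regulation_trs = 0), "strictly positive")
})
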