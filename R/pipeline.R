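#' Run a full synthetic neurofeedback study
#'
#' End-to-end driver: samples a cohort, runs each participant's localizer
#' (grid simulation, streaming GLM, threshold-and-cluster ROI selection,
#' display calibration), simulates both closed-loop neurofeedback runs with
#' learning carried across runs, scores blocks, computes occupancy and
#' distance-to-range metrics, aggregates performance, runs the learning
#' inference, and simulates and summarizes per-volume latency logs. With an
#' output directory, all stage outputs are written as TSV/JSON together
#' with a manifest (seeds, checksums, scoring rule), so a rerun with the
#' same configuration and seed reproduces identical files.
#'
#' @param config a \code{\link{session_config}}.
#' @param cohort a \code{\link{cohort_spec}}; its \code{master_seed} is
#'   replaced by a stream derived from \code{seed}.
#' @param latency a \code{\link{latency_model}}.
#' @param scoring a \code{\link{scoring_config}}.
#' @param seed master seed of the whole study.
#' @param out_dir optional output directory.
#' @param roi_thresholds candidate t thresholds tried from the top until a
#'   suprathreshold cluster exists (the interactive adjustment of a real
#'   session).
#' @param localizer a \code{\link{localizer_design}}.
#' @param grid_shape localizer grid dimensions.
#' @return list with \code{models}, \code{calibrations}, \code{rois},
#'   \code{outcomes}, \code{samples}, \code{summaries}, \code{learning}
#'   (per-modality test table), \code{friedman}, \code{latency_log},
#'   \code{latency_summary}, \code{manifest}.
#' @export
run_study <- function(config = session_config(),
                      cohort = cohort_spec(),
                      latency = latency_model(),
                      scoring = scoring_config(),
                      seed = 1L,
                      out_dir = NULL,
                      roi_thresholds = c(7, 6, 5, 4, 3, 2),
                      localizer = localizer_design(tr_seconds = config$tr_seconds),
                      grid_shape = c(6L, 6L, 4L)) {
  cohort$master_seed <- derive_seed(seed, "cohort")
  models <- sample_cohort(cohort)
  ids <- names(models)
  levels <- target_levels()

  active <- as.matrix(expand.grid(x = 2:3, y = 2:3, z = 2:3))
  if (any(active > grid_shape)) stop("grid too small for planted ROI", call. = FALSE)

  calibrations <- list(); rois <- list()
  all_outcomes <- list(); all_samples <- list(); lat_logs <- list()

  for (pid in ids) {
    model <- models[[pid]]
    sim <- simulate_localizer_grid(model, localizer, grid_shape, active,
                                   seed = derive_seed(seed, "localizer", pid))
    design <- localizer_design_matrix(sim$labels, localizer$tr_seconds,
                                      model$hrf_peak_s, model$hrf_undershoot_s)
    tmap <- localize_grid(sim$grid, design)
    roi <- NULL
    for (th in roi_thresholds) {
      roi <- tryCatch(select_roi(tmap, th), error = function(e) NULL)
      if (!is.null(roi)) break
    }
    if (is.null(roi)) stop("no ROI found for ", pid, call. = FALSE)
    series <- roi_mean_series(sim$grid, roi)
    cal <- calibrate_max(series, localizer)
    calibrations[[pid]] <- cal
    rois[[pid]] <- roi

    runs <- run_session(model, cal, config, scoring, levels,
                        participant_id = pid,
                        run_seed_master = derive_seed(seed, "session", pid))
    for (r in seq_along(runs)) {
      all_outcomes[[paste(pid, r)]] <- runs[[r]]$outcomes
      all_samples[[paste(pid, r)]] <- runs[[r]]$samples
    }

    n_vol <- length(sim$labels) +
      config$runs_per_session * length(runs[[1]]$trace)
    lat_logs[[pid]] <- simulate_latency_log(
      latency, n_vol, seed = derive_seed(seed, "latency", pid),
      participant_id = pid, field_strength = model$field_strength)
  }

  outcomes <- do.call(rbind, all_outcomes)
  samples <- do.call(rbind, all_samples)
  rownames(outcomes) <- rownames(samples) <- NULL

  metrics <- block_metrics_table(samples, scoring, levels)
  met_aligned <- metrics[match(
    paste(outcomes$participant_id, outcomes$run_id, outcomes$block_index),
    paste(metrics$participant_id, metrics$run_id, metrics$block_index)), ]
  summaries <- aggregate_performance(outcomes,
                                     by = c("participant_id", "run_id", "modality"),
                                     metrics = met_aligned)
  learning <- if (config$runs_per_session >= 2) {
    modality_learning_report(summaries)
  } else {
    message("single-run session: learning analysis unavailable")
    NULL
  }

  by_mod <- aggregate_performance(outcomes, by = c("participant_id", "modality"))
  fri_mat <- stats::reshape(by_mod[c("participant_id", "modality", "success_rate")],
                            idvar = "participant_id", timevar = "modality",
                            direction = "wide")
  friedman <- friedman_rank_test(as.matrix(fri_mat[, -1]))

  latency_log <- do.call(rbind, lat_logs)
  rownames(latency_log) <- NULL
  latency_summary <- summarize_latency(latency_log, "all",
                                       threshold_ms = latency$tail_floor_ms)

  result <- list(models = models, calibrations = calibrations, rois = rois,
                 outcomes = outcomes, samples = samples,
                 summaries = summaries, learning = learning,
                 friedman = friedman,
                 latency_log = latency_log,
                 latency_summary = latency_summary,
                 manifest = NULL)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(outcomes = file.path(out_dir, "outcomes.tsv"),
               summaries = file.path(out_dir, "summaries.tsv"),
               learning = file.path(out_dir, "learning_tests.tsv"),
               latency_log = file.path(out_dir, "latency_log.tsv"),
               latency_summary = file.path(out_dir, "latency_summary.tsv"))
    utils::write.table(outcomes, paths["outcomes"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(summaries, paths["summaries"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(learning, paths["learning"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_latency_log(latency_log, paths["latency_log"])
    utils::write.table(latency_summary, paths["latency_summary"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (pid in ids) {
      for (r in seq_len(config$runs_per_session)) {
        p <- file.path(out_dir, sprintf("%s_run%d_events.tsv", pid, r))
        write_events(make_schedule(config, pid, r), config, p)
        paths[sprintf("events_%s_%d", pid, r)] <- p
      }
    }
    manifest <- list(seed = seed,
                     hit_rule = scoring$hit_rule,
                     package_version = as.character(utils::packageVersion("nfbloop")),
                     files = as.list(tools::md5sum(unname(paths))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    result$manifest <- manifest
  }
  result
}

#' Per-block occupancy and distance-to-range table
#'
#' @param samples per-TR regulation samples (from the closed loop) with
#'   \code{participant_id}, \code{run_id}, \code{block_index},
#'   \code{cued_level}, \code{s_value}.
#' @param scoring a \code{\link{scoring_config}}.
#' @param levels target level table.
#' @return one row per block with \code{occupancy}, \code{dist_median},
#'   \code{dist_sd}.
#' @export
block_metrics_table <- function(samples, scoring = scoring_config(),
                                levels = target_levels()) {
  key <- paste(samples$participant_id, samples$run_id, samples$block_index)
  parts <- split(samples, key)
  rows <- lapply(parts, function(p) {
    bm <- block_metrics(p$s_value, p$cued_level[1], scoring, levels)
    data.frame(participant_id = p$participant_id[1],
               run_id = p$run_id[1],
               block_index = p$block_index[1],
               modality = p$modality[1],
               cued_level = p$cued_level[1],
               occupancy = bm$occupancy,
               dist_median = bm$dist_median,
               dist_sd = bm$dist_sd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant_id, out$run_id, out$block_index), ]
}

#' Write the packaged worked-example fixtures
#'
#' Builds the deterministic fixture set used by the worked examples and
#' the reproduction script: a 486-block outcome table for nine synthetic
#' participants and two runs whose group-level marginals match the
#' published worked example (216/486 successful blocks overall; modality
#' totals 76/71/69 for cFB/aFB/noFB; per-run cFB success sums of 32 and
#' 44 of 81 blocks; weakest run 5/27, strongest 20/27), a 12,276-volume
#' latency log with exactly 44 transfer latencies above 2000 ms (all in 7T
#' sessions, 41 from one participant) and component means matching the
#' published transfer and processing means, and a small packed localizer
#' grid with a planted active block. All values are synthetic;
#' regeneration is byte-identical.
#'
#' @param out_dir directory to write into (created if needed).
#' @return named character vector of the written file paths, invisibly.
#' @export
make_fixtures <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(outcomes = file.path(out_dir, "worked_example_outcomes.tsv"),
             latency = file.path(out_dir, "worked_example_latency.tsv"),
             grid = file.path(out_dir, "worked_example_grid.tsv"))

  outcomes <- fixture_outcomes()
  utils::write.table(outcomes, paths["outcomes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  lat <- fixture_latency_log()
  lat$transfer_ms <- round(lat$transfer_ms, 3)
  lat$processing_ms <- round(lat$processing_ms, 3)
  utils::write.table(lat, paths["latency"], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  grid_fix <- fixture_grid()
  utils::write.table(grid_fix, paths["grid"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# Success-count design of the worked-example cohort: blocks succeeded out
# of 9 per participant (rows S01..S09), run and modality. Synthetic counts
# chosen so the group-level marginals reproduce the published worked
# example exactly (see make_fixtures).
fixture_success_counts <- function() {
  list(
    run1 = cbind(cFB = c(4, 4, 5, 4, 1, 4, 3, 4, 3),
                 aFB = c(4, 4, 5, 4, 2, 4, 4, 4, 3),
                 noFB = c(4, 4, 5, 5, 2, 4, 4, 4, 4)),
    run2 = cbind(cFB = c(5, 5, 7, 5, 4, 5, 5, 3, 5),
                 aFB = c(4, 4, 7, 5, 3, 4, 4, 3, 3),
                 noFB = c(4, 4, 6, 4, 3, 4, 3, 3, 2))
  )
}

fixture_outcomes <- function() {
  counts <- fixture_success_counts()
  ids <- sprintf("S%02d", 1:9)
  # within a cell of 9 blocks (3 levels x 3 repeats), successes fill from
  # the strongest level down: high targets showed the highest success rates
  level_order <- rep(c(3L, 2L, 1L), each = 3)
  rows <- list()
  for (r in 1:2) {
    cmat <- counts[[paste0("run", r)]]
    for (i in seq_along(ids)) {
      bi <- 0L
      for (mod in colnames(cmat)) {
        k <- cmat[i, mod]
        success <- seq_len(9) <= k
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = ids[i], run_id = r,
          block_index = bi + seq_len(9) - 1L,
          modality = mod, cued_level = level_order,
          success = success, stringsAsFactors = FALSE)
        bi <- bi + 9L
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

fixture_latency_log <- function() {
  per_part <- 1364L   # localizer (160 TRs) + 2 runs x 602 TRs
  ids <- sprintf("S%02d", 1:9)
  fields <- ifelse(ids %in% c("S01", "S02", "S04"), "7T", "3T")
  n_total <- per_part * length(ids)
  model <- latency_model(outlier_prob = 0)
  logs <- lapply(seq_along(ids), function(i) {
    simulate_latency_log(model, per_part, seed = derive_seed(20260130L, "lat", ids[i]),
                         participant_id = ids[i], field_strength = fields[i])
  })
  log <- do.call(rbind, logs)
  rownames(log) <- NULL
  log$transfer_ms <- pmax(log$transfer_ms, 164)

  # plant exactly 44 heavy-tail volumes: 41 in S02 (two consecutive aFB
  # blocks and scattered others), 2 in S01, 1 in S04 -- all 7T
  tails <- with_seed(derive_seed(20260130L, "tails"), {
    v <- pmin(2000 + stats::rexp(44, rate = 1 / 2500), 12004)
    v[which.max(v)] <- 12004
    v
  })
  idx_s02 <- which(log$participant_id == "S02")[seq(10, by = 30, length.out = 41)]
  idx_s01 <- which(log$participant_id == "S01")[c(200, 900)]
  idx_s04 <- which(log$participant_id == "S04")[500]
  tail_idx <- c(idx_s02, idx_s01, idx_s04)
  log$transfer_ms[tail_idx] <- tails

  # shift non-tail transfer values so the overall mean matches the
  # published transfer mean exactly; same for processing
  target_transfer_mean <- 497.78
  target_processing_mean <- 296.83
  non_tail <- setdiff(seq_len(n_total), tail_idx)
  delta <- (target_transfer_mean * n_total - sum(log$transfer_ms)) / length(non_tail)
  log$transfer_ms[non_tail] <- log$transfer_ms[non_tail] + delta
  log$processing_ms <- pmin(pmax(log$processing_ms, 5), 478)
  log$processing_ms <- log$processing_ms +
    (target_processing_mean - mean(log$processing_ms))
  log
}

fixture_grid <- function() {
  design <- localizer_design(task_blocks = 4L)
  model <- participant_model(noise_sd = 0.2)
  active <- as.matrix(expand.grid(x = 2:3, y = 2:3, z = 1L))
  sim <- simulate_localizer_grid(model, design, grid_shape = c(4L, 4L, 2L),
                                 active_voxels = active,
                                 seed = derive_seed(20260130L, "grid"))
  dims <- dim(sim$grid)
  flat <- matrix(sim$grid, nrow = prod(dims[1:3]))
  coords <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                                  z = seq_len(dims[3])))
  df <- data.frame(coords, active = as.vector(sim$truth_mask),
                   round(flat, 4))
  names(df)[-(1:4)] <- paste0("t", seq_len(dims[4]) - 1L)
  df
}
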