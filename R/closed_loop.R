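#' Simulate one neurofeedback run as a closed loop
#'
#' Advances the session TR by TR: the participant's effort at each
#' regulation TR is corrected using the display state of the previous TR
#' (\code{\link{effort_trace}} stepping rule), the effort history is pushed
#' through the hemodynamic forward model of \code{\link{simulate_bold}},
#' and the feedback chain (baseline reference, percent signal change,
#' normalization, display mapping) produces the next display state. After
#' each block's outcome phase the block is classified and — only on
#' success — the participant's set-point and effort noise are updated with
#' the modality's learning rate.
#'
#' Effort is zero outside regulation windows. Each block's percent signal
#' change is referenced to the mean of its own immediately preceding
#' baseline window. A TR whose baseline reference is non-positive is
#' flagged invalid and the display holds the last valid state; held values
#' still count toward classification.
#'
#' @param model a \code{\link{participant_model}}.
#' @param schedule an \code{nfb_schedule} with TR windows filled.
#' @param cal a \code{\link{calibration_info}}.
#' @param config the \code{\link{session_config}} of the schedule.
#' @param scoring a \code{\link{scoring_config}}.
#' @param levels target level table.
#' @param seed integer seed for the run's noise and behavior streams.
#' @param state participant behavioral state from a previous run (as
#'   returned in the output), so learning carries across runs; NULL starts
#'   a fresh state with set-points at the level midpoints.
#' @param baseline_raw raw intensity about which the simulated percent
#'   signal fluctuates.
#' @return list with \code{samples} (one row per regulation TR:
#'   \code{tr_index}, \code{block_index}, \code{modality},
#'   \code{cued_level}, \code{raw_value}, \code{psc}, \code{s_value},
#'   \code{display_level}, \code{display_fraction}, \code{held}),
#'   \code{outcomes} (one row per block), \code{trace} (full raw series)
#'   and \code{state} (updated behavioral state).
#' @export
run_closed_loop <- function(model, schedule, cal,
                            config = session_config(),
                            scoring = scoring_config(),
                            levels = target_levels(),
                            seed = NULL, state = NULL,
                            baseline_raw = 100) {
  stopifnot(inherits(model, "nfb_participant_model"),
            inherits(schedule, "nfb_schedule"),
            inherits(cal, "nfb_calibration"))
  n_trs <- schedule$total_trs
  blocks <- schedule$blocks
  if (is.null(state)) state <- init_participant_state(model, cal, levels)

  kern <- hrf_kernel(config$tr_seconds, model$hrf_peak_s, model$hrf_undershoot_s)
  klen <- length(kern)

  with_seed(seed, {
    drift <- model$drift_slope * (seq_len(n_trs) - 1)
    noise <- ar1_noise(n_trs, model$ar_phi, model$noise_sd)

    effort <- numeric(n_trs)
    raw <- numeric(n_trs)
    # per-regulation-TR records, filled block by block
    rec <- vector("list", nrow(blocks))
    outcomes <- vector("list", nrow(blocks))

    compute_raw <- function(t) {
      lo <- max(1L, t - klen + 1L)
      idx <- t:lo
      baseline_raw + model$gain * sum(kern[seq_along(idx)] * effort[idx]) +
        drift[t] + noise[t]
    }

    t <- 1L
    for (bi in seq_len(nrow(blocks))) {
      blk <- blocks[bi, ]
      # stabilization (first block only) + baseline: rest
      while (t <= blk$regulation_start) {
        raw[t] <- compute_raw(t)
        t <- t + 1L
      }
      base_ref <- baseline_mean(raw, blk)

      mid <- level_midpoint(blk$cued_level, levels)
      rate <- switch(blk$modality,
                     cFB = model$tracking_rate_cFB,
                     aFB = model$tracking_rate_aFB,
                     noFB = model$tracking_rate_noFB)
      sp <- state$set_point[blk$modality, as.character(blk$cued_level)]
      eff_now <- max(0, sp + stats::rnorm(1, 0, state$effort_noise_sd[blk$modality]))

      n_reg <- blk$regulation_end - blk$regulation_start
      s_vals <- numeric(n_reg)
      psc_vals <- numeric(n_reg)
      raw_vals <- numeric(n_reg)
      disp_lv <- rep(NA_integer_, n_reg)
      disp_fr <- rep(NA_real_, n_reg)
      held <- logical(n_reg)
      eff_vals <- numeric(n_reg)
      last_s <- 0  # display state entering the block is the empty/neutral one

      for (j in seq_len(n_reg)) {
        effort[t] <- eff_now
        eff_vals[j] <- eff_now
        raw[t] <- compute_raw(t)
        raw_vals[j] <- raw[t]
        if (base_ref > 0) {
          psc_vals[j] <- percent_signal_change(raw[t], base_ref)
          s_vals[j] <- normalize_feedback(psc_vals[j], cal)
        } else {
          psc_vals[j] <- NA_real_
          s_vals[j] <- last_s   # hold last valid state
          held[j] <- TRUE
        }
        dm <- map_display(s_vals[j], blk$modality, levels)
        disp_lv[j] <- dm$display_level
        disp_fr[j] <- dm$display_fraction
        # participant reacts to this TR's display when choosing the next effort
        err <- if (blk$modality == "cFB") {
          (s_vals[j] - mid) / 100
        } else if (blk$modality == "aFB") {
          (dm$display_level - blk$cued_level) / nrow(levels)
        } else 0
        eff_now <- max(0, eff_now - rate * err)
        last_s <- s_vals[j]
        t <- t + 1L
      }

      # outcome phase: rest, outcome cue shown
      while (t <= blk$outcome_end) {
        raw[t] <- compute_raw(t)
        t <- t + 1L
      }

      cls <- classify_block(s_vals, blk$cued_level, levels, scoring)
      if (cls$success) {
        lr <- switch(blk$modality,
                     cFB = model$learning_rate_cFB,
                     aFB = model$learning_rate_aFB,
                     noFB = model$learning_rate_noFB)
        if (lr > 0) {
          state$effort_noise_sd[blk$modality] <-
            (1 - lr) * state$effort_noise_sd[blk$modality]
          lv <- as.character(blk$cued_level)
          state$set_point[blk$modality, lv] <-
            (1 - lr) * state$set_point[blk$modality, lv] + lr * mean(eff_vals)
        }
      }

      rec[[bi]] <- data.frame(
        tr_index = blk$regulation_start + seq_len(n_reg) - 1L,
        block_index = blk$block_index,
        modality = blk$modality,
        cued_level = blk$cued_level,
        raw_value = raw_vals, psc = psc_vals, s_value = s_vals,
        display_level = disp_lv, display_fraction = disp_fr,
        held = held, stringsAsFactors = FALSE)
      outcomes[[bi]] <- data.frame(
        block_index = blk$block_index,
        modality = blk$modality,
        cued_level = blk$cued_level,
        n_hit_trs = cls$n_hit_trs,
        success = cls$success,
        outcome_display = cls$outcome_display,
        stringsAsFactors = FALSE)
    }
    # trailing TRs, if any (none under the default contiguous layout)
    while (t <= n_trs) {
      raw[t] <- compute_raw(t)
      t <- t + 1L
    }

    list(samples = do.call(rbind, rec),
         outcomes = do.call(rbind, outcomes),
         trace = raw,
         state = state)
  })
}

#' Initialize a participant's behavioral state
#'
#' Set-points start at the effort that places the feedback value at each
#' level's band midpoint given the participant's gain and the session
#' calibration; the per-modality effort noise starts at the model's
#' \code{effort_noise_sd}.
#'
#' @param model a \code{\link{participant_model}}.
#' @param cal a \code{\link{calibration_info}}.
#' @param levels target level table.
#' @param modalities modalities tracked in the state.
#' @return list with \code{set_point} (modality x level matrix) and
#'   \code{effort_noise_sd} (named per-modality vector).
#' @export
init_participant_state <- function(model, cal, levels = target_levels(),
                                   modalities = c("cFB", "aFB", "noFB")) {
  mids <- (levels$range_lo + levels$range_hi) / 2
  # effort such that gain * effort = (mid/100) * calibration max
  sp <- (mids / 100) * cal$localizer_max_percent / model$gain
  set_point <- matrix(rep(sp, each = length(modalities)),
                      nrow = length(modalities),
                      dimnames = list(modalities, as.character(levels$level)))
  list(set_point = set_point,
       effort_noise_sd = stats::setNames(
         rep(model$effort_noise_sd, length(modalities)), modalities))
}

#' Simulate a full multi-run session for one participant
#'
#' Runs \code{config$runs_per_session} closed-loop runs back to back,
#' carrying the participant's learned state across runs.
#'
#' @inheritParams run_closed_loop
#' @param participant_id participant label used for schedule seeds.
#' @param run_seed_master master seed; each run derives its own stream.
#' @return named list of per-run \code{\link{run_closed_loop}} results.
#' @export
run_session <- function(model, cal, config = session_config(),
                        scoring = scoring_config(),
                        levels = target_levels(),
                        participant_id = "S01", run_seed_master = 1L) {
  state <- NULL
  out <- vector("list", config$runs_per_session)
  names(out) <- paste0("run", seq_len(config$runs_per_session))
  for (r in seq_len(config$runs_per_session)) {
    sched <- make_schedule(config, participant_id, r)
    res <- run_closed_loop(model, sched, cal, config, scoring, levels,
                           seed = derive_seed(run_seed_master, "loop",
                                              participant_id, r),
                           state = state)
    state <- res$state
    res$outcomes$participant_id <- participant_id
    res$outcomes$run_id <- r
    res$samples$participant_id <- participant_id
    res$samples$run_id <- r
    out[[r]] <- res
  }
  out
}
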