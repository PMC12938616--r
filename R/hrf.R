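#' Double-gamma hemodynamic response kernel sampled at the TR
#'
#' Canonical double-gamma HRF: a gamma density peaking at
#' \code{peak_s} minus a gamma density peaking at \code{undershoot_s}
#' scaled by \code{undershoot_ratio}. The discrete kernel is normalized to
#' unit sum, so convolving a sustained unit input yields a plateau of
#' exactly 1 — the participant's \code{gain} then carries all amplitude
#' information.
#'
#' @param tr_seconds sampling interval (s).
#' @param peak_s response peak delay (s).
#' @param undershoot_s undershoot delay (s).
#' @param undershoot_ratio relative undershoot amplitude.
#' @param duration_s kernel support length (s).
#' @return numeric kernel, first element at lag 0.
#' @export
hrf_kernel <- function(tr_seconds = 2.0, peak_s = 6.0, undershoot_s = 16.0,
                       undershoot_ratio = 1 / 6, duration_s = 32.0) {
  stopifnot(tr_seconds > 0, peak_s > 0, undershoot_s > peak_s)
  t <- seq(0, duration_s, by = tr_seconds)
  # gamma(shape = d + 1, rate = 1) has its mode at delay d
  h <- stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_s + 1, rate = 1)
  h / sum(h)
}

# AR(1) noise with innovation SD `sd` and coefficient `phi`; the first
# sample is drawn from the stationary distribution.
ar1_noise <- function(n, phi, sd) {
  if (sd == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd)
  if (phi == 0) return(innov)
  innov[1] <- stats::rnorm(1, 0, sd / sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive", init = 0))
}

#' Forward-simulate an ROI BOLD trace from a per-TR effort series
#'
#' The neural input \code{gain * effort} is convolved with the double-gamma
#' kernel of \code{\link{hrf_kernel}}, then linear drift and AR(1) Gaussian
#' noise are added. Output is in percent-signal units about a baseline of 0.
#'
#' @param effort per-TR effort values (length \code{n_trs}).
#' @param model a \code{\link{participant_model}}.
#' @param n_trs number of TRs; must equal \code{length(effort)}.
#' @param tr_seconds sampling interval (s).
#' @param seed integer seed for the noise stream (NULL: current RNG state).
#' @return numeric trace of length \code{n_trs}.
#' @export
simulate_bold <- function(effort, model, n_trs = length(effort),
                          tr_seconds = 2.0, seed = NULL) {
  stopifnot(length(effort) == n_trs)
  k <- hrf_kernel(tr_seconds, model$hrf_peak_s, model$hrf_undershoot_s)
  signal <- convolve_causal(model$gain * effort, k)
  with_seed(seed, {
    drift <- model$drift_slope * (seq_len(n_trs) - 1)
    signal + drift + ar1_noise(n_trs, model$ar_phi, model$noise_sd)
  })
}

# Causal discrete convolution truncated to the input length.
convolve_causal <- function(x, k) {
  n <- length(x)
  if (n == 0) return(numeric(0))
  out <- stats::convolve(x, rev(k), type = "open")[seq_len(n)]
  as.numeric(out)
}

#' Open-loop effort trace for one block
#'
#' Reconstructs the within-block effort dynamics given an already observed
#' feedback stream: effort starts at \code{start_effort} and each subsequent
#' TR is corrected by the modality's tracking rate times the perceived
#' error. Perceived error is \code{(S - target midpoint)/100} for continuous
#' feedback, \code{(displayed level - cued level)/n_levels} for categorical
#' feedback, and 0 for the no-feedback condition. The same stepping rule
#' drives the closed-loop simulator (\code{\link{run_closed_loop}}), where
#' the feedback stream is produced online.
#'
#' @param model a \code{\link{participant_model}}.
#' @param modality \code{"cFB"}, \code{"aFB"} or \code{"noFB"}.
#' @param cued_level cued target level.
#' @param feedback per-TR feedback stream: \code{s_value}s for cFB,
#'   displayed levels for aFB, ignored for noFB. Element \code{t} is the
#'   display the participant saw before choosing effort at TR \code{t+1}.
#' @param n_trs number of regulation TRs.
#' @param start_effort initial effort (the block's set-point draw).
#' @param levels target level table from \code{\link{target_levels}}.
#' @return numeric effort vector of length \code{n_trs}.
#' @export
effort_trace <- function(model, modality, cued_level, feedback,
                         n_trs = 12L, start_effort, levels = target_levels()) {
  rate <- switch(modality,
                 cFB = model$tracking_rate_cFB,
                 aFB = model$tracking_rate_aFB,
                 noFB = model$tracking_rate_noFB,
                 stop("unknown modality: ", modality, call. = FALSE))
  mid <- level_midpoint(cued_level, levels)
  eff <- numeric(n_trs)
  eff[1] <- start_effort
  for (t in seq_len(n_trs - 1L)) {
    err <- if (modality == "cFB") {
      (feedback[t] - mid) / 100
    } else if (modality == "aFB") {
      (feedback[t] - cued_level) / nrow(levels)
    } else 0
    eff[t + 1L] <- max(0, eff[t] - rate * err)
  }
  eff
}

# Midpoint of a level's display range (level 3 spans [70, 100] on the
# clipped scale).
level_midpoint <- function(level, levels = target_levels()) {
  row <- levels[levels$level == level, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown level: ", level, call. = FALSE)
  (row$range_lo + row$range_hi) / 2
}

#' Simulate a small voxel-grid localizer acquisition
#'
#' Active voxels carry the HRF-convolved task boxcar scaled by the
#' participant's gain; every voxel carries independent AR(1) noise. Values
#' are raw intensities about a baseline of \code{baseline_raw}, suitable for
#' the streaming GLM and percent-signal-change calibration.
#'
#' @param model a \code{\link{participant_model}}.
#' @param design a \code{\link{localizer_design}}.
#' @param grid_shape integer vector of three dimensions.
#' @param active_voxels integer matrix (n x 3) of 1-based active-voxel
#'   coordinates.
#' @param seed integer seed.
#' @param baseline_raw raw baseline intensity added to every voxel.
#' @return list with \code{grid} (4D array, last dim = time),
#'   \code{truth_mask} (logical 3D array) and \code{labels} (per-TR
#'   condition labels).
#' @export
simulate_localizer_grid <- function(model, design, grid_shape = c(4L, 4L, 4L),
                                    active_voxels, seed = NULL,
                                    baseline_raw = 100) {
  labels <- make_localizer_design(design)
  n_trs <- length(labels)
  boxcar <- as.numeric(labels == "task")
  k <- hrf_kernel(design$tr_seconds, model$hrf_peak_s, model$hrf_undershoot_s)
  task_signal <- model$gain * convolve_causal(boxcar, k)

  active_voxels <- as.matrix(active_voxels)
  if (ncol(active_voxels) != 3L) stop("active_voxels must be n x 3", call. = FALSE)
  if (any(active_voxels < 1) ||
      any(sweep(active_voxels, 2, grid_shape, ">"))) {
    stop("active_voxels outside grid", call. = FALSE)
  }
  truth <- array(FALSE, dim = grid_shape)
  truth[active_voxels] <- TRUE

  n_vox <- prod(grid_shape)
  grid <- with_seed(seed, {
    g <- matrix(0, nrow = n_vox, ncol = n_trs)
    for (v in seq_len(n_vox)) {
      g[v, ] <- baseline_raw + ar1_noise(n_trs, model$ar_phi, model$noise_sd)
    }
    g[as.vector(truth), ] <- sweep(g[as.vector(truth), , drop = FALSE],
                                   2, task_signal, `+`)
    array(g, dim = c(grid_shape, n_trs))
  })
  list(grid = grid, truth_mask = truth, labels = labels)
}
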