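#' Behavioral and hemodynamic model of one synthetic participant
#'
#' Describes how a simulated participant converts effort into BOLD signal
#' and how they use the feedback display. Effort is dimensionless and scaled
#' so that sustained effort 1 produces a plateau of \code{gain} percent
#' signal change. Control behavior has three parts: a per-block set-point
#' for each cued level (initialized at the effort that would place the
#' feedback signal at the level's midpoint), per-TR error correction whose
#' strength is the modality-specific tracking rate, and within-session
#' learning that multiplicatively shrinks the participant's effort noise
#' after each successful block at the modality-specific learning rate.
#'
#' @param gain peak percent signal change per unit sustained effort.
#' @param effort_noise_sd SD of the per-block effort set-point perturbation
#'   (dimensionless effort units; 0.01 corresponds to one display point when
#'   the calibration maximum equals \code{gain}).
#' @param tracking_rate_cFB,tracking_rate_aFB,tracking_rate_noFB per-TR
#'   error-correction gains in [0, 1] for the three modalities.
#' @param learning_rate_cFB,learning_rate_aFB,learning_rate_noFB per-block
#'   multiplicative reduction of \code{effort_noise_sd} applied after a
#'   successful block of the given modality, in [0, 1].
#' @param ar_phi lag-1 autoregressive coefficient of the measurement noise.
#' @param noise_sd innovation SD of the AR(1) noise, in percent signal units.
#' @param drift_slope linear drift in percent signal units per TR.
#' @param hrf_peak_s,hrf_undershoot_s hemodynamic response peak and
#'   undershoot delays in seconds.
#' @param field_strength scanner field, \code{"3T"} or \code{"7T"}.
#' @return an object of class \code{nfb_participant_model}.
#' @export
participant_model <- function(gain = 4.0,
                              effort_noise_sd = 0.70,
                              tracking_rate_cFB = 0.05,
                              tracking_rate_aFB = 0.03,
                              tracking_rate_noFB = 0.0,
                              learning_rate_cFB = 0.25,
                              learning_rate_aFB = 0.0,
                              learning_rate_noFB = 0.0,
                              ar_phi = 0.3,
                              noise_sd = 0.30,
                              drift_slope = 0.0,
                              hrf_peak_s = 6.0,
                              hrf_undershoot_s = 16.0,
                              field_strength = "3T") {
  m <- list(gain = gain, effort_noise_sd = effort_noise_sd,
            tracking_rate_cFB = tracking_rate_cFB,
            tracking_rate_aFB = tracking_rate_aFB,
            tracking_rate_noFB = tracking_rate_noFB,
            learning_rate_cFB = learning_rate_cFB,
            learning_rate_aFB = learning_rate_aFB,
            learning_rate_noFB = learning_rate_noFB,
            ar_phi = ar_phi, noise_sd = noise_sd,
            drift_slope = drift_slope,
            hrf_peak_s = hrf_peak_s, hrf_undershoot_s = hrf_undershoot_s,
            field_strength = match.arg(field_strength, c("3T", "7T")))
  class(m) <- "nfb_participant_model"
  validate_participant_model(m)
  m
}

validate_participant_model <- function(m) {
  if (m$gain <= 0) stop("gain must be > 0", call. = FALSE)
  rates <- unlist(m[grep("^(tracking|learning)_rate", names(m))])
  if (any(rates < 0 | rates > 1)) stop("tracking/learning rates must be in [0, 1]", call. = FALSE)
  if (abs(m$ar_phi) >= 1) stop("|ar_phi| must be < 1", call. = FALSE)
  if (m$noise_sd < 0 || m$effort_noise_sd < 0) stop("noise SDs must be >= 0", call. = FALSE)
  invisible(m)
}

#' Cohort sampling specification
#'
#' Defines a synthetic cohort: the number of participants, their assignment
#' to scanner field strengths (default six at 3T and three at 7T), and
#' per-parameter sampling intervals for \code{\link{participant_model}}
#' fields. Ranges default to a spread of hemodynamic gains (peak percent
#' signal change roughly 1.5--4.5) with shared behavioral parameters.
#'
#' @param n_participants cohort size.
#' @param field_assignment character vector of \code{"3T"}/\code{"7T"} per
#'   participant.
#' @param model_ranges named list; each element is a length-2 numeric
#'   interval (or a single value) for a \code{participant_model} field.
#' @param master_seed integer seed for cohort sampling.
#' @return an object of class \code{nfb_cohort_spec}.
#' @export
cohort_spec <- function(n_participants = 9L,
                        field_assignment = c(rep("3T", 6), rep("7T", 3)),
                        model_ranges = list(gain = c(1.5, 4.5)),
                        master_seed = 1L) {
  if (length(field_assignment) != n_participants) {
    stop("field_assignment must have one entry per participant", call. = FALSE)
  }
  bad <- vapply(model_ranges, function(r) {
    !is.numeric(r) || !(length(r) %in% c(1L, 2L)) || anyNA(r) ||
      (length(r) == 2L && r[2] < r[1])
  }, logical(1))
  if (any(bad)) {
    stop("model_ranges entries must be finite length-1 or ordered length-2 numerics",
         call. = FALSE)
  }
  structure(list(n_participants = as.integer(n_participants),
                 field_assignment = as.character(field_assignment),
                 model_ranges = model_ranges,
                 master_seed = as.integer(master_seed)),
            class = "nfb_cohort_spec")
}

#' Sample a cohort of participant models
#'
#' Each participant's parameters are drawn uniformly from the intervals in
#' \code{spec$model_ranges} (point values are used as-is; fields without a
#' range keep the \code{\link{participant_model}} default). Sampling uses a
#' per-participant seed stream derived from the master seed, so the cohort
#' is reproducible and insensitive to generation order.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return named list of \code{nfb_participant_model} objects
#'   (\code{"S01"} ... ).
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "nfb_cohort_spec"))
  ids <- sprintf("S%02d", seq_len(spec$n_participants))
  models <- vector("list", spec$n_participants)
  names(models) <- ids
  for (i in seq_len(spec$n_participants)) {
    draws <- with_seed(derive_seed(spec$master_seed, "cohort", ids[i]), {
      lapply(spec$model_ranges, function(r) {
        if (length(r) == 1L || r[1] == r[2]) r[1] else stats::runif(1, r[1], r[2])
      })
    })
    args <- c(draws, list(field_strength = spec$field_assignment[i]))
    models[[i]] <- do.call(participant_model, args)
  }
  models
}

#' Latency-generating model for per-volume pipeline timing
#'
#' Transfer/reconstruction latency is lognormal (right-skewed), with a rare
#' heavy-tail outlier mechanism: with probability \code{outlier_prob} a
#' volume's transfer latency is replaced by a tail draw above
#' \code{tail_floor_ms}. Processing latency is normal truncated at zero.
#' Defaults are calibrated to a 454 ms transfer median with an
#' interquartile range of about 181 ms, a 297 ms mean processing time, and
#' a per-volume tail probability of 0.36% confined to 7T sessions.
#'
#' @param transfer_log_mu,transfer_log_sigma log-scale location and scale of
#'   the transfer-latency distribution (ms).
#' @param processing_mean_ms,processing_sd_ms processing-time parameters (ms).
#' @param outlier_prob per-volume probability of a heavy-tail transfer event.
#' @param outlier_scale_ms mean of the exponential tail beyond the floor.
#' @param tail_floor_ms lower bound of tail events (ms).
#' @param outlier_fields field strengths whose sessions can produce tail
#'   events (default 7T only).
#' @return an object of class \code{nfb_latency_model}.
#' @export
latency_model <- function(transfer_log_mu = log(454),
                          transfer_log_sigma = 0.294,
                          processing_mean_ms = 296.83,
                          processing_sd_ms = 72.87,
                          outlier_prob = 44 / 12276,
                          outlier_scale_ms = 2500,
                          tail_floor_ms = 2000,
                          outlier_fields = "7T") {
  stopifnot(outlier_prob >= 0, outlier_prob <= 1,
            transfer_log_sigma >= 0, processing_sd_ms >= 0,
            outlier_scale_ms > 0, tail_floor_ms > 0)
  structure(list(transfer_log_mu = transfer_log_mu,
                 transfer_log_sigma = transfer_log_sigma,
                 processing_mean_ms = processing_mean_ms,
                 processing_sd_ms = processing_sd_ms,
                 outlier_prob = outlier_prob,
                 outlier_scale_ms = outlier_scale_ms,
                 tail_floor_ms = tail_floor_ms,
                 outlier_fields = outlier_fields),
            class = "nfb_latency_model")
}

#' Simulate a per-volume latency log
#'
#' @param model a \code{\link{latency_model}}.
#' @param n_volumes number of volumes to draw.
#' @param seed integer seed (NULL leaves the RNG state alone).
#' @param participant_id,field_strength labels carried into the log.
#' @param block_context optional per-volume character vector (e.g. the block
#'   modality, or \code{"none"}); recycled to \code{n_volumes}.
#' @return data frame with columns \code{volume_index}, \code{transfer_ms},
#'   \code{processing_ms}, \code{participant_id}, \code{field_strength},
#'   \code{block_context}.
#' @export
simulate_latency_log <- function(model, n_volumes, seed = NULL,
                                 participant_id = "S01",
                                 field_strength = "3T",
                                 block_context = "none") {
  stopifnot(inherits(model, "nfb_latency_model"), n_volumes > 0)
  with_seed(seed, {
    transfer <- stats::rlnorm(n_volumes, model$transfer_log_mu,
                              model$transfer_log_sigma)
    if (model$outlier_prob > 0 && field_strength %in% model$outlier_fields) {
      hit <- stats::runif(n_volumes) < model$outlier_prob
      n_hit <- sum(hit)
      if (n_hit > 0) {
        transfer[hit] <- model$tail_floor_ms +
          stats::rexp(n_hit, rate = 1 / model$outlier_scale_ms)
      }
    }
    processing <- stats::rnorm(n_volumes, model$processing_mean_ms,
                               model$processing_sd_ms)
    processing <- pmax(processing, 0)  # truncate at zero
    data.frame(volume_index = seq_len(n_volumes) - 1L,
               transfer_ms = transfer,
               processing_ms = processing,
               participant_id = participant_id,
               field_strength = field_strength,
               block_context = rep_len(as.character(block_context), n_volumes),
               stringsAsFactors = FALSE)
  })
}
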