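#' Target level table of the feedback display
#'
#' Three a priori target bands on the normalized 0--100 display scale:
#' level 1 (weak) 10--40, level 2 (medium) 40--70, level 3 (strong) 70 and
#' above. Bands are left-closed and right-open; level 3 is closed at 100
#' because the display scale clips there.
#'
#' @return data frame with columns \code{level}, \code{range_lo},
#'   \code{range_hi}.
#' @export
target_levels <- function() {
  data.frame(level = 1:3,
             range_lo = c(10, 40, 70),
             range_hi = c(40, 70, 100))
}

#' Display calibration from the localizer maximum
#'
#' @param localizer_max_percent percent signal change mapped to 100 on the
#'   display scale; must be strictly positive.
#' @return an object of class \code{nfb_calibration}.
#' @export
calibration_info <- function(localizer_max_percent) {
  if (!is.numeric(localizer_max_percent) || localizer_max_percent <= 0) {
    stop("localizer_max_percent must be strictly positive", call. = FALSE)
  }
  structure(list(localizer_max_percent = localizer_max_percent),
            class = "nfb_calibration")
}

#' Block success scoring configuration
#'
#' A block is successful when at least \code{hit_fraction} of its counted
#' regulation TRs are hits. Under the default \code{met_or_exceeded} rule a
#' TR is a hit when the feedback value reaches the cued level's lower bound
#' or more; under \code{within_range} the value must lie inside the cued
#' band. \code{grace_trs} initial regulation TRs may be excluded from
#' counting to discount the hemodynamic rise; the default of 0 keeps the
#' literal 12-TR rule.
#'
#' @param hit_fraction fraction of counted TRs that must be hits.
#' @param regulation_trs regulation TRs per block.
#' @param hit_rule \code{"met_or_exceeded"} or \code{"within_range"}.
#' @param grace_trs initial regulation TRs excluded from hit counting.
#' @return an object of class \code{nfb_scoring_config}.
#' @export
scoring_config <- function(hit_fraction = 0.5, regulation_trs = 12L,
                           hit_rule = c("met_or_exceeded", "within_range"),
                           grace_trs = 0L) {
  stopifnot(hit_fraction > 0, hit_fraction <= 1, regulation_trs > 0,
            grace_trs >= 0, grace_trs < regulation_trs)
  structure(list(hit_fraction = hit_fraction,
                 regulation_trs = as.integer(regulation_trs),
                 hit_rule = match.arg(hit_rule),
                 grace_trs = as.integer(grace_trs)),
            class = "nfb_scoring_config")
}

#' Mean of a block's baseline window
#'
#' @param series numeric ROI time series (one value per TR, 0-based TR
#'   index \code{t} stored at position \code{t + 1}).
#' @param block one row of a schedule's \code{blocks} table (needs
#'   \code{baseline_start}, \code{baseline_end}).
#' @return arithmetic mean over the half-open baseline window.
#' @export
baseline_mean <- function(series, block) {
  s <- block$baseline_start
  e <- block$baseline_end
  if (is.na(s) || is.na(e) || s < 0 || e > length(series) || e <= s) {
    stop("baseline window out of range for the supplied series", call. = FALSE)
  }
  mean(series[(s + 1):e])
}

#' Percent signal change relative to a baseline value
#'
#' @param raw raw ROI mean at the current TR.
#' @param baseline baseline reference value; must be strictly positive.
#' @return \code{100 * (raw - baseline) / baseline}.
#' @export
percent_signal_change <- function(raw, baseline) {
  if (any(baseline <= 0)) {
    stop("baseline must be strictly positive for percent signal change",
         call. = FALSE)
  }
  100 * (raw - baseline) / baseline
}

#' Normalize percent signal change to the 0--100 display scale
#'
#' The calibration maximum maps to 100; values beyond the scale are clipped
#' to [0, 100] (negative signal change shows as an empty display).
#'
#' @param psc percent signal change.
#' @param cal a \code{\link{calibration_info}}.
#' @return normalized feedback value(s) in [0, 100].
#' @export
normalize_feedback <- function(psc, cal) {
  stopifnot(inherits(cal, "nfb_calibration"))
  pmin(100, pmax(0, 100 * psc / cal$localizer_max_percent))
}

#' Map a normalized feedback value to its display state
#'
#' Continuous feedback shows a bar filled to \code{s_value/100};
#' categorical feedback shows one of four faces: level 0 (neutral) below
#' the level-1 band, then levels 1--3 at the band boundaries (left-closed
#' at 10/40/70); the no-feedback condition shows a static cross.
#'
#' @param s_value normalized feedback value(s) in [0, 100].
#' @param modality \code{"cFB"}, \code{"aFB"} or \code{"noFB"}.
#' @param levels target level table.
#' @return data frame with \code{display_level} (integer, NA for noFB) and
#'   \code{display_fraction} (bar fill, NA unless cFB).
#' @export
map_display <- function(s_value, modality, levels = target_levels()) {
  if (any(s_value < 0 | s_value > 100)) {
    stop("s_value must be in [0, 100]", call. = FALSE)
  }
  n <- length(s_value)
  out <- data.frame(display_level = rep(NA_integer_, n),
                    display_fraction = rep(NA_real_, n))
  if (modality == "cFB") {
    out$display_fraction <- s_value / 100
    out$display_level <- display_level_of(s_value, levels)
  } else if (modality == "aFB") {
    out$display_level <- display_level_of(s_value, levels)
  } else if (modality != "noFB") {
    stop("unknown modality: ", modality, call. = FALSE)
  }
  out
}

# Step function with boundaries at the band lower bounds; values below the
# level-1 band map to the neutral level 0.
display_level_of <- function(s_value, levels = target_levels()) {
  lo <- levels$range_lo[order(levels$level)]
  findInterval(s_value, lo)
}

#' Classify success of one block from its regulation samples
#'
#' A TR is a hit when its feedback value meets or exceeds the cued level's
#' lower bound (default rule) or lies within the cued band
#' (\code{within_range} rule). The block succeeds when the number of hits
#' among counted TRs reaches
#' \code{ceiling(hit_fraction * n_counted)} — 6 of 12 for the defaults.
#'
#' @param samples numeric vector of regulation-window \code{s_value}s, or a
#'   data frame with an \code{s_value} column; length must equal
#'   \code{scoring$regulation_trs}.
#' @param cued_level cued target level.
#' @param levels target level table.
#' @param scoring a \code{\link{scoring_config}}.
#' @return list with \code{n_hit_trs}, \code{success},
#'   \code{outcome_display} (\code{"green"}/\code{"red"}),
#'   \code{n_counted_trs} and \code{required_hits}.
#' @export
classify_block <- function(samples, cued_level, levels = target_levels(),
                           scoring = scoring_config()) {
  s <- if (is.data.frame(samples)) samples$s_value else samples
  if (length(s) != scoring$regulation_trs) {
    stop(sprintf("expected %d regulation samples, got %d",
                 scoring$regulation_trs, length(s)), call. = FALSE)
  }
  if (scoring$grace_trs > 0) s <- s[-seq_len(scoring$grace_trs)]
  row <- levels[levels$level == cued_level, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown cued level: ", cued_level, call. = FALSE)
  hits <- if (scoring$hit_rule == "met_or_exceeded") {
    s >= row$range_lo
  } else {
    in_target_range(s, row, levels)
  }
  n_counted <- length(s)
  required <- ceiling(scoring$hit_fraction * n_counted)
  n_hit <- sum(hits)
  list(n_hit_trs = n_hit,
       success = n_hit >= required,
       outcome_display = if (n_hit >= required) "green" else "red",
       n_counted_trs = n_counted,
       required_hits = required)
}

# Within-range membership; the top band has no active upper boundary on the
# clipped scale (s <= 100 always).
in_target_range <- function(s, row, levels = target_levels()) {
  if (row$level == max(levels$level)) {
    s >= row$range_lo
  } else {
    s >= row$range_lo & s < row$range_hi
  }
}
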