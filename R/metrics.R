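#' Per-TR distance to the cued target range
#'
#' 0 when the feedback value lies within the cued band (left-closed,
#' right-open; the top band is open above because the display clips at
#' 100), otherwise the absolute distance to the nearest band boundary.
#'
#' @param s_values numeric vector of feedback values in [0, 100].
#' @param cued_level cued target level.
#' @param levels target level table.
#' @return numeric vector of non-negative distances.
#' @export
distance_to_range <- function(s_values, cued_level, levels = target_levels()) {
  row <- levels[levels$level == cued_level, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown cued level: ", cued_level, call. = FALSE)
  inside <- in_target_range(s_values, row, levels)
  top <- row$level == max(levels$level)
  d_lo <- abs(s_values - row$range_lo)
  d <- if (top) d_lo else pmin(d_lo, abs(s_values - row$range_hi))
  ifelse(inside, 0, d)
}

#' Occupancy and distance-to-range summaries of one block
#'
#' Occupancy is the fraction of regulation TRs whose feedback value lies
#' within the cued band (within-range semantics, regardless of the success
#' hit rule); distance-to-range is summarized by its median (precision) and
#' its n-1 standard deviation (stability).
#'
#' @param s_values regulation-window feedback values (length
#'   \code{scoring$regulation_trs}).
#' @param cued_level cued target level.
#' @param scoring a \code{\link{scoring_config}} (supplies the expected TR
#'   count).
#' @param levels target level table.
#' @return list with \code{occupancy}, \code{dist_median}, \code{dist_sd},
#'   \code{distances}.
#' @export
block_metrics <- function(s_values, cued_level, scoring = scoring_config(),
                          levels = target_levels()) {
  if (length(s_values) != scoring$regulation_trs) {
    stop(sprintf("expected %d regulation samples, got %d",
                 scoring$regulation_trs, length(s_values)), call. = FALSE)
  }
  d <- distance_to_range(s_values, cued_level, levels)
  list(occupancy = mean(d == 0),
       dist_median = stats::median(d),
       dist_sd = stats::sd(d),
       distances = d)
}

#' Aggregate block outcomes into cell summaries
#'
#' One row per grouping cell with block counts, success counts and the
#' success rate in percent (full precision; round only for display). When
#' per-block metrics are supplied their means are carried along.
#'
#' @param outcomes data frame with one row per block, containing a logical
#'   \code{success} column plus the grouping columns.
#' @param by character vector of grouping column names.
#' @param metrics optional data frame aligned with \code{outcomes} rows,
#'   with columns \code{occupancy}, \code{dist_median}, \code{dist_sd}.
#' @return data frame with the grouping columns, \code{n_blocks},
#'   \code{n_success}, \code{success_rate} and, if metrics were given,
#'   \code{mean_occupancy}, \code{mean_dist_median}, \code{mean_dist_sd}.
#' @export
aggregate_performance <- function(outcomes,
                                  by = c("participant_id", "run_id", "modality"),
                                  metrics = NULL) {
  missing_cols <- setdiff(c(by, "success"), names(outcomes))
  if (length(missing_cols) > 0) {
    stop("outcomes lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  keys <- outcomes[by]
  agg <- stats::aggregate(outcomes$success, by = keys,
                          FUN = function(s) c(n = length(s), k = sum(s)))
  out <- agg[by]
  out$n_blocks <- agg$x[, "n"]
  out$n_success <- as.integer(agg$x[, "k"])
  out$success_rate <- 100 * out$n_success / out$n_blocks
  if (!is.null(metrics)) {
    for (col in c("occupancy", "dist_median", "dist_sd")) {
      m <- stats::aggregate(metrics[[col]], by = keys, FUN = mean)
      out[[paste0("mean_", col)]] <- m$x[match(
        do.call(paste, out[by]), do.call(paste, m[by]))]
    }
  }
  out[do.call(order, out[by]), , drop = FALSE]
}

#' Per-participant run-to-run learning deltas
#'
#' Pairs each participant's first- and second-run summaries per modality
#' and reports the success-rate difference (second minus first) in
#' percentage points, with group mean and SD per modality. Participants
#' missing either run are excluded with a warning.
#'
#' @param summaries a cell-summary table from
#'   \code{\link{aggregate_performance}} grouped by participant, run and
#'   modality.
#' @param run_ids length-2 vector identifying the first and second run.
#' @return list with \code{deltas} (participant x modality differences)
#'   and \code{group} (per-modality mean/SD of the deltas).
#' @export
learning_delta <- function(summaries, run_ids = c(1, 2)) {
  need <- c("participant_id", "run_id", "modality", "success_rate")
  missing_cols <- setdiff(need, names(summaries))
  if (length(missing_cols) > 0) {
    stop("summaries lack columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  r1 <- summaries[summaries$run_id == run_ids[1], ]
  r2 <- summaries[summaries$run_id == run_ids[2], ]
  key1 <- paste(r1$participant_id, r1$modality)
  key2 <- paste(r2$participant_id, r2$modality)
  common <- intersect(key1, key2)
  incomplete <- setdiff(union(key1, key2), common)
  if (length(incomplete) > 0) {
    dropped <- unique(vapply(strsplit(incomplete, " "), `[`, "", 1L))
    warning("cells missing a run were excluded (participants: ",
            paste(dropped, collapse = ", "), ")", call. = FALSE)
  }
  i1 <- match(common, key1)
  i2 <- match(common, key2)
  deltas <- data.frame(participant_id = r1$participant_id[i1],
                       modality = r1$modality[i1],
                       rate_run1 = r1$success_rate[i1],
                       rate_run2 = r2$success_rate[i2],
                       delta_pp = r2$success_rate[i2] - r1$success_rate[i1],
                       stringsAsFactors = FALSE)
  grp <- stats::aggregate(deltas$delta_pp, by = deltas["modality"],
                          FUN = function(d) c(mean = mean(d), sd = stats::sd(d)))
  group <- data.frame(modality = grp$modality,
                      mean_delta_pp = grp$x[, "mean"],
                      sd_delta_pp = grp$x[, "sd"],
                      stringsAsFactors = FALSE)
  list(deltas = deltas[order(deltas$modality, deltas$participant_id), ],
       group = group)
}
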