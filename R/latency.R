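#' Summarize a per-volume latency log
#'
#' Computes, per group, the usual location/spread summaries of the
#' transfer and processing latencies (mean, SD, median, quartiles with
#' linear interpolation, IQR, range), a normal-theory 99\% confidence
#' interval for the transfer mean, the count and percentage of volumes
#' whose transfer latency strictly exceeds \code{threshold_ms}, and the
#' end-to-end mean (transfer mean + processing mean). No records are ever
#' dropped from the summaries.
#'
#' @param records latency data frame as produced by
#'   \code{\link{simulate_latency_log}} (columns \code{transfer_ms},
#'   \code{processing_ms}, optionally \code{participant_id},
#'   \code{field_strength}).
#' @param group_by \code{"all"}, \code{"participant"} or
#'   \code{"field_strength"}.
#' @param threshold_ms strict threshold for over-threshold accounting.
#' @return data frame with one row per group.
#' @export
summarize_latency <- function(records, group_by = c("all", "participant",
                                                    "field_strength"),
                              threshold_ms = 2000) {
  group_by <- match.arg(group_by)
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty data frame", call. = FALSE)
  }
  key <- switch(group_by,
                all = rep("all", nrow(records)),
                participant = records$participant_id,
                field_strength = records$field_strength)
  if (is.null(key)) stop("grouping column missing from records", call. = FALSE)
  groups <- split(records, key)
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]$transfer_ms
    p <- groups[[g]]$processing_ms
    n <- length(x)
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    se <- stats::sd(x) / sqrt(n)
    zc <- stats::qnorm(0.995)
    n_over <- sum(x > threshold_ms)
    data.frame(group = g, n = n,
               mean = mean(x), sd = stats::sd(x),
               median = q[2], q1 = q[1], q3 = q[3], iqr = q[3] - q[1],
               min = min(x), max = max(x),
               ci99_lo = mean(x) - zc * se, ci99_hi = mean(x) + zc * se,
               n_over_threshold = n_over,
               pct_over_threshold = 100 * n_over / n,
               processing_mean = mean(p), processing_sd = stats::sd(p),
               end_to_end_mean = mean(x) + mean(p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flag heavy-tail and TR-exceedance latency events
#'
#' A record is a tail outlier when its transfer latency strictly exceeds
#' \code{tail_threshold_ms}, and a TR exceedance when it strictly exceeds
#' the repetition time \code{tr_ms}. Tallies of tail events by block
#' context and by field strength are returned alongside the per-record
#' flags.
#'
#' @param records latency data frame.
#' @param tail_threshold_ms heavy-tail threshold (ms).
#' @param tr_ms repetition time (ms).
#' @return list with \code{records} (input plus logical \code{tail} and
#'   \code{tr_exceeded} columns), \code{n_tail}, \code{pct_tail},
#'   \code{by_context} and \code{by_field} tally tables.
#' @export
flag_latency_outliers <- function(records, tail_threshold_ms = 2000,
                                  tr_ms = 2000) {
  stopifnot(tail_threshold_ms > 0, tr_ms > 0)
  records$tail <- records$transfer_ms > tail_threshold_ms
  records$tr_exceeded <- records$transfer_ms > tr_ms
  tally <- function(col) {
    if (is.null(records[[col]])) return(NULL)
    tab <- table(records[[col]][records$tail])
    data.frame(key = names(tab), n_tail = as.integer(tab),
               stringsAsFactors = FALSE)
  }
  list(records = records,
       n_tail = sum(records$tail),
       pct_tail = 100 * mean(records$tail),
       by_context = tally("block_context"),
       by_field = tally("field_strength"))
}

#' Write / read a latency log as a tab-separated file
#' @param records latency data frame.
#' @param path file path.
#' @return the data frame, invisibly (write) or the data frame (read).
#' @export
write_latency_log <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(records)
}

#' @rdname write_latency_log
#' @export
read_latency_log <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
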