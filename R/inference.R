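#' Exact paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are discarded (Wilcoxon's original procedure; see
#' \code{zero_method}), absolute differences are ranked with mid-ranks for
#' ties, and the test statistic is \eqn{W = \min(W^+, W^-)}. For
#' \code{n_effective <= exact_cutoff} the two-sided p-value is computed
#' from the exact null distribution of the positive rank sum over all
#' \eqn{2^n} sign assignments of the (fixed) ranks, as
#' \eqn{p = \min(1, 2 P(W^+ \le W))}; the distribution is accumulated by
#' dynamic programming over doubled ranks so mid-ranks stay exact. Above
#' the cutoff a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param diffs numeric vector of paired differences.
#' @param exact_cutoff largest effective n for which the exact null
#'   distribution is enumerated.
#' @param zero_method only \code{"discard"} is implemented; the argument
#'   exists so the zero-handling convention is explicit in calling code.
#' @return an object of class \code{nfb_paired_test}: list with
#'   \code{n_input}, \code{n_effective}, \code{w_statistic},
#'   \code{w_plus}, \code{w_minus}, \code{p_two_sided}, \code{method},
#'   \code{degenerate}.
#' @export
wilcoxon_exact <- function(diffs, exact_cutoff = 20L,
                           zero_method = "discard") {
  zero_method <- match.arg(zero_method, "discard")
  stopifnot(is.numeric(diffs), length(diffs) >= 1)
  n_input <- length(diffs)
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0L) {
    return(structure(list(n_input = n_input, n_effective = 0L,
                          w_statistic = 0, w_plus = 0, w_minus = 0,
                          p_two_sided = 1.0, method = "degenerate",
                          degenerate = TRUE),
                     class = "nfb_paired_test"))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  if (n <= exact_cutoff) {
    # exact null distribution of W+ over doubled ranks (integers even with
    # mid-ranks), by convolution
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1)      # counts[s + 1] = #assignments with 2*W+ = s
    counts[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(total + 1 - ri)])
      counts <- counts + shifted
    }
    w2 <- as.integer(round(2 * w))
    p <- min(1, 2 * sum(counts[seq_len(w2 + 1)]) / 2^n)
    method <- "exact"
  } else {
    # normal approximation with tie and continuity corrections
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(z))
    method <- "normal_approx"
  }
  structure(list(n_input = n_input, n_effective = n,
                 w_statistic = w, w_plus = w_plus, w_minus = w_minus,
                 p_two_sided = p, method = method, degenerate = FALSE),
            class = "nfb_paired_test")
}

#' Cohen's dz paired effect size
#'
#' Mean of the paired differences divided by their n-1 standard deviation.
#'
#' @param diffs numeric vector of paired differences (length >= 2).
#' @return numeric effect size.
#' @export
cohens_dz <- function(diffs) {
  stopifnot(is.numeric(diffs), length(diffs) >= 2)
  s <- stats::sd(diffs)
  if (s == 0) stop("zero SD of differences; dz undefined", call. = FALSE)
  mean(diffs) / s
}

#' Friedman rank test for repeated measures
#'
#' Within-subject mid-ranks across conditions;
#' \eqn{\chi^2 = [12/(nk(k+1))] \sum_j R_j^2 - 3n(k+1)}, divided by the
#' tie-correction factor \eqn{1 - \sum (t^3 - t) / (n k (k^2 - 1))} when
#' ties occur. The p-value comes from the \eqn{\chi^2_{k-1}} distribution.
#'
#' @param mat numeric matrix, subjects in rows, conditions in columns.
#' @return an object of class \code{nfb_friedman}: list with \code{chi2},
#'   \code{df}, \code{p}, \code{n_subjects}, \code{k_conditions},
#'   \code{tie_corrected}.
#' @export
friedman_rank_test <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  k <- ncol(mat)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 conditions", call. = FALSE)
  ranks <- t(apply(mat, 1, rank))
  rj <- colSums(ranks)
  chi2 <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  # tie correction across within-subject rank groups
  tie_sum <- 0
  for (i in seq_len(n)) {
    tt <- table(mat[i, ])
    tie_sum <- tie_sum + sum(tt^3 - tt)
  }
  tie_corrected <- tie_sum > 0
  if (tie_corrected) {
    cf <- 1 - tie_sum / (n * k * (k^2 - 1))
    if (cf <= 0) {
      chi2 <- 0    # all values tied within every subject: no information
    } else {
      chi2 <- chi2 / cf
    }
  }
  df <- k - 1
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 n_subjects = n, k_conditions = k,
                 tie_corrected = tie_corrected),
            class = "nfb_friedman")
}

#' Per-modality learning test table
#'
#' For each modality (plus a pooled row across modalities) the table lists
#' the run means and SDs of the per-participant success rates, the mean
#' paired difference (second minus first run, percentage points), Cohen's
#' dz and the two-sided exact Wilcoxon signed-rank p-value.
#'
#' @param summaries cell-summary table from
#'   \code{\link{aggregate_performance}} grouped by participant, run and
#'   modality.
#' @param run_ids length-2 vector identifying the paired runs.
#' @return data frame with one row per modality and a final
#'   \code{"overall"} row.
#' @export
modality_learning_report <- function(summaries, run_ids = c(1, 2)) {
  ld <- learning_delta(summaries, run_ids)
  deltas <- ld$deltas
  mods <- unique(deltas$modality)
  one_row <- function(label, d) {
    dz <- if (length(d$delta_pp) >= 2 && stats::sd(d$delta_pp) > 0) {
      cohens_dz(d$delta_pp)
    } else NA_real_
    wt <- wilcoxon_exact(d$delta_pp)
    data.frame(modality = label,
               n = nrow(d),
               mean_run1 = mean(d$rate_run1), sd_run1 = stats::sd(d$rate_run1),
               mean_run2 = mean(d$rate_run2), sd_run2 = stats::sd(d$rate_run2),
               mean_delta_pp = mean(d$delta_pp),
               cohens_dz = dz,
               p_wilcoxon = wt$p_two_sided,
               stringsAsFactors = FALSE)
  }
  rows <- lapply(mods, function(m) one_row(m, deltas[deltas$modality == m, ]))
  # pooled: per participant, success rate across all modalities per run
  pooled <- stats::aggregate(
    cbind(rate_run1, rate_run2) ~ participant_id, data = deltas, FUN = mean)
  pooled$delta_pp <- pooled$rate_run2 - pooled$rate_run1
  rows <- c(rows, list(one_row("overall", pooled)))
  do.call(rbind, rows)
}
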