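#' Session configuration for a neurofeedback run
#'
#' Encodes the trial structure of one neurofeedback run: each block consists
#' of a baseline phase, a cued regulation phase and a short outcome phase,
#' and a run opens with a stabilization period that is excluded from all
#' scoring. The default values reproduce the standard layout: TR = 2 s,
#' 8-TR stabilization, 8-TR baseline, 12-TR regulation, 2-TR outcome, and
#' 27 blocks per run formed by fully crossing three feedback modalities
#' (continuous \code{cFB}, categorical \code{aFB}, no-feedback \code{noFB})
#' with three cued target levels, three repeats each.
#'
#' @param tr_seconds repetition time in seconds.
#' @param stabilization_trs TRs of the run-initial stabilization baseline.
#' @param baseline_trs TRs of each block's baseline phase.
#' @param regulation_trs TRs of each block's regulation phase.
#' @param outcome_trs TRs of each block's outcome phase.
#' @param blocks_per_run total blocks per run; must equal
#'   \code{length(modalities) * length(levels) * repeats_per_cell}.
#' @param runs_per_session number of neurofeedback runs in a session.
#' @param modalities ordered character vector of feedback modalities.
#' @param levels ordered integer vector of cued target levels.
#' @param repeats_per_cell repeats of each (modality, level) cell per run.
#' @param rng_seed master seed for schedule randomization.
#' @return an object of class \code{nfb_session_config}.
#' @export
session_config <- function(tr_seconds = 2.0,
                           stabilization_trs = 8L,
                           baseline_trs = 8L,
                           regulation_trs = 12L,
                           outcome_trs = 2L,
                           blocks_per_run = 27L,
                           runs_per_session = 2L,
                           modalities = c("cFB", "aFB", "noFB"),
                           levels = 1:3,
                           repeats_per_cell = 3L,
                           rng_seed = 1L) {
  cfg <- list(
    tr_seconds = tr_seconds,
    stabilization_trs = as.integer(stabilization_trs),
    baseline_trs = as.integer(baseline_trs),
    regulation_trs = as.integer(regulation_trs),
    outcome_trs = as.integer(outcome_trs),
    blocks_per_run = as.integer(blocks_per_run),
    runs_per_session = as.integer(runs_per_session),
    modalities = as.character(modalities),
    levels = as.integer(levels),
    repeats_per_cell = as.integer(repeats_per_cell),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "nfb_session_config"
  validate_session_config(cfg)
  cfg
}

validate_session_config <- function(cfg) {
  counts <- c(cfg$stabilization_trs, cfg$baseline_trs, cfg$regulation_trs,
              cfg$outcome_trs, cfg$blocks_per_run, cfg$runs_per_session,
              cfg$repeats_per_cell)
  if (cfg$tr_seconds <= 0) stop("tr_seconds must be positive", call. = FALSE)
  if (cfg$stabilization_trs < 0) stop("stabilization_trs must be >= 0", call. = FALSE)
  if (any(counts[-1] <= 0)) stop("all TR/block counts must be strictly positive", call. = FALSE)
  n_cells <- length(cfg$modalities) * length(cfg$levels) * cfg$repeats_per_cell
  if (cfg$blocks_per_run != n_cells) {
    stop(sprintf(
      "blocks_per_run (%d) must equal |modalities| x |levels| x repeats_per_cell (%d)",
      cfg$blocks_per_run, n_cells), call. = FALSE)
  }
  invisible(cfg)
}

#' TRs per block (baseline + regulation + outcome)
#' @param config a \code{\link{session_config}}.
#' @return integer TR count per block.
#' @export
block_trs <- function(config) {
  config$baseline_trs + config$regulation_trs + config$outcome_trs
}

#' Generate the randomized block schedule of a neurofeedback run
#'
#' Draws the fully crossed (modality, level) cell multiset —
#' \code{repeats_per_cell} copies of each cell — and shuffles it without
#' replacement using a seeded stream derived from
#' \code{(rng_seed, participant_id, run_id)}, so a cohort of schedules is
#' reproducible and independent of generation order. TR windows for the
#' three phases are laid out back-to-back after the stabilization period.
#'
#' @param config a \code{\link{session_config}}.
#' @param participant_id participant label.
#' @param run_id run label (e.g. 1 or 2).
#' @return an object of class \code{nfb_schedule}: a list with
#'   \code{participant_id}, \code{run_id}, \code{blocks} (one row per block
#'   with modality, cued level and half-open 0-based TR windows) and
#'   \code{total_trs}.
#' @export
make_schedule <- function(config, participant_id = "S01", run_id = 1L) {
  validate_session_config(config)
  cells <- expand.grid(modality = config$modalities,
                       cued_level = config$levels,
                       rep = seq_len(config$repeats_per_cell),
                       stringsAsFactors = FALSE)
  ord <- with_seed(derive_seed(config$rng_seed, participant_id, run_id),
                   sample.int(nrow(cells)))
  blocks <- data.frame(
    block_index = seq_len(nrow(cells)) - 1L,
    modality = cells$modality[ord],
    cued_level = as.integer(cells$cued_level[ord]),
    stringsAsFactors = FALSE
  )
  sched <- structure(
    list(participant_id = participant_id, run_id = run_id,
         blocks = blocks, total_trs = NA_integer_),
    class = "nfb_schedule")
  block_windows(config, sched)
}

#' Fill half-open TR windows for every block of a schedule
#'
#' Windows are 0-based and half-open; block phases tile the run contiguously
#' after stabilization, so block \code{b} occupies TRs
#' \code{stabilization + b * (baseline + regulation + outcome)} onward.
#'
#' @param config a \code{\link{session_config}}.
#' @param schedule an \code{nfb_schedule} (windows are recomputed).
#' @return the schedule with window columns and \code{total_trs} filled.
#' @export
block_windows <- function(config, schedule) {
  b <- schedule$blocks
  per_block <- block_trs(config)
  start <- config$stabilization_trs + b$block_index * per_block
  b$baseline_start <- start
  b$baseline_end <- start + config$baseline_trs
  b$regulation_start <- b$baseline_end
  b$regulation_end <- b$regulation_start + config$regulation_trs
  b$outcome_start <- b$regulation_end
  b$outcome_end <- b$outcome_start + config$outcome_trs
  schedule$blocks <- b
  schedule$total_trs <- config$stabilization_trs +
    nrow(b) * per_block
  schedule
}

#' Localizer run design
#'
#' Alternating rest/task block design of the pre-session localizer used to
#' define the feedback ROI: task blocks of finger tapping alternate with
#' fixation rest blocks, beginning and ending with rest.
#'
#' @param task_blocks number of task blocks.
#' @param task_trs TRs per task block.
#' @param rest_trs TRs per rest block.
#' @param tr_seconds repetition time in seconds.
#' @return an object of class \code{nfb_localizer_design}.
#' @export
localizer_design <- function(task_blocks = 10L, task_trs = 5L,
                             rest_trs = 10L, tr_seconds = 2.0) {
  stopifnot(task_blocks > 0, task_trs > 0, rest_trs > 0, tr_seconds > 0)
  structure(list(task_blocks = as.integer(task_blocks),
                 task_trs = as.integer(task_trs),
                 rest_trs = as.integer(rest_trs),
                 tr_seconds = tr_seconds),
            class = "nfb_localizer_design")
}

#' Per-TR condition labels of the localizer design
#'
#' @param design a \code{\link{localizer_design}}.
#' @return character vector of per-TR labels (\code{"rest"}/\code{"task"}),
#'   beginning and ending with a rest block, of length
#'   \code{task_blocks * task_trs + (task_blocks + 1) * rest_trs}.
#' @export
make_localizer_design <- function(design) {
  labs <- rep("rest", design$rest_trs)
  for (i in seq_len(design$task_blocks)) {
    labs <- c(labs, rep("task", design$task_trs), rep("rest", design$rest_trs))
  }
  labs
}

#' Write a schedule as a BIDS-style events table
#'
#' One row per block phase with columns \code{onset} (s), \code{duration}
#' (s), \code{trial_type} (baseline/regulation/outcome), \code{modality},
#' \code{cued_level}, \code{block_index}.
#'
#' @param schedule an \code{nfb_schedule}.
#' @param config the \code{\link{session_config}} used to build it.
#' @param path output path of the tab-separated file.
#' @return the events data frame, invisibly.
#' @export
write_events <- function(schedule, config, path) {
  ev <- events_table(schedule, config)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ev)
}

#' @rdname write_events
#' @export
events_table <- function(schedule, config) {
  b <- schedule$blocks
  tr <- config$tr_seconds
  phase <- function(type, s, e) data.frame(
    onset = s * tr, duration = (e - s) * tr, trial_type = type,
    modality = b$modality, cued_level = b$cued_level,
    block_index = b$block_index, stringsAsFactors = FALSE)
  ev <- rbind(phase("baseline", b$baseline_start, b$baseline_end),
              phase("regulation", b$regulation_start, b$regulation_end),
              phase("outcome", b$outcome_start, b$outcome_end))
  ev[order(ev$onset), , drop = FALSE]
}

#' Read a BIDS-style events table written by \code{\link{write_events}}
#' @param path path to the events.tsv file.
#' @return data frame of events.
#' @export
read_events <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
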