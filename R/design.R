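#' Study design parameters
#'
#' Holds the trial structure of the visual detection task. The two presets
#' mirror the two experiments the simulator emulates: `study1` has 43 subjects
#' and two load levels (low, high) alternating over 8 blocks; `study2` has 45
#' subjects and four conditions (no, low, high, very_high) over 16 blocks.
#' Each block presents 360 trials of 500 ms each (20% targets, i.e. 72 targets
#' and 288 nontargets), preceded by 7 lead-in nontarget trials, with the
#' amplitude-modulated tone starting 200 ms before the first trial.
#'
#' @param study `"study1"` or `"study2"` preset, or `NULL` with explicit fields.
#' @param n_subjects number of subjects.
#' @param conditions ordered condition labels.
#' @param blocks_per_condition blocks per condition.
#' @param trials_per_block trials per block (after the lead-in).
#' @param trial_period_s trial onset asynchrony in seconds.
#' @param stim_duration_s visual stimulus duration in seconds.
#' @param target_fraction fraction of target trials.
#' @param lead_in_nontargets extra nontarget trials at block start.
#' @param min_gap,max_gap minimum / maximum number of nontarget trials between
#'   consecutive targets.
#' @param tone_lead_s tone onset lead before the first trial, seconds.
#' @return an object of class `study_design`.
#' @export
study_design <- function(study = c("study1", "study2"), n_subjects = NULL,
                         conditions = NULL, blocks_per_condition = 4,
                         trials_per_block = 360, trial_period_s = 0.5,
                         stim_duration_s = 0.1, target_fraction = 0.2,
                         lead_in_nontargets = 7, min_gap = 2, max_gap = 6,
                         tone_lead_s = 0.2) {
  study <- match.arg(study)
  if (is.null(conditions))
    conditions <- if (study == "study1") c("low", "high")
                  else c("no", "low", "high", "very_high")
  if (is.null(n_subjects)) n_subjects <- if (study == "study1") 43L else 45L
  n_targets <- target_fraction * trials_per_block
  if (abs(n_targets - round(n_targets)) > 1e-9)
    stop("target_fraction * trials_per_block must be an integer", call. = FALSE)
  structure(
    list(study = study, n_subjects = as.integer(n_subjects),
         conditions = conditions,
         blocks_per_condition = as.integer(blocks_per_condition),
         trials_per_block = as.integer(trials_per_block),
         trial_period_s = trial_period_s, stim_duration_s = stim_duration_s,
         target_fraction = target_fraction,
         lead_in_nontargets = as.integer(lead_in_nontargets),
         min_gap = as.integer(min_gap), max_gap = as.integer(max_gap),
         tone_lead_s = tone_lead_s),
    class = "study_design")
}

#' Generate one block's event table
#'
#' Places exactly `target_fraction * trials_per_block` targets among the
#' trials so that consecutive targets are separated by `min_gap` to `max_gap`
#' nontarget trials, prepends the lead-in nontargets, and embeds the tone
#' onset `tone_lead_s` before the first trial. The passive-viewing condition
#' (`"no"`) contains no targets. Gap lengths are drawn uniformly and
#' re-drawn until the block length constraint is satisfied; leftover nontarget
#' trials are split randomly between the head and tail of the block.
#'
#' @param design a [study_design()].
#' @param condition condition label; `"no"` yields zero targets.
#' @param seed integer seed; the sequence is a pure function of
#'   `(design, condition, seed)`.
#' @param fs sampling rate used to convert onset times to sample indices.
#' @return a `data.frame` with columns `onset_sample` (1-based), `time_s`, and
#'   `code` (one of `tone_onset`, `stim_target`, `stim_nontarget`), sorted by
#'   onset.
#' @export
generate_event_sequence <- function(design, condition, seed, fs = 1024) {
  stopifnot(inherits(design, "study_design"))
  nt <- design$trials_per_block
  n_targets <- if (identical(condition, "no")) 0L
               else as.integer(round(design$target_fraction * nt))
  if (n_targets > 0 &&
      (n_targets - 1) * design$min_gap + n_targets > nt)
    stop("gap constraints infeasible for requested target count", call. = FALSE)

  cond_idx <- match(condition, design$conditions)
  if (is.na(cond_idx)) cond_idx <- 0L
  is_target <- with_seed(derive_seed(seed, cond_idx), {
    flags <- rep(FALSE, nt)
    if (n_targets > 0) {
      repeat {
        gaps <- sample(design$min_gap:design$max_gap, n_targets - 1, replace = TRUE)
        spare <- (nt - n_targets) - sum(gaps)
        if (spare >= 0) break
      }
      head_n <- sample.int(spare + 1L, 1L) - 1L
      pos <- head_n + 1L + cumsum(c(0L, gaps + 1L))
      flags[pos] <- TRUE
    }
    flags
  })

  trial_times <- design$tone_lead_s +
    (seq_len(design$lead_in_nontargets + nt) - 1) * design$trial_period_s
  codes <- c(rep("stim_nontarget", design$lead_in_nontargets),
             ifelse(is_target, "stim_target", "stim_nontarget"))
  ev <- data.frame(
    time_s = c(0, trial_times),
    code = c("tone_onset", codes),
    stringsAsFactors = FALSE)
  ev$onset_sample <- round(ev$time_s * fs) + 1L
  ev[order(ev$onset_sample), c("onset_sample", "time_s", "code")]
}

#' Decode target/nontarget counts from an event table
#'
#' @param events event table as returned by [generate_event_sequence()].
#' @param drop_lead_in if `TRUE` (default) the lead-in nontarget trials are not
#'   counted, matching how behaviour is scored.
#' @param lead_in number of lead-in trials to drop.
#' @return named integer vector with elements `targets` and `nontargets`.
#' @export
event_counts <- function(events, drop_lead_in = TRUE, lead_in = 7L) {
  stim <- events[events$code %in% c("stim_target", "stim_nontarget"), ]
  if (drop_lead_in && lead_in > 0 && nrow(stim) > lead_in)
    stim <- stim[-seq_len(lead_in), ]
  c(targets = sum(stim$code == "stim_target"),
    nontargets = sum(stim$code == "stim_nontarget"))
}
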