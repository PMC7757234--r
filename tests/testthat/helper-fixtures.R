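# shared fixtures: small designs and quiet ground truths keep the suite fast

quiet_truth <- function(study = "study1", ...) {
  # all nuisance sources off unless a test turns them back on
  defaults <- list(noise_rms_uV = 0, blink_rate_hz = 0,
                   erp_p3_target_uV = 0, erp_p3_nontarget_uV = 0,
                   erp_early_uV = c(p1 = 0, n1 = 0),
                   assr_phase_jitter_sd = 0)
  dots <- list(...)
  defaults[names(dots)] <- dots
  do.call(ground_truth, c(list(study = study), defaults))
}

small_design <- function(study = "study1", trials = 60, blocks = 2, n = 4)
  study_design(study, n_subjects = n, blocks_per_condition = blocks,
               trials_per_block = trials)

# recording built directly from a channel x sample matrix, with a tone onset
# at sample 1 and optional visual stimuli every `period` seconds
toy_recording <- function(data, fs = 1024, channels = rownames(data),
                          vis_period = NULL, vis_from = 0.2) {
  ev <- data.frame(onset_sample = 1L, time_s = 0, code = "tone_onset",
                   stringsAsFactors = FALSE)
  if (!is.null(vis_period)) {
    times <- seq(vis_from, ncol(data) / fs - 0.01, by = vis_period)
    ev <- rbind(ev, data.frame(onset_sample = round(times * fs) + 1L,
                               time_s = times, code = "stim_nontarget",
                               stringsAsFactors = FALSE))
  }
  new_recording(data, channels, fs, ev)
}

# epochs object assembled in place (bypasses segmentation)
toy_epochs <- function(arr, fs = 1024, channels = NULL) {
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(arr)[2]))
  dimnames(arr) <- list(NULL, channels, NULL)
  structure(list(data = arr, fs = fs,
                 epoch_len_s = dim(arr)[3] / fs, channels = channels,
                 rejected = rep(FALSE, dim(arr)[1]),
                 onsets = seq_len(dim(arr)[1]), meta = list()),
            class = "assr_epochs")
}

# detection counts assembled directly
toy_counts <- function(hits, fas, n_targets, n_nontargets, hit_rts = numeric(0))
  structure(list(hits = hits, misses = n_targets - hits, false_alarms = fas,
                 correct_rejections = n_nontargets - fas,
                 n_targets = n_targets, n_nontargets = n_nontargets,
                 hit_window = c(0.2, 1.0), hit_rts = hit_rts),
            class = "detection_counts")

# complete ospan record sheet from per-sequence proportions is awkward;
# instead build records from explicit correct counts per (length, repetition)
toy_ospan <- function(n_correct) {
  lens <- rep(2:6, each = 3)
  stopifnot(length(n_correct) == 15)
  data.frame(sequence = 1:15, length = lens, n_correct = n_correct)
}
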