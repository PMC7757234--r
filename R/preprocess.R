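#' Zero-phase Butterworth high-pass filter
#'
#' Applies a forward--backward (two-pass) Butterworth high-pass to every
#' channel, doubling the filter order's effective roll-off and cancelling
#' phase distortion. The 0.1-Hz default removes drift and offsets while
#' leaving the 40.96-Hz band untouched (two-pass attenuation there is below
#' 1e-10 relative).
#'
#' @param recording an `assr_recording`.
#' @param cutoff_hz -3 dB cutoff per pass, Hz.
#' @param order filter order per pass.
#' @return the filtered recording.
#' @export
highpass_filter <- function(recording, cutoff_hz = 0.1, order = 4) {
  stopifnot(inherits(recording, "assr_recording"))
  if (cutoff_hz >= recording$fs / 2)
    stop("cutoff at or above the Nyquist frequency", call. = FALSE)
  bt <- signal::butter(order, cutoff_hz / (recording$fs / 2), type = "high")
  for (i in seq_len(nrow(recording$data)))
    recording$data[i, ] <- signal::filtfilt(bt, recording$data[i, ])
  recording
}

#' Re-reference channels to a common reference
#'
#' Subtracts the reference trace sample-wise from each listed channel and
#' drops the reference from the output, emulating nose-referenced recording.
#'
#' @param recording an `assr_recording`.
#' @param channels channels to re-reference; defaults to all except the
#'   reference.
#' @param reference reference channel name.
#' @return the re-referenced recording without the reference channel.
#' @export
rereference <- function(recording, channels = NULL, reference = "nose") {
  stopifnot(inherits(recording, "assr_recording"))
  if (!reference %in% recording$channels)
    stop(sprintf("reference channel '%s' not present", reference), call. = FALSE)
  if (is.null(channels)) channels <- setdiff(recording$channels, reference)
  missing <- setdiff(channels, recording$channels)
  if (length(missing))
    stop("missing channel(s): ", paste(missing, collapse = ", "), call. = FALSE)
  ref <- recording$data[reference, ]
  out <- recording$data[channels, , drop = FALSE] -
    matrix(ref, length(channels), ncol(recording$data), byrow = TRUE)
  new_recording(out, channels, recording$fs, recording$events, recording$meta)
}

#' Cut contiguous steady-state analysis epochs
#'
#' Divides the recording into contiguous, non-overlapping epochs starting at
#' the tone onset. At the defaults (1.5625 s at 1024 Hz) every epoch holds
#' exactly 1600 samples = 64 modulation cycles of the 40.96-Hz stimulus, so
#' epoch k starts exactly `k * 1600` samples after tone onset with no
#' rounding drift, and 115 epochs cover the first ~3 min of stimulation.
#'
#' @param recording an `assr_recording` containing a `tone_onset` event.
#' @param n_epochs number of epochs; `NULL` takes as many as fit.
#' @param epoch_len_s epoch duration in seconds (`epoch_len_s * fs` must be a
#'   whole number of samples).
#' @param channels channels to keep; default all.
#' @return an object of class `assr_epochs`: a list with `data`
#'   (epoch x channel x sample array), `fs`, `epoch_len_s`, `channels`,
#'   logical `rejected`, and `meta`.
#' @export
segment_assr_epochs <- function(recording, n_epochs = 115, epoch_len_s = 1.5625,
                                channels = NULL) {
  stopifnot(inherits(recording, "assr_recording"))
  len <- epoch_len_s * recording$fs
  if (abs(len - round(len)) > 1e-9)
    stop("epoch_len_s * fs must be an integer sample count", call. = FALSE)
  len <- as.integer(round(len))
  onset <- recording$events$onset_sample[recording$events$code == "tone_onset"]
  if (length(onset) != 1) stop("recording must contain one tone_onset event",
                               call. = FALSE)
  if (is.null(channels)) channels <- recording$channels
  avail <- (ncol(recording$data) - onset + 1L) %/% len
  if (is.null(n_epochs)) n_epochs <- avail
  if (avail < n_epochs)
    stop(sprintf("recording too short: %d epochs fit, %d requested",
                 avail, n_epochs), call. = FALSE)
  arr <- array(NA_real_, c(n_epochs, length(channels), len),
               dimnames = list(NULL, channels, NULL))
  for (k in seq_len(n_epochs)) {
    s <- onset + (k - 1L) * len
    arr[k, , ] <- recording$data[channels, s:(s + len - 1L), drop = FALSE]
  }
  structure(list(data = arr, fs = recording$fs, epoch_len_s = epoch_len_s,
                 channels = channels,
                 rejected = rep(FALSE, n_epochs),
                 onsets = onset + (seq_len(n_epochs) - 1L) * len,
                 meta = recording$meta),
            class = "assr_epochs")
}

#' @export
print.assr_epochs <- function(x, ...) {
  cat(sprintf("<assr_epochs> %d epochs x %d channels x %d samples (%.4f s), %.1f%% retained\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$epoch_len_s,
              100 * retention(x)))
  invisible(x)
}

#' Range-based artifact rejection
#'
#' Marks an epoch rejected when its peak-to-peak amplitude (max minus min,
#' taken as the worst channel among the analysis channels) exceeds the
#' cutoff. The decision uses only the waveform, never the condition labels,
#' so rejection is blind to the experimental manipulation. Instead of the
#' fixed cutoff, `method = "percentile"` rejects epochs whose range exceeds
#' the given per-subject range quantile.
#'
#' @param epochs an `assr_epochs` object.
#' @param cutoff_uV peak-to-peak cutoff in microvolts (`method = "absolute"`).
#' @param channels channels entering the range computation; defaults to the
#'   frontal analysis channels when present, else all.
#' @param method `"absolute"` (fixed cutoff) or `"percentile"`.
#' @param percentile quantile for the percentile rule.
#' @return the epochs object with an updated `rejected` mask.
#' @export
reject_by_range <- function(epochs, cutoff_uV = 200, channels = NULL,
                            method = c("absolute", "percentile"),
                            percentile = 0.99) {
  stopifnot(inherits(epochs, "assr_epochs"))
  method <- match.arg(method)
  if (cutoff_uV <= 0) stop("'cutoff_uV' must be positive", call. = FALSE)
  if (is.null(channels)) {
    channels <- intersect(c("Fz", "FCz"), epochs$channels)
    if (!length(channels)) channels <- epochs$channels
  }
  r <- epoch_ranges(epochs, channels)
  thr <- if (method == "absolute") cutoff_uV else stats::quantile(r, percentile)
  epochs$rejected <- r > thr
  epochs
}

# worst-channel peak-to-peak range per epoch
epoch_ranges <- function(epochs, channels = NULL) {
  if (is.null(channels)) channels <- epochs$channels
  idx <- match(channels, epochs$channels)
  apply(epochs$data[, idx, , drop = FALSE], 1,
        function(m) max(apply(m, 1, function(v) max(v) - min(v))))
}

#' Fraction of epochs retained
#' @param epochs an `assr_epochs` object.
#' @export
retention <- function(epochs) mean(!epochs$rejected)

#' Flag subjects by per-block retention
#'
#' A subject is flagged when any block retained less than the threshold
#' fraction of epochs (strictly less: a block at exactly the threshold
#' passes). The flag is advisory -- the four-condition study dropped the
#' exclusion rule entirely.
#'
#' @param retentions numeric vector of per-block retention fractions.
#' @param threshold minimum acceptable retention.
#' @return `TRUE` if the subject should be flagged for exclusion.
#' @export
retention_check <- function(retentions, threshold = 0.70) {
  any(retentions < threshold)
}
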