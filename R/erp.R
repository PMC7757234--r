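#' Cut and baseline-correct visual ERP epochs
#'
#' Extracts epochs from 100 ms before to 500 ms after each matching visual
#' stimulus, subtracts each channel's mean over the 100-ms pre-stimulus
#' interval, and applies range-based artifact rejection. Rejection sees only
#' the waveforms, never the class or condition labels.
#'
#' @param recording a (re-referenced) `assr_recording`.
#' @param stim_class `"target"`, `"nontarget"`, or both.
#' @param tmin,tmax epoch window relative to stimulus onset, seconds.
#' @param baseline baseline window, seconds.
#' @param reject_cutoff_uV peak-to-peak rejection cutoff; `Inf` disables.
#' @param channels channels to keep; rejection uses these channels too.
#' @return an object of class `erp_epochs`: `data`
#'   (epoch x channel x sample), `times`, `fs`, `channels`, `stim_class` per
#'   epoch, `rejected`.
#' @export
segment_visual_epochs <- function(recording,
                                  stim_class = c("target", "nontarget"),
                                  tmin = -0.1, tmax = 0.5,
                                  baseline = c(-0.1, 0),
                                  reject_cutoff_uV = 500,
                                  channels = NULL) {
  stopifnot(inherits(recording, "assr_recording"))
  fs <- recording$fs
  codes <- paste0("stim_", stim_class)
  ev <- recording$events[recording$events$code %in% codes, ]
  if (!nrow(ev)) stop("no matching stimulus events", call. = FALSE)
  if (is.null(channels)) {
    channels <- intersect(c("Cz", "CPz", "Pz"), recording$channels)
    if (!length(channels)) channels <- recording$channels
  }
  rel <- seq(round(tmin * fs), round(tmax * fs))
  times <- rel / fs
  keep_ev <- ev$onset_sample + min(rel) >= 1 &
             ev$onset_sample + max(rel) <= ncol(recording$data)
  ev <- ev[keep_ev, ]
  arr <- array(NA_real_, c(nrow(ev), length(channels), length(rel)),
               dimnames = list(NULL, channels, NULL))
  bl <- times >= baseline[1] & times <= baseline[2]
  for (i in seq_len(nrow(ev))) {
    seg <- recording$data[channels, ev$onset_sample[i] + rel, drop = FALSE]
    arr[i, , ] <- seg - rowMeans(seg[, bl, drop = FALSE])
  }
  ranges <- apply(arr, 1, function(m) max(apply(m, 1, function(v) max(v) - min(v))))
  structure(list(data = arr, times = times, fs = fs, channels = channels,
                 stim_class = sub("^stim_", "", ev$code),
                 rejected = ranges > reject_cutoff_uV,
                 meta = recording$meta),
            class = "erp_epochs")
}

#' Average ERP epochs of one class
#'
#' @param epochs an `erp_epochs` object.
#' @param stim_class class to average (`"target"` or `"nontarget"`); `NULL`
#'   averages all kept epochs.
#' @return an object of class `erp_average` with `times`, `data`
#'   (channel x time), and `n_epochs`.
#' @export
erp_average <- function(epochs, stim_class = NULL) {
  stopifnot(inherits(epochs, "erp_epochs"))
  keep <- !epochs$rejected
  if (!is.null(stim_class)) keep <- keep & epochs$stim_class == stim_class
  if (!any(keep)) stop("no kept epochs to average", call. = FALSE)
  structure(list(times = epochs$times,
                 data = apply(epochs$data[keep, , , drop = FALSE], c(2, 3), mean),
                 channels = epochs$channels,
                 n_epochs = sum(keep),
                 stim_class = stim_class %||% "all"),
            class = "erp_average")
}

#' Visual P3 effect (target minus nontarget)
#'
#' Mean amplitude in the 300--400 ms window, averaged over the requested
#' electrodes, for the target and nontarget averages; the P3 effect is their
#' difference. This is the load manipulation check: the effect shrinks as
#' perceptual load increases.
#'
#' @param target_avg,nontarget_avg `erp_average` objects on identical time
#'   grids.
#' @param electrodes electrodes to average over (one study used Cz; the
#'   follow-up Cz, CPz, Pz).
#' @param window amplitude extraction window, seconds.
#' @return object of class `p3_result` with `target_uV`, `nontarget_uV`, and
#'   `effect_uV = target_uV - nontarget_uV`.
#' @export
p3_effect <- function(target_avg, nontarget_avg, electrodes = "Cz",
                      window = c(0.3, 0.4)) {
  stopifnot(inherits(target_avg, "erp_average"),
            inherits(nontarget_avg, "erp_average"))
  if (!isTRUE(all.equal(target_avg$times, nontarget_avg$times)))
    stop("time grids differ between averages", call. = FALSE)
  win_mean <- function(avg) {
    idx <- avg$times >= window[1] & avg$times <= window[2]
    chans <- match(electrodes, avg$channels)
    if (anyNA(chans)) stop("electrode(s) missing from average", call. = FALSE)
    mean(avg$data[chans, idx])
  }
  tg <- win_mean(target_avg); ntg <- win_mean(nontarget_avg)
  structure(list(window = window, electrodes = electrodes,
                 target_uV = tg, nontarget_uV = ntg,
                 effect_uV = tg - ntg),
            class = "p3_result")
}

#' @export
print.p3_result <- function(x, ...) {
  cat(sprintf("<p3_result> %g-%g ms @ %s: target %.3g, nontarget %.3g, effect %.3g uV\n",
              1000 * x$window[1], 1000 * x$window[2],
              paste(x$electrodes, collapse = "/"),
              x$target_uV, x$nontarget_uV, x$effect_uV))
  invisible(x)
}

#' Zero-phase 30-Hz low-pass for ERP plotting
#'
#' Smoothing used only for display; analyses always run on the unfiltered
#' averages.
#'
#' @param avg an `erp_average`.
#' @param cutoff_hz low-pass cutoff.
#' @param fs sampling rate of the average.
#' @param order Butterworth order per pass.
#' @export
erp_lowpass <- function(avg, cutoff_hz = 30, fs = 1024, order = 4) {
  stopifnot(inherits(avg, "erp_average"))
  bt <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  for (i in seq_len(nrow(avg$data)))
    avg$data[i, ] <- signal::filtfilt(bt, avg$data[i, ])
  avg
}
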