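#' Specification of the amplitude-modulated tone
#'
#' Describes the task-irrelevant auditory stimulus: a sinusoidal carrier whose
#' amplitude is modulated by a raised cosine. The default modulation frequency
#' of 40.96 Hz is the frequency closest to 40 Hz that lands exactly on the
#' spectral grid of a 1024-Hz recording (1024 / 40.96 = 25 samples per
#' modulation cycle), so the steady-state response is leakage-free by
#' construction.
#'
#' @param carrier_hz carrier frequency in Hz.
#' @param modulation_hz modulation frequency in Hz.
#' @param depth modulation depth in `[0, 1]`; 1 means the envelope swings from
#'   zero to maximum.
#' @param start_polarity `"condensation"` or `"rarefaction"`; flips the sign of
#'   the carrier, used in the original design to cancel any response to the
#'   carrier itself across blocks.
#' @param fs sampling rate in samples/s of the analysis grid.
#' @param level_note free-text presentation-level note (metadata only).
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(carrier_hz = 500, modulation_hz = 40.96, depth = 1.0,
                          start_polarity = c("condensation", "rarefaction"),
                          fs = 1024, level_note = "60 dB SL") {
  start_polarity <- match.arg(start_polarity)
  stopifnot_scalar(carrier_hz); stopifnot_scalar(modulation_hz)
  stopifnot_scalar(depth); stopifnot_scalar(fs)
  if (depth < 0 || depth > 1) stop("'depth' must be in [0, 1]", call. = FALSE)
  if (fs <= 2 * carrier_hz)
    stop("sampling rate below Nyquist rate of the carrier", call. = FALSE)
  structure(
    list(carrier_hz = carrier_hz, modulation_hz = modulation_hz, depth = depth,
         start_polarity = start_polarity, fs = fs, level_note = level_note),
    class = "stimulus_spec")
}

#' Render the amplitude-modulated tone
#'
#' Generates `s(t) = env(t) * sin(2 pi f_c t)` with the raised-cosine envelope
#' `env(t) = 1 - depth/2 * (1 + cos(2 pi f_m t))`, so at full depth the
#' envelope is `0.5 * (1 - cos(2 pi f_m t))`: it starts at zero and reaches
#' each maximum once per modulation cycle. `start_polarity = "rarefaction"`
#' negates the carrier.
#'
#' @param spec a [stimulus_spec()].
#' @param duration_s duration in seconds (> 0).
#' @return numeric waveform sampled at `spec$fs`, with attribute `"fs"`.
#' @export
generate_am_tone <- function(spec, duration_s) {
  stopifnot(inherits(spec, "stimulus_spec"))
  stopifnot_scalar(duration_s)
  if (duration_s <= 0) stop("'duration_s' must be positive", call. = FALSE)
  n <- round(duration_s * spec$fs)
  t <- (seq_len(n) - 1) / spec$fs
  env <- 1 - spec$depth / 2 * (1 + cos(2 * pi * spec$modulation_hz * t))
  pol <- if (spec$start_polarity == "condensation") 1 else -1
  w <- pol * env * sin(2 * pi * spec$carrier_hz * t)
  attr(w, "fs") <- spec$fs
  w
}

#' Raised-cosine envelope of the tone
#'
#' Convenience accessor used by tests and plots: the modulation envelope alone,
#' without the carrier.
#' @inheritParams generate_am_tone
#' @return numeric envelope in `[0, 1]`.
#' @export
am_envelope <- function(spec, duration_s) {
  stopifnot(inherits(spec, "stimulus_spec"))
  n <- round(duration_s * spec$fs)
  t <- (seq_len(n) - 1) / spec$fs
  1 - spec$depth / 2 * (1 + cos(2 * pi * spec$modulation_hz * t))
}
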