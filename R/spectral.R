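#' One-sided amplitude spectrum
#'
#' FFT-based amplitude spectrum scaled so that a unit-amplitude sinusoid
#' centred on a bin reads exactly 1.0 at that bin (`2|X_k|/N` for interior
#' bins; DC and Nyquist scaled `1/N`). No taper is applied: the steady-state
#' epoch length is an exact integer number of modulation cycles, so the
#' target bin is leakage-free by construction.
#'
#' @param mean_waveform numeric vector (typically the across-epoch mean
#'   waveform of one channel or a channel average); even length required.
#' @param fs sampling rate, samples/s.
#' @return an object of class `assr_spectrum` with fields `freqs` (Hz),
#'   `values`, and `kind = "amplitude"`. The bin spacing is
#'   `1 / (length(x)/fs)` -- 0.64 Hz for the 1.5625-s analysis epochs.
#' @export
amplitude_spectrum <- function(mean_waveform, fs) {
  n <- length(mean_waveform)
  if (n == 0) stop("empty input", call. = FALSE)
  if (n %% 2 != 0) stop("waveform length must be even", call. = FALSE)
  X <- stats::fft(mean_waveform)
  half <- n / 2 + 1
  vals <- Mod(X[seq_len(half)]) * c(1, rep(2, half - 2), 1) / n
  structure(list(freqs = (seq_len(half) - 1) * fs / n, values = vals,
                 kind = "amplitude"),
            class = "assr_spectrum")
}

#' @export
print.assr_spectrum <- function(x, ...) {
  cat(sprintf("<assr_spectrum> kind=%s, %d bins, df=%.4g Hz, range [%g, %g] Hz\n",
              x$kind, length(x$freqs), x$freqs[2] - x$freqs[1],
              min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Signal-minus-noise at a target frequency
#'
#' The study's primary measure: the spectrum value at the target bin (S)
#' minus the mean over 20 neighbouring bins (N) -- ten per side, omitting the
#' two bins immediately adjacent to the target on each side, i.e. noise bins
#' at offsets `(skip_side+1) .. (skip_side+n_side)` on both sides. Because
#' both S and N see any flat noise floor equally, SmN cancels it; SNR = S/N
#' is reported alongside.
#'
#' @param spectrum an `assr_spectrum` (amplitude or ITC).
#' @param target_hz target frequency; must lie on the bin grid.
#' @param n_side noise bins per side.
#' @param skip_side immediately adjacent bins omitted per side.
#' @return an object of class `smn_result` with fields `S`, `N`, `SmN`,
#'   `SNR`, `target_hz`, `n_side`, `skip_side`, `kind`.
#' @export
compute_smn <- function(spectrum, target_hz = 40.96, n_side = 10, skip_side = 2) {
  stopifnot(inherits(spectrum, "assr_spectrum"))
  df <- spectrum$freqs[2] - spectrum$freqs[1]
  bin <- (target_hz - spectrum$freqs[1]) / df
  if (abs(bin - round(bin)) > 1e-6)
    stop(sprintf("target %.4g Hz is off the %.4g-Hz bin grid", target_hz, df),
         call. = FALSE)
  bin <- as.integer(round(bin)) + 1L
  offs <- (skip_side + 1):(skip_side + n_side)
  idx <- c(bin - offs, bin + offs)
  if (any(idx < 1) || any(idx > length(spectrum$values)))
    stop("not enough neighbouring bins around the target", call. = FALSE)
  S <- spectrum$values[bin]
  N <- mean(spectrum$values[idx])
  structure(list(S = S, N = N, SmN = S - N, SNR = S / N,
                 target_hz = target_hz, n_side = n_side,
                 skip_side = skip_side, kind = spectrum$kind),
            class = "smn_result")
}

#' @export
print.smn_result <- function(x, ...) {
  cat(sprintf("<smn_result> %s @ %.4g Hz: S=%.4g N=%.4g SmN=%.4g SNR=%.3g\n",
              x$kind, x$target_hz, x$S, x$N, x$SmN, x$SNR))
  invisible(x)
}

#' Intertrial phase coherence spectrum
#'
#' For every frequency bin, each kept epoch contributes a unit phasor
#' `exp(i * arg(X_k))` from its own FFT; the ITC is the modulus of the mean
#' phasor across epochs, from 0 (uniform phase) to 1 (perfect phase
#' locking). Computed per channel, then averaged over the requested channel
#' set.
#'
#' @param epochs an `assr_epochs` object (rejected epochs are excluded).
#' @param channels channel set to average over; defaults to the frontal
#'   analysis channels when present.
#' @return an `assr_spectrum` of kind `"itc"`.
#' @export
compute_itc <- function(epochs, channels = NULL) {
  stopifnot(inherits(epochs, "assr_epochs"))
  if (is.null(channels)) {
    channels <- intersect(c("Fz", "FCz"), epochs$channels)
    if (!length(channels)) channels <- epochs$channels
  }
  keep <- which(!epochs$rejected)
  if (length(keep) < 2) stop("need at least 2 kept epochs", call. = FALSE)
  len <- dim(epochs$data)[3]
  half <- len %/% 2 + 1
  acc <- 0
  for (ch in channels) {
    ci <- match(ch, epochs$channels)
    X <- stats::mvfft(t(epochs$data[keep, ci, , drop = TRUE]))[seq_len(half), , drop = FALSE]
    phasors <- X / Mod(X)
    phasors[Mod(X) == 0] <- 0
    acc <- acc + Mod(rowMeans(phasors))
  }
  structure(list(freqs = (seq_len(half) - 1) * epochs$fs / len,
                 values = acc / length(channels), kind = "itc"),
            class = "assr_spectrum")
}

#' Signal-minus-noise of an ITC spectrum
#'
#' [compute_smn()] applied to an ITC spectrum: ITC at the target frequency
#' minus the mean ITC over the neighbour bins, the phase-coherence analogue
#' of the amplitude measure.
#'
#' @inheritParams compute_smn
#' @param itc_spectrum an `assr_spectrum` of kind `"itc"`.
#' @export
itc_smn <- function(itc_spectrum, target_hz = 40.96, n_side = 10, skip_side = 2) {
  if (!identical(itc_spectrum$kind, "itc"))
    stop("expected an ITC spectrum", call. = FALSE)
  compute_smn(itc_spectrum, target_hz, n_side, skip_side)
}

#' Mean waveform of the kept epochs
#'
#' Across-epoch mean for one channel or averaged over a channel set --
#' the quantity whose spectrum defines the amplitude measure (average the
#' waveforms first, then transform; transforming epochs individually and
#' averaging magnitudes would inflate the noise floor).
#'
#' @param epochs an `assr_epochs` object.
#' @param channels channels to average over; default frontal set.
#' @return numeric vector of length `epoch_len_s * fs`.
#' @export
mean_waveform <- function(epochs, channels = NULL) {
  stopifnot(inherits(epochs, "assr_epochs"))
  if (is.null(channels)) {
    channels <- intersect(c("Fz", "FCz"), epochs$channels)
    if (!length(channels)) channels <- epochs$channels
  }
  keep <- which(!epochs$rejected)
  if (!length(keep)) stop("no kept epochs", call. = FALSE)
  idx <- match(channels, epochs$channels)
  apply(epochs$data[keep, idx, , drop = FALSE], 3, mean)
}
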