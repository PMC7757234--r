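#' Simulate a block of multi-channel EEG
#'
#' Builds one block's recording as the sum of four sources, each projected
#' onto the montage with fixed per-channel gains:
#' \itemize{
#'   \item the auditory steady-state response: a sinusoid at the modulation
#'     frequency whose phase is jittered independently per 1.5625-s analysis
#'     epoch (Gaussian, SD `assr_phase_jitter_sd`) and whose amplitude can be
#'     modulated at 2 Hz locked to the visual stimulus train
#'     (`assr_2hz_mod_depth`); carried by the frontal channels (Fz, FCz);
#'   \item `1/f^alpha` background noise, independent per channel;
#'   \item biphasic 400-ms eye-blink templates at Poisson times, strongest
#'     frontally -- large enough to exercise artifact rejection but far below
#'     40 Hz in frequency content;
#'   \item visual evoked responses at every stimulus onset: load-independent
#'     early components plus a P3 whose amplitude depends on condition and on
#'     target status; carried by the centro-parietal channels.
#' }
#' The output is bit-identical for identical `(design, truth, stim, ids,
#' seed)`.
#'
#' @param design a [study_design()].
#' @param truth a [ground_truth()].
#' @param stim a [stimulus_spec()].
#' @param subject,block identifiers stored in the metadata.
#' @param condition condition label (must appear in `truth`).
#' @param seed integer master seed for this block.
#' @param events optional pre-generated event table; generated from
#'   `(design, condition, seed)` when omitted.
#' @param channels montage; defaults to the study montage (`Fz, FCz, Cz, Fpz,
#'   nose`, plus `CPz, Pz` for the four-condition study).
#' @param duration_s recording length; defaults to the full block (tone lead +
#'   all trials + 0.3 s tail).
#' @param amp_override optional scalar overriding the condition's response
#'   amplitude (used for individual-differences simulations).
#' @param crosstalk fraction of each source bleeding onto the other source's
#'   channels (default 0).
#' @return an [new_recording()] object with the events embedded.
#' @export
simulate_recording <- function(design, truth, stim, subject, block, condition,
                               seed, events = NULL, channels = NULL,
                               duration_s = NULL, amp_override = NULL,
                               crosstalk = 0) {
  stopifnot(inherits(design, "study_design"), inherits(truth, "ground_truth"),
            inherits(stim, "stimulus_spec"))
  fs <- stim$fs
  if (is.null(events)) events <- generate_event_sequence(design, condition, seed, fs)
  if (is.null(duration_s))
    duration_s <- design$tone_lead_s +
      (design$lead_in_nontargets + design$trials_per_block) *
        design$trial_period_s + 0.3
  n <- round(duration_s * fs)
  if (is.null(channels))
    channels <- if (design$study == "study2")
      c("Fz", "FCz", "Cz", "CPz", "Pz", "Fpz", "nose")
    else c("Fz", "FCz", "Cz", "Fpz", "nose")

  gain <- channel_gains(channels, crosstalk)
  amp <- if (!is.null(amp_override)) amp_override else truth$assr_amp_uV[[condition]]
  jit <- truth$assr_phase_jitter_sd[[condition]]

  with_seed(derive_seed(seed, 101), {
    ## --- steady-state response, phase-jittered per analysis epoch
    tone_t0 <- events$time_s[events$code == "tone_onset"][1]
    stim_t <- events$time_s[events$code %in% c("stim_target", "stim_nontarget")]
    t <- (seq_len(n) - 1) / fs
    epoch_len <- 64 / stim$modulation_hz            # 1.5625 s at 40.96 Hz
    k <- pmax(0, floor((t - tone_t0) / epoch_len))  # epoch index per sample
    n_ep <- max(k) + 1
    phi0 <- stats::runif(1, 0, 2 * pi)
    eps <- if (jit > 0) stats::rnorm(n_ep, 0, jit) else numeric(n_ep)
    phase <- 2 * pi * stim$modulation_hz * (t - tone_t0) + phi0 + eps[k + 1]
    assr <- amp * sin(phase)
    if (truth$assr_2hz_mod_depth > 0 && length(stim_t)) {
      f_vis <- 1 / design$trial_period_s
      assr <- assr * (1 + truth$assr_2hz_mod_depth *
                        cos(2 * pi * f_vis * (t - stim_t[1])))
    }
    assr[t < tone_t0] <- 0

    ## --- background noise (independent per channel; quiet reference)
    data <- matrix(0, length(channels), n, dimnames = list(channels, NULL))
    for (ch in channels) {
      rms <- truth$noise_rms_uV * if (ch == "nose") 0.2 else 1
      data[ch, ] <- one_over_f_noise(n, fs, rms, truth$noise_slope)
    }

    ## --- blinks
    n_blinks <- stats::rpois(1, truth$blink_rate_hz * duration_s)
    if (n_blinks > 0) {
      tmpl <- blink_template(fs) * truth$blink_amp_uV
      at <- sort(stats::runif(n_blinks, 0, duration_s - 0.45))
      blink <- add_templates(numeric(n), round(at * fs) + 1L, tmpl)
      data <- data + outer(gain$blink, blink)
    }

    ## --- visual evoked responses
    erp <- numeric(n)
    stim_ev <- events[events$code %in% c("stim_target", "stim_nontarget"), ]
    if (nrow(stim_ev)) {
      early <- erp_early_template(fs, truth$erp_early_uV)
      p3 <- p3_template(fs)
      is_tg <- stim_ev$code == "stim_target"
      erp <- add_templates(erp, stim_ev$onset_sample, early)
      p3_t <- truth$erp_p3_target_uV[[condition]]
      p3_n <- truth$erp_p3_nontarget_uV[[condition]]
      if (any(is_tg) && p3_t != 0)
        erp <- add_templates(erp, stim_ev$onset_sample[is_tg], p3 * p3_t)
      if (any(!is_tg) && p3_n != 0)
        erp <- add_templates(erp, stim_ev$onset_sample[!is_tg], p3 * p3_n)
    }

    data <- data + outer(gain$assr, assr) + outer(gain$erp, erp)
    new_recording(data, channels, fs, events,
                  meta = list(subject = subject, block = block,
                              condition = condition, seed = seed))
  })
}

# montage gains: frontal channels carry the steady-state response,
# centro-parietal channels the visual ERPs, frontal-most the blinks
channel_gains <- function(channels, crosstalk = 0) {
  g <- function(defaults) {
    v <- stats::setNames(numeric(length(channels)), channels)
    common <- intersect(names(defaults), channels)
    v[common] <- defaults[common]
    v
  }
  assr <- g(c(Fz = 1, FCz = 1))
  erp <- g(c(Cz = 1, CPz = 1, Pz = 1))
  if (crosstalk > 0) {
    assr <- assr + crosstalk * g(c(Cz = 1, CPz = 1, Pz = 1))
    erp <- erp + crosstalk * g(c(Fz = 1, FCz = 1))
  }
  list(assr = assr, erp = erp,
       blink = g(c(Fpz = 1, Fz = 0.8, FCz = 0.6, Cz = 0.3, CPz = 0.15, Pz = 0.1)))
}

# colored noise via spectral shaping: amplitude ~ f^(-alpha/2), flat below f0
one_over_f_noise <- function(n, fs, rms, alpha = 1, f0 = 0.5) {
  if (rms <= 0) return(numeric(n))
  nfft <- n + n %% 2
  freqs <- seq(0, fs / 2, by = fs / nfft)
  shape <- c(0, 1 / pmax(freqs[-1], f0)^(alpha / 2))
  nh <- length(freqs)
  z <- complex(real = stats::rnorm(nh), imaginary = stats::rnorm(nh)) * shape
  z[1] <- 0
  z[nh] <- complex(real = Re(z[nh]), imaginary = 0)
  spec <- c(z, Conj(z[(nh - 1):2]))
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
  x * (rms / stats::sd(x))
}

# biphasic 400-ms blink, peak-normalised to 1; the raised-cosine taper
# forces exact zeros at the ends so truncation adds no broadband splatter
blink_template <- function(fs) {
  t <- seq(0, 0.4, by = 1 / fs)
  w <- exp(-(t - 0.15)^2 / (2 * 0.05^2)) - 0.35 * exp(-(t - 0.28)^2 / (2 * 0.06^2))
  w <- w * sin(pi * t / 0.4)^2
  w / max(abs(w))
}

# early visual components (P1/N1), peak amplitudes as given
erp_early_template <- function(fs, amps) {
  t <- seq(0, 0.35, by = 1 / fs)
  amps[["p1"]] * exp(-(t - 0.10)^2 / (2 * 0.020^2)) +
    amps[["n1"]] * exp(-(t - 0.17)^2 / (2 * 0.025^2))
}

# P3 bump normalised so its mean over the 300--400 ms window equals 1,
# making the generating parameter directly comparable to the measured effect
p3_template <- function(fs) {
  t <- seq(0, 0.7, by = 1 / fs)
  g <- exp(-(t - 0.35)^2 / (2 * 0.045^2))
  win <- t >= 0.3 & t <= 0.4
  g / mean(g[win])
}

# add template starting at each onset sample, clipping at the signal end
add_templates <- function(x, onsets, template) {
  nt <- length(template); n <- length(x)
  for (s in onsets) {
    e <- min(n, s + nt - 1L)
    if (e >= s) x[s:e] <- x[s:e] + template[seq_len(e - s + 1L)]
  }
  x
}

#' Simulate button-press responses to the visual task
#'
#' Applies the equal-variance signal-detection model: each target elicits a
#' hit with probability `pnorm(d'/2 - c)`, each nontarget a false alarm with
#' probability `pnorm(-d'/2 - c)`. Hit latencies are drawn from a normal
#' distribution truncated to the 0.2--1.0 s response window; false-alarm
#' presses are placed outside every target response window so the generating
#' rates survive downstream classification.
#'
#' @param events event table for the block.
#' @param truth a [ground_truth()].
#' @param condition condition label; a condition without targets returns an
#'   empty response set.
#' @param seed integer seed.
#' @return `data.frame` with columns `time_s` (press time) and `trial_time_s`
#'   (onset of the eliciting trial).
#' @export
simulate_behavior <- function(events, truth, condition, seed) {
  stim <- events[events$code %in% c("stim_target", "stim_nontarget"), ]
  tg <- stim$time_s[stim$code == "stim_target"]
  ntg <- stim$time_s[stim$code == "stim_nontarget"]
  d <- truth$dprime[[condition]]
  if (length(tg) == 0 || is.na(d))
    return(data.frame(time_s = numeric(0), trial_time_s = numeric(0)))
  cc <- truth$criterion
  rtm <- truth$rt_mean_s[[condition]]; rts <- truth$rt_sd_s
  with_seed(derive_seed(seed, 202), {
    hit <- stats::runif(length(tg)) < stats::pnorm(d / 2 - cc)
    rt <- rtrunc_norm(sum(hit), rtm, rts, 0.2, 1.0)
    presses <- data.frame(time_s = tg[hit] + rt, trial_time_s = tg[hit])
    fa <- stats::runif(length(ntg)) < stats::pnorm(-d / 2 - cc)
    if (any(fa)) {
      t_fa <- ntg[fa] + stats::runif(sum(fa), 0.2, 0.45)
      # shift any press that would land inside a target response window
      for (i in seq_along(t_fa)) {
        inside <- which(t_fa[i] >= tg + 0.2 & t_fa[i] <= tg + 1.0)
        if (length(inside))
          t_fa[i] <- tg[inside[1]] + 1.0 + stats::runif(1, 0.005, 0.15)
      }
      presses <- rbind(presses,
                       data.frame(time_s = t_fa, trial_time_s = ntg[fa]))
    }
    presses[order(presses$time_s), , drop = FALSE]
  })
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (n == 0) return(numeric(0))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate one complex-span (OSPAN) session
#'
#' Fifteen letter sequences (lengths two to six, three of each, in random
#' order); every letter is recalled in its correct position with the
#' subject's latent capacity probability, so the expected partial-credit-unit
#' score equals that latent capacity.
#'
#' @param truth a [ground_truth()]; supplies the capacity distribution.
#' @param seed integer seed.
#' @param wmc optional latent capacity in `[0, 1]`; drawn from
#'   `(pcu_mean, pcu_sd)` and clipped when omitted.
#' @return `data.frame(sequence, length, n_correct)` with the latent capacity
#'   attached as attribute `"wmc"`.
#' @export
simulate_ospan <- function(truth, seed, wmc = NULL) {
  with_seed(derive_seed(seed, 303), {
    if (is.null(wmc))
      wmc <- min(1, max(0, stats::rnorm(1, truth$pcu_mean, truth$pcu_sd)))
    lens <- sample(rep(2:6, each = 3))
    rec <- data.frame(sequence = seq_along(lens), length = lens,
                      n_correct = stats::rbinom(length(lens), lens, wmc))
    attr(rec, "wmc") <- wmc
    rec
  })
}

#' Simulate one block's workload ratings
#'
#' Borg CR100 ratings of the six workload scales; condition means come from
#' the ground truth, noise is Gaussian, and values are clipped below at zero
#' (the scale is open above 100).
#'
#' @param truth a [ground_truth()].
#' @param condition condition label.
#' @param seed integer seed.
#' @return `data.frame(scale, rating)`.
#' @export
simulate_ratings <- function(truth, condition, seed) {
  m <- truth$ratings_mean[, condition]
  with_seed(derive_seed(seed, 404), {
    r <- pmax(0, stats::rnorm(length(m), m, truth$ratings_sd))
    data.frame(scale = rownames(truth$ratings_mean), rating = r,
               stringsAsFactors = FALSE)
  })
}
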