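#' Ground-truth generating parameters for the synthetic EEG
#'
#' Collects every latent quantity the simulator needs, per condition where the
#' studies manipulate it. The defaults encode the observed study conditions:
#' a ~0.24 uV steady-state response at 40.96 Hz over a ~0.05 uV spectral noise
#' floor with phase coherence ~0.38 (study 1; study 2 ran slightly stronger
#' responses, SmN ~0.24 and ITC SmN ~0.37), load-dependent visual P3
#' target-nontarget effects, d' of ~4.3 (low load) vs ~2.6 (high load),
#' reaction times of ~378 vs ~505 ms, and complex-span partial-credit scores
#' of mean 0.72 (SD 0.18). `noise_rms_uV` and `assr_phase_jitter_sd` defaults
#' were fixed once by calibrating the full simulate-and-measure pipeline to
#' those observed levels (see the package vignette).
#'
#' @param study `"study1"` or `"study2"`; selects per-condition defaults.
#' @param assr_amp_uV named per-condition amplitude (uV) of the 40.96-Hz
#'   response component.
#' @param assr_phase_jitter_sd named per-condition SD (radians) of the
#'   Gaussian per-epoch phase jitter; controls intertrial phase coherence.
#' @param assr_2hz_mod_depth fractional amplitude modulation of the 40-Hz
#'   response locked to the 2-Hz visual stimulation rhythm (0 = none).
#' @param noise_rms_uV RMS (uV) of the broadband `1/f^alpha` background per
#'   channel.
#' @param noise_slope spectral exponent alpha of the background.
#' @param blink_rate_hz Poisson rate of eye blinks.
#' @param blink_amp_uV blink template peak amplitude on the frontal-most
#'   channel.
#' @param erp_p3_target_uV,erp_p3_nontarget_uV named per-condition P3
#'   amplitudes, parameterised directly as the 300--400 ms window mean (uV).
#' @param erp_early_uV peak amplitudes (uV) of the load-independent early
#'   visual components, named `p1` and `n1`.
#' @param dprime named per-condition detection sensitivity (NA where the
#'   condition has no targets).
#' @param criterion signal-detection response bias.
#' @param rt_mean_s,rt_sd_s named per-condition mean and common SD of hit
#'   reaction times (seconds), truncated to the 0.2--1.0 s response window.
#' @param pcu_mean,pcu_sd population mean and SD of latent working-memory
#'   capacity on the partial-credit-unit scale, clipped to `[0, 1]`.
#' @param rho_wmc_load target correlation between latent capacity and a
#'   subject's load effect on response amplitude.
#' @param subject_amp_sd between-subject SD (uV) of the per-subject load
#'   effect on the response amplitude (only relevant with nonzero
#'   `rho_wmc_load` or for individual-differences simulations).
#' @param ratings_mean matrix (scale x condition) of mean Borg CR100 workload
#'   ratings; defaults encode the observed ordinal pattern in which high load
#'   is rated most demanding on every scale except performance.
#' @param ratings_sd rating noise SD.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(study = c("study1", "study2"),
                         assr_amp_uV = NULL,
                         assr_phase_jitter_sd = NULL,
                         assr_2hz_mod_depth = 0,
                         noise_rms_uV = 8,
                         noise_slope = 1,
                         blink_rate_hz = 0.25,
                         blink_amp_uV = 100,
                         erp_p3_target_uV = NULL,
                         erp_p3_nontarget_uV = NULL,
                         erp_early_uV = c(p1 = 1.5, n1 = -2.0),
                         dprime = NULL,
                         criterion = 0.5,
                         rt_mean_s = NULL,
                         rt_sd_s = 0.08,
                         pcu_mean = 0.721,
                         pcu_sd = 0.175,
                         rho_wmc_load = 0,
                         subject_amp_sd = 0.05,
                         ratings_mean = NULL,
                         ratings_sd = 10) {
  study <- match.arg(study)
  conds <- if (study == "study1") c("low", "high")
           else c("no", "low", "high", "very_high")
  fill <- function(x, default) {
    if (is.null(x)) x <- default
    if (length(x) == 1L && is.null(names(x))) x <- stats::setNames(rep(x, length(conds)), conds)
    if (is.null(names(x))) names(x) <- conds
    x
  }
  if (study == "study1") {
    assr_amp_uV <- fill(assr_amp_uV, c(low = 0.246, high = 0.240))
    assr_phase_jitter_sd <- fill(assr_phase_jitter_sd, c(low = 0.20, high = 0.30))
    erp_p3_target_uV <- fill(erp_p3_target_uV, c(low = 8.704, high = 2.683))
    dprime <- fill(dprime, c(low = 4.324, high = 2.607))
    rt_mean_s <- fill(rt_mean_s, c(low = 0.378, high = 0.505))
  } else {
    assr_amp_uV <- fill(assr_amp_uV,
      c(no = 0.30, low = 0.30, high = 0.30, very_high = 0.30))
    assr_phase_jitter_sd <- fill(assr_phase_jitter_sd,
      c(no = 0.25, low = 0.25, high = 0.25, very_high = 0.25))
    erp_p3_target_uV <- fill(erp_p3_target_uV,
      c(no = 0, low = 6.9, high = 2.1, very_high = 3.9))
    dprime <- fill(dprime, c(no = NA, low = 4.3, high = 2.3, very_high = 3.3))
    rt_mean_s <- fill(rt_mean_s, c(no = NA, low = 0.37, high = 0.52, very_high = 0.47))
  }
  erp_p3_nontarget_uV <- fill(erp_p3_nontarget_uV, 0)
  if (is.null(ratings_mean)) ratings_mean <- default_ratings(conds)
  stopifnot(all(assr_amp_uV >= 0), all(assr_phase_jitter_sd >= 0),
            abs(rho_wmc_load) <= 1, assr_2hz_mod_depth >= 0,
            noise_rms_uV >= 0, blink_amp_uV >= 0)
  structure(
    list(study = study, conditions = conds,
         assr_amp_uV = assr_amp_uV,
         assr_phase_jitter_sd = assr_phase_jitter_sd,
         assr_2hz_mod_depth = assr_2hz_mod_depth,
         noise_rms_uV = noise_rms_uV, noise_slope = noise_slope,
         blink_rate_hz = blink_rate_hz, blink_amp_uV = blink_amp_uV,
         erp_p3_target_uV = erp_p3_target_uV,
         erp_p3_nontarget_uV = erp_p3_nontarget_uV,
         erp_early_uV = erp_early_uV,
         dprime = dprime, criterion = criterion,
         rt_mean_s = rt_mean_s, rt_sd_s = rt_sd_s,
         pcu_mean = pcu_mean, pcu_sd = pcu_sd,
         rho_wmc_load = rho_wmc_load, subject_amp_sd = subject_amp_sd,
         ratings_mean = ratings_mean, ratings_sd = ratings_sd),
    class = "ground_truth")
}

# workload-rating means (Borg CR100): high load maximal on every scale except
# performance, where it is minimal; values are plausible scale levels only
default_ratings <- function(conds) {
  scales <- c("mental_demand", "physical_demand", "temporal_demand",
              "performance", "effort", "frustration")
  m <- matrix(0, length(scales), length(conds),
              dimnames = list(scales, conds))
  preset <- list(
    no        = c(3, 2, 4, 55, 5, 4),
    low       = c(28, 10, 30, 72, 30, 14),
    high      = c(58, 20, 52, 38, 57, 42),
    very_high = c(47, 17, 45, 55, 48, 30))
  for (cn in conds) m[, cn] <- preset[[cn]] %||% 0
  m
}
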