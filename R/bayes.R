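#' Standard error from a reported confidence interval
#'
#' Recovers the standard error of a mean from its printed 95% CI:
#' `se = (upper - lower) / (2 * q)`, with `q` the 0.975 quantile of the
#' central t distribution on `df` degrees of freedom (`method = "t"`) or of
#' the standard normal (`method = "normal"`, q = 1.96). Needed to consume
#' published summary tables when raw data are unavailable.
#'
#' @param lower,upper CI bounds.
#' @param df degrees of freedom (n - 1) for the t method.
#' @param method `"t"` or `"normal"`.
#' @param level confidence level of the interval.
#' @return the standard error.
#' @export
se_from_ci <- function(lower, upper, df = NULL, method = c("t", "normal"),
                       level = 0.95) {
  method <- match.arg(method)
  if (upper <= lower) stop("'upper' must exceed 'lower'", call. = FALSE)
  p <- 1 - (1 - level) / 2
  q <- if (method == "t") {
    if (is.null(df) || df < 1) stop("'df' must be >= 1 for the t method",
                                    call. = FALSE)
    stats::qt(p, df)
  } else stats::qnorm(p)
  (upper - lower) / (2 * q)
}

# evidence-category label on the conventional 3 / 10 / 30 / 100 scheme,
# applied to whichever direction the evidence favours
bf_evidence_label <- function(bf01) {
  b <- max(bf01, 1 / bf01)
  side <- if (bf01 >= 1) "null" else "alternative"
  strength <- if (b <= 3) "anecdotal" else if (b <= 10) "moderate" else
    if (b <= 30) "strong" else if (b <= 100) "very strong" else "extreme"
  if (b == 1) "no evidence" else paste(strength, "for", side)
}

new_bf_result <- function(bf01, prior, details = list()) {
  structure(c(list(bf01 = bf01, bf10 = 1 / bf01,
                   evidence = bf_evidence_label(bf01), prior = prior),
              details),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("<bf_result> BF01 = %.4g (BF10 = %.4g), %s; prior: %s\n",
              x$bf01, x$bf10, x$evidence, x$prior))
  invisible(x)
}

#' Bayes factor for a mean difference under a uniform effect prior
#'
#' One-sample Bayesian test of a difference score from its summary
#' statistics. The likelihood of the population effect `theta` given the
#' observed mean is a location-shifted, se-scaled t density on `df` degrees
#' of freedom (default), or a normal density (`likelihood = "normal"`, the
#' convention of the common summary-statistic calculators). Evidence for the
#' null is the likelihood at `theta = 0`; evidence for the alternative
#' averages the likelihood over a uniform prior on `[lower, upper]` by
#' adaptive quadrature. `BF01` is their ratio.
#'
#' Typical priors: `[-1, 1]` for a two-tailed effect of bounded plausible
#' size, `[0, 1]` for a directional effect, `[0, 0.2]` for a small
#' directional effect.
#'
#' @param mean_diff observed mean difference.
#' @param se standard error of the mean difference (supply directly or via
#'   [se_from_ci()]).
#' @param n sample size (df = n - 1).
#' @param lower,upper uniform prior bounds on the effect (same units as
#'   `mean_diff`).
#' @param likelihood `"t"` or `"normal"`.
#' @return a `bf_result` with `bf01`, `bf10`, and an evidence label.
#' @export
bf_uniform <- function(mean_diff, se, n, lower = -1, upper = 1,
                       likelihood = c("t", "normal")) {
  likelihood <- match.arg(likelihood)
  stopifnot_scalar(mean_diff); stopifnot_scalar(se)
  if (se <= 0) stop("'se' must be positive", call. = FALSE)
  if (upper <= lower) stop("'upper' must exceed 'lower'", call. = FALSE)
  df <- n - 1
  if (df < 1) stop("need n >= 2", call. = FALSE)
  dens <- if (likelihood == "t") {
    function(theta) stats::dt((mean_diff - theta) / se, df) / se
  } else {
    function(theta) stats::dnorm(mean_diff, theta, se)
  }
  h0 <- dens(0)
  q <- stats::integrate(dens, lower, upper, rel.tol = 1e-10, abs.tol = 0)
  if (q$message != "OK") stop("quadrature failed: ", q$message, call. = FALSE)
  h1 <- q$value / (upper - lower)
  new_bf_result(h0 / h1,
                sprintf("uniform [%g, %g], %s likelihood, df=%g",
                        lower, upper, likelihood, df),
                list(mean_diff = mean_diff, se = se, n = n))
}

#' Bayes factor for a Pearson correlation under a stretched-beta prior
#'
#' Tests `rho = 0` against a stretched-beta prior on the population
#' correlation: `(rho + 1)/2 ~ Beta(1/width, 1/width)` on `[-1, 1]`, so
#' `width = 1` is the flat (uniform) prior. The marginal likelihood under
#' the alternative integrates the exact sampling density of the Pearson
#' correlation coefficient (Gaussian-data null distribution with a
#' hypergeometric term) over the prior; the null evidence is that density at
#' `rho = 0`.
#'
#' @param r observed Pearson correlation, |r| < 1.
#' @param n sample size, >= 4.
#' @param width stretched-beta prior width (1 = flat).
#' @return a `bf_result`.
#' @export
bf_correlation <- function(r, n, width = 1) {
  stopifnot_scalar(r); stopifnot_scalar(n)
  if (abs(r) >= 1) stop("|r| must be < 1", call. = FALSE)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  prior_d <- function(rho) stats::dbeta((rho + 1) / 2, 1 / width, 1 / width) / 2
  h0 <- pearson_r_density(r, 0, n)
  # integrate in rho; the density decays fast near |rho| -> 1 for moderate n,
  # and the substitution rho = tanh(z) regularises the endpoints
  f <- function(z) vapply(z, function(zi) {
    rho <- tanh(zi)
    pearson_r_density(r, rho, n) * prior_d(rho) * (1 - rho^2)
  }, 0)
  q <- stats::integrate(f, -Inf, Inf, rel.tol = 1e-9)
  if (q$message != "OK") stop("quadrature failed: ", q$message, call. = FALSE)
  new_bf_result(h0 / q$value,
                sprintf("stretched-beta width %g on [-1, 1]", width),
                list(r = r, n = n))
}

# exact sampling density of the Pearson correlation under bivariate
# normality (Hotelling's form, with a 2F1 hypergeometric factor)
pearson_r_density <- function(r, rho, n) {
  lg <- log(n - 2) + lgamma(n - 1) - 0.5 * log(2 * pi) - lgamma(n - 0.5) +
    ((n - 1) / 2) * log1p(-rho^2) + ((n - 4) / 2) * log1p(-r^2) -
    (n - 1.5) * log1p(-rho * r) +
    log_hyper2f1(0.5, 0.5, n - 0.5, (rho * r + 1) / 2)
  exp(lg)
}

# Gauss hypergeometric 2F1 by direct series; converges for z in [0, 1)
# when c - a - b > 0, which holds here (c grows with n)
log_hyper2f1 <- function(a, b, cc, z) {
  if (z < 0 || z >= 1) stop("2F1 series requires 0 <= z < 1", call. = FALSE)
  logterm <- 0; s <- 1
  for (k in seq_len(5000)) {
    logterm <- logterm + log((a + k - 1) * (b + k - 1) / ((cc + k - 1) * k)) + log(z)
    tk <- exp(logterm)
    s <- s + tk
    if (tk < s * 1e-16) return(log(s))
  }
  warning("2F1 series slow to converge")
  log(s)
}

#' Default Bayesian t-test (JZS) Bayes factor from a t statistic
#'
#' One-sample Jeffreys--Zellner--Siow Bayes factor: the alternative places a
#' Cauchy prior with scale `scale` on the standardised effect size delta,
#' the marginal likelihood is the noncentral-t density of the observed t
#' averaged over that prior by adaptive quadrature, and the null is the
#' central-t density. Used for interaction contrasts in the time analyses.
#'
#' @param t_stat observed t value.
#' @param n sample size of the contrast scores (df = n - 1).
#' @param scale Cauchy prior scale r.
#' @return a `bf_result`.
#' @export
jzs_bf <- function(t_stat, n, scale = 0.5) {
  stopifnot_scalar(t_stat); stopifnot_scalar(n)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  if (scale <= 0) stop("'scale' must be positive", call. = FALSE)
  df <- n - 1
  h0 <- stats::dt(t_stat, df)
  f <- function(delta)
    suppressWarnings(stats::dt(t_stat, df, ncp = delta * sqrt(n))) *
      stats::dcauchy(delta, 0, scale)
  q <- stats::integrate(f, -Inf, Inf, rel.tol = 1e-9)
  if (q$message != "OK") stop("quadrature failed: ", q$message, call. = FALSE)
  new_bf_result(h0 / q$value,
                sprintf("JZS Cauchy scale %g", scale),
                list(t = t_stat, n = n))
}

#' One-sample summary of difference scores
#'
#' Mean, SE, t statistic, df, and 95% CI of a vector of per-subject
#' difference scores -- the bridge from the subject table to the
#' summary-level Bayes-factor tests.
#'
#' @param x numeric vector of difference scores.
#' @param level confidence level.
#' @return list with `mean`, `se`, `t`, `df`, `n`, `ci`.
#' @export
ttest_summary <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("need at least 2 finite values", call. = FALSE)
  m <- mean(x); se <- stats::sd(x) / sqrt(n)
  q <- stats::qt(1 - (1 - level) / 2, n - 1)
  list(mean = m, se = se, t = m / se, df = n - 1, n = n,
       ci = c(m - q * se, m + q * se))
}
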