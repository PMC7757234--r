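#' Repeated-measures ANOVA interaction with a linear-trend contrast
#'
#' Classical two-way fully-within-subject ANOVA on a balanced table of cell
#' means (one observation per subject x cell). Reports the overall
#' interaction F test (df `(a-1)(b-1)` over `(a-1)(b-1)(n-1)`) and a focused
#' interaction contrast: per-subject linear-trend scores of the
#' factor-1 difference across factor-2 levels, tested against zero with a
#' one-sample t and accompanied by its JZS Bayes factor -- the package's
#' summary of interaction evidence in place of a full Bayesian
#' model-comparison ANOVA.
#'
#' @param data `data.frame` with columns `subject`, `f1` (2 levels, e.g.
#'   load), `f2` (k levels, e.g. block or minute), `value`; one row per cell.
#' @param trend_weights contrast weights over the levels of `f2`; defaults to
#'   the centred linear trend.
#' @param jzs_scale Cauchy prior scale for the contrast Bayes factor.
#' @param gg if `TRUE`, also report the Greenhouse--Geisser epsilon and the
#'   sphericity-corrected interaction p value.
#' @return object of class `rm_anova_result` with the interaction `F`,
#'   `df1`, `df2`, `p`, the contrast `t`, `df`, `p`, and `bf01`.
#' @export
rm_anova_interaction <- function(data, trend_weights = NULL, jzs_scale = 0.5,
                                 gg = FALSE) {
  stopifnot(all(c("subject", "f1", "f2", "value") %in% names(data)))
  data$subject <- factor(data$subject)
  data$f1 <- factor(data$f1, levels = unique(data$f1))
  data$f2 <- factor(data$f2, levels = unique(data$f2))
  a <- nlevels(data$f1); b <- nlevels(data$f2); n <- nlevels(data$subject)
  if (a != 2) stop("'f1' must have exactly 2 levels", call. = FALSE)
  if (nrow(data) != a * b * n || anyNA(data$value))
    stop("table must be complete and balanced (one value per subject x cell)",
         call. = FALSE)

  y <- array(NA_real_, c(n, a, b))
  y[cbind(as.integer(data$subject), as.integer(data$f1),
          as.integer(data$f2))] <- data$value

  m_ij <- apply(y, c(2, 3), mean)          # cell means
  m_i <- rowMeans(m_ij); m_j <- colMeans(m_ij); m <- mean(m_ij)
  m_si <- apply(y, c(1, 2), mean); m_sj <- apply(y, c(1, 3), mean)
  m_s <- apply(y, 1, mean)

  ss_int <- n * sum((m_ij - outer(m_i, rep(1, b)) -
                       outer(rep(1, a), m_j) + m)^2)
  resid <- y
  for (s in seq_len(n)) for (i in seq_len(a)) for (j in seq_len(b))
    resid[s, i, j] <- y[s, i, j] - m_ij[i, j] -
      (m_si[s, i] - m_i[i]) - (m_sj[s, j] - m_j[j]) + (m_s[s] - m)
  ss_err <- sum(resid^2)

  df1 <- (a - 1) * (b - 1); df2 <- (a - 1) * (b - 1) * (n - 1)
  if (ss_int <= .Machine$double.eps * max(1, sum(y^2))) {
    Fv <- 0; p <- 1
  } else {
    Fv <- (ss_int / df1) / (ss_err / df2)
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  }

  if (is.null(trend_weights)) trend_weights <- seq_len(b) - (b + 1) / 2
  if (length(trend_weights) != b)
    stop("'trend_weights' must match the levels of f2", call. = FALSE)
  diff_sb <- y[, 1, , drop = TRUE] - y[, 2, , drop = TRUE]  # n x b
  if (is.null(dim(diff_sb))) diff_sb <- matrix(diff_sb, nrow = n)
  scores <- drop(diff_sb %*% trend_weights)
  if (stats::sd(scores) == 0) {
    # degenerate contrast: identical scores carry no trend evidence when
    # zero, and overwhelming evidence otherwise
    t_c <- if (mean(scores) == 0) 0 else sign(mean(scores)) * Inf
    ts <- list(t = t_c, df = n - 1L, n = n)
  } else {
    ts <- ttest_summary(scores)
  }
  contrast_bf <- if (is.finite(ts$t)) jzs_bf(ts$t, ts$n, scale = jzs_scale)
                 else list(bf01 = 0)

  out <- list(F = Fv, df1 = df1, df2 = df2, p = p,
              contrast_t = ts$t, contrast_df = ts$df,
              contrast_p = 2 * stats::pt(-abs(ts$t), ts$df),
              contrast_scores = scores,
              jzs_bf01 = contrast_bf$bf01,
              trend_weights = trend_weights,
              n = n, a = a, b = b)
  if (gg) {
    eps <- gg_epsilon(y)
    out$gg_epsilon <- eps
    out$p_gg <- if (Fv == 0) 1 else
      stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
  }
  structure(out, class = "rm_anova_result")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("<rm_anova_result> interaction F(%d, %d) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  cat(sprintf("  linear-trend contrast: t(%d) = %.3f, p = %.4g, BF01 = %.4g\n",
              x$contrast_df, x$contrast_t, x$contrast_p, x$jzs_bf01))
  if (!is.null(x$gg_epsilon))
    cat(sprintf("  Greenhouse-Geisser eps = %.3f, corrected p = %.4g\n",
                x$gg_epsilon, x$p_gg))
  invisible(x)
}

# Greenhouse-Geisser epsilon for the interaction: covariance of the
# orthonormalised interaction contrasts across subjects
gg_epsilon <- function(y) {
  n <- dim(y)[1]; b <- dim(y)[3]
  diff_sb <- y[, 1, , drop = TRUE] - y[, 2, , drop = TRUE]
  if (is.null(dim(diff_sb))) diff_sb <- matrix(diff_sb, nrow = n)
  C <- stats::contr.poly(b)                 # orthonormal, b x (b-1)
  Z <- diff_sb %*% C
  S <- stats::cov(Z)
  min(1, sum(diag(S))^2 / ((b - 1) * sum(S^2)))
}
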