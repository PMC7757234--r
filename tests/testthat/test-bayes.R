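test_that("standard errors recovered from printed CIs match quantile arithmetic", {
  expect_equal(se_from_ci(0, 0.038, df = 42), 0.019 / qt(0.975, 42),
               tolerance = 1e-12)
  expect_equal(se_from_ci(0, 0.038, df = 42), 0.0094149, tolerance = 1e-5)
  expect_equal(se_from_ci(0, 0.038, method = "normal"), 0.0096941,
               tolerance = 1e-5)
  # width-only: the centre of a symmetric CI is irrelevant
  expect_equal(se_from_ci(-1, 1, df = 10), se_from_ci(99, 101, df = 10))
  expect_error(se_from_ci(1, 0, df = 10), "exceed")
  expect_error(se_from_ci(0, 1, method = "t"), "df")
})

test_that("bf_uniform reproduces the closed-form normal case", {
  # mean 0, se 0.01, prior [-1, 1]: H0 density dnorm(0,0,.01) = 39.894,
  # H1 = 1/2 * (integral of the normal over [-1,1]) = 0.5 -> BF01 = 79.788
  r <- bf_uniform(0, 0.01, n = 50, lower = -1, upper = 1,
                  likelihood = "normal")
  expect_equal(r$bf01, dnorm(0, 0, 0.01) / 0.5, tolerance = 1e-6)
  expect_equal(r$bf01, 79.78846, tolerance = 1e-5)
  expect_equal(r$bf01 * r$bf10, 1)
})

test_that("bf_uniform agrees with an independent Simpson-rule oracle to 1e-4", {
  simpson_bf <- function(m, se, df, a, b, lik) {
    x <- seq(a, b, length.out = 20001)
    dens <- if (lik == "t") dt((m - x) / se, df) / se else dnorm(m, x, se)
    w <- c(1, rep(c(4, 2), (length(x) - 3) / 2), 4, 1)
    h1 <- sum(w * dens) * (x[2] - x[1]) / 3 / (b - a)
    h0 <- if (lik == "t") dt(m / se, df) / se else dnorm(m, 0, se)
    h0 / h1
  }
  cases <- list(c(0.019, 0.0094, 43, -1, 1), c(0.006, 0.0054, 43, 0, 1),
                c(-0.03, 0.02, 20, -1, 1), c(0.08, 0.05, 12, 0, 0.2),
                c(0.15, 0.04, 30, 0, 1))
  for (cs in cases) for (lik in c("t", "normal")) {
    got <- bf_uniform(cs[1], cs[2], cs[3], cs[4], cs[5], likelihood = lik)$bf01
    want <- simpson_bf(cs[1], cs[2], cs[3] - 1, cs[4], cs[5], lik)
    expect_equal(got, want, tolerance = 1e-4)
  }
})

test_that("a symmetric prior makes the Bayes factor depend on |mean| only", {
  a <- bf_uniform(0.03, 0.01, 43, -1, 1)$bf01
  b <- bf_uniform(-0.03, 0.01, 43, -1, 1)$bf01
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("t and normal likelihood modes agree closely at df >= 40", {
  # at the study's summary scale the conventions differ by a few percent at
  # most: ~3-4% where the observed mean sits ~2 SE from zero (the t tail is
  # heavier there), ~1% nearer the null
  itc <- c(0.019, 0.0097); amp <- c(0.006, 0.0054)
  ratio <- function(cs)
    bf_uniform(cs[1], cs[2], 43, -1, 1, likelihood = "t")$bf01 /
    bf_uniform(cs[1], cs[2], 43, -1, 1, likelihood = "normal")$bf01
  expect_lt(abs(ratio(itc) - 1), 0.05)
  expect_lt(abs(ratio(amp) - 1), 0.02)
})

test_that("the Pearson-r sampling density is a proper, well-calibrated density", {
  dens <- function(r, rho, n) assrload:::pearson_r_density(r, rho, n)
  for (cfg in list(c(0, 43), c(0.5, 20), c(-0.7, 12))) {
    total <- integrate(function(r) sapply(r, dens, rho = cfg[1], n = cfg[2]),
                       -1, 1, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  # tail probability matches an empirical draw of Pearson correlations
  set.seed(9); n <- 20; rho <- 0.5; reps <- 4000
  rs <- vapply(seq_len(reps), function(i) {
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    cor(x, y)
  }, 0)
  p_emp <- mean(rs <= 0.5)
  p_th <- integrate(function(r) sapply(r, dens, rho = rho, n = n),
                    -1, 0.5, rel.tol = 1e-9)$value
  expect_lt(abs(p_emp - p_th), 3 * sqrt(p_th * (1 - p_th) / reps))
})

test_that("the flat-prior correlation Bayes factor is symmetric and sensible", {
  expect_equal(bf_correlation(0.25, 43)$bf01, bf_correlation(-0.25, 43)$bf01,
               tolerance = 1e-6)
  # stronger observed correlations give less support for the null
  bfs <- vapply(c(0, 0.2, 0.4, 0.6), function(r) bf_correlation(r, 43)$bf01, 0)
  expect_identical(order(bfs, decreasing = TRUE), 1:4)
  expect_error(bf_correlation(1, 43), "< 1")
  expect_error(bf_correlation(0.1, 3), "n >= 4")
})

test_that("the JZS Bayes factor matches the g-prior integral to 1e-4", {
  # independent route: delta | g ~ N(0, g), g ~ InvGamma(1/2, r^2/2)
  gprior_bf01 <- function(t, n, r) {
    nu <- n - 1
    h1 <- integrate(function(g) {
      (1 + n * g)^(-1 / 2) *
        (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
        (r^2 / 2)^(1 / 2) / gamma(1 / 2) * g^(-3 / 2) * exp(-r^2 / (2 * g))
    }, 0, Inf, rel.tol = 1e-10)$value
    (1 + t^2 / nu)^(-(nu + 1) / 2) / h1
  }
  for (cs in list(c(2.5, 43, 0.5), c(0.8, 20, 0.707), c(-1.7, 30, 0.5),
                  c(0, 43, 0.5))) {
    expect_equal(jzs_bf(cs[1], cs[2], cs[3])$bf01,
                 gprior_bf01(cs[1], cs[2], cs[3]), tolerance = 1e-4)
  }
})

test_that("JZS limits behave: null evidence grows with n at t = 0, vanishing scale is inert", {
  bfs <- vapply(c(10, 20, 40, 80, 160), function(n) jzs_bf(0, n)$bf01, 0)
  expect_true(all(diff(bfs) > 0))
  expect_equal(jzs_bf(1.3, 25, scale = 1e-5)$bf01, 1, tolerance = 1e-3)
})

test_that("evidence labels follow the 3/10/30/100 scheme on both sides", {
  expect_match(assrload:::bf_evidence_label(5), "moderate for null")
  expect_match(assrload:::bf_evidence_label(12), "strong for null")
  expect_match(assrload:::bf_evidence_label(45), "very strong for null")
  expect_match(assrload:::bf_evidence_label(250), "extreme for null")
  expect_match(assrload:::bf_evidence_label(1 / 50), "very strong for alternative")
  expect_match(assrload:::bf_evidence_label(2), "anecdotal for null")
})
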