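test_that("spectrum scaling is exact for bin-centred sinusoids and constants", {
  fs <- 1024; n <- 1600
  t <- (0:(n - 1)) / fs
  sp <- amplitude_spectrum(0.24 * sin(2 * pi * 40.96 * t), fs)
  expect_equal(sp$freqs[2] - sp$freqs[1], 0.64)     # 1 / 1.5625 s
  bin <- which(sp$freqs == 40.96)
  expect_identical(bin, 65L)                        # 40.96 / 0.64 = 64 (0-based)
  expect_equal(sp$values[bin], 0.24, tolerance = 1e-9)
  expect_lt(max(sp$values[-bin]), 1e-9)
  # unit sinusoid reads exactly 1.0
  u <- amplitude_spectrum(sin(2 * pi * 40.96 * t), fs)
  expect_equal(u$values[bin], 1, tolerance = 1e-9)
  # DC convention
  dc <- amplitude_spectrum(rep(3, n), fs)
  expect_equal(dc$values[1], 3, tolerance = 1e-9)
  expect_lt(max(dc$values[-1]), 1e-9)
  expect_true(all(amplitude_spectrum(numeric(n), fs)$values == 0))
  expect_error(amplitude_spectrum(numeric(0), fs), "empty")
  expect_error(amplitude_spectrum(numeric(15), fs), "even")
})

test_that("SmN uses exactly the ten noise bins per side beyond the skipped neighbours", {
  freqs <- (0:200) * 0.64
  vals <- numeric(201)
  bin <- 65  # 40.96 Hz
  vals[bin] <- 5
  vals[c(bin - 1, bin - 2, bin + 1, bin + 2)] <- 99   # skipped: must be ignored
  vals[c(bin - (3:12), bin + (3:12))] <- 1            # the 20 noise bins
  spec <- structure(list(freqs = freqs, values = vals, kind = "amplitude"),
                    class = "assr_spectrum")
  res <- compute_smn(spec)
  expect_equal(res$S, 5)
  expect_equal(res$N, 1)
  expect_equal(res$SmN, 4)
  expect_equal(res$SNR, 5)
  # flat spectrum: SmN 0, SNR 1; adding a constant never changes SmN
  flat <- structure(list(freqs = freqs, values = rep(2, 201), kind = "amplitude"),
                    class = "assr_spectrum")
  expect_equal(compute_smn(flat)$SmN, 0)
  expect_equal(compute_smn(flat)$SNR, 1)
  spec2 <- spec; spec2$values <- spec2$values + 7
  expect_equal(compute_smn(spec2)$SmN, res$SmN, tolerance = 1e-12)
  # off-grid target and edge targets error
  expect_error(compute_smn(spec, target_hz = 40.5), "grid")
  expect_error(compute_smn(spec, target_hz = 0.64 * 5), "neighbouring")
  # alternative one-per-side skip convention shifts the noise set
  res1 <- compute_smn(spec, skip_side = 1)
  expect_equal(res1$N, mean(vals[c(bin - (2:11), bin + (2:11))]))
})

test_that("printed component values reproduce the SmN arithmetic", {
  mk <- function(S, N, kind) {
    vals <- rep(N, 201); vals[65] <- S
    structure(list(freqs = (0:200) * 0.64, values = vals, kind = kind),
              class = "assr_spectrum")
  }
  expect_equal(compute_smn(mk(0.24, 0.05, "amplitude"))$SmN, 0.19)
  expect_equal(itc_smn(mk(0.38, 0.08, "itc"))$SmN, 0.30)
})

test_that("white-noise-only spectra give SmN centred on zero", {
  set.seed(42)
  vals <- vapply(1:200, function(i) {
    mw <- rnorm(1600) / sqrt(20)  # mean of 20 white epochs
    compute_smn(amplitude_spectrum(mw, 1024))$SmN
  }, 0)
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 3 * se)
})

test_that("ITC is 1 for identical epochs, bounded in [0,1], and errors below 2 epochs", {
  t <- (0:1599) / 1024
  one <- sin(2 * pi * 40.96 * t) + 0.3 * sin(2 * pi * 10.24 * t)
  arr <- array(rep(one, each = 12), c(12, 1, 1600))
  itc <- compute_itc(toy_epochs(arr))
  energetic <- itc$freqs %in% c(10.24, 40.96)
  expect_equal(itc$values[energetic], c(1, 1), tolerance = 1e-9)
  expect_true(all(itc$values >= 0 & itc$values <= 1 + 1e-12))

  set.seed(1)
  noisy <- array(rnorm(12 * 1 * 1600), c(12, 1, 1600))
  v <- compute_itc(toy_epochs(noisy))$values
  expect_true(all(v >= 0 & v <= 1))

  ep1 <- toy_epochs(arr); ep1$rejected[2:12] <- TRUE
  expect_error(compute_itc(ep1), "at least 2")
})

test_that("uniform phase at the target bin gives the Rayleigh resultant mean", {
  set.seed(7)
  t <- (0:1599) / 1024
  M <- 115
  vals <- vapply(1:60, function(i) {
    ph <- runif(M, 0, 2 * pi)
    arr <- array(0, c(M, 1, 1600))
    for (m in 1:M) arr[m, 1, ] <- sin(2 * pi * 40.96 * t + ph[m])
    itc <- compute_itc(toy_epochs(arr))
    itc$values[itc$freqs == 40.96]
  }, 0)
  expected <- sqrt(pi) / (2 * sqrt(M))   # ~0.0827
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - expected), 3 * se)
})

test_that("ITC decreases monotonically with phase jitter", {
  set.seed(11)
  t <- (0:1599) / 1024
  jitters <- c(0, 0.4, 0.8, 1.2, 1.8)
  means <- vapply(jitters, function(j) {
    mean(vapply(1:30, function(i) {
      ph <- rnorm(40, 0, j)
      arr <- array(0, c(40, 1, 1600))
      for (m in 1:40) arr[m, 1, ] <- sin(2 * pi * 40.96 * t + ph[m]) +
          0.5 * rnorm(1600)
      itc <- compute_itc(toy_epochs(arr))
      itc$values[itc$freqs == 40.96]
    }, 0))
  }, 0)
  expect_identical(order(means, decreasing = TRUE), seq_along(jitters))
})

test_that("averaging waveforms before the FFT gives a lower noise floor than after", {
  set.seed(5)
  t <- (0:1599) / 1024
  arr <- array(0, c(30, 1, 1600))
  for (m in 1:30) arr[m, 1, ] <- 0.24 * sin(2 * pi * 40.96 * t) + 3 * rnorm(1600)
  ep <- toy_epochs(arr)
  # package path: mean waveform first
  first <- compute_smn(amplitude_spectrum(mean_waveform(ep, "ch1"), 1024))
  # reference alternative: transform each epoch, then average magnitudes
  specs <- sapply(1:30, function(m)
    amplitude_spectrum(arr[m, 1, ], 1024)$values)
  alt <- structure(list(freqs = (0:800) * 0.64, values = rowMeans(specs),
                        kind = "amplitude"),
                   class = "assr_spectrum")
  second <- compute_smn(alt)
  expect_gt(second$N, 3 * first$N)  # incoherent averaging inflates the floor
  expect_gt(first$SmN, second$SmN)  # and eats into the SmN measure
})
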