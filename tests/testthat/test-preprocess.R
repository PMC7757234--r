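test_that("the high-pass filter removes offsets and drift but spares 40.96 Hz", {
  fs <- 1024
  t <- (0:(fs * 30 - 1)) / fs
  rec <- toy_recording(rbind(Fz = 50 + sin(2 * pi * 40.96 * t), nose = 0))
  out <- highpass_filter(rec)
  mid <- (10 * fs):(20 * fs)
  # offset gone (edge transients excluded)
  resid <- out$data["Fz", mid] - sin(2 * pi * 40.96 * t[mid])
  expect_lt(max(abs(resid)), 0.02 * 50)
  # 40.96-Hz amplitude preserved (clean sinusoid, no transient in the way)
  pure <- highpass_filter(toy_recording(
    rbind(Fz = sin(2 * pi * 40.96 * t), nose = 0)))
  amp_ratio <- sqrt(mean(pure$data["Fz", mid]^2) /
                    mean(sin(2 * pi * 40.96 * t[mid])^2))
  expect_lt(abs(amp_ratio - 1), 1e-3)

  # slow 0.01-Hz drift of 50 uV is suppressed below 5 uV mid-record
  t2 <- (0:(fs * 200 - 1)) / fs
  drift <- toy_recording(rbind(Fz = 50 * sin(2 * pi * 0.01 * t2), nose = 0))
  outd <- highpass_filter(drift)
  expect_lt(max(abs(outd$data["Fz", (90 * fs):(110 * fs)])), 5)

  expect_error(highpass_filter(rec, cutoff_hz = 600), "Nyquist")
})

test_that("re-referencing subtracts the reference samplewise and is idempotent", {
  fs <- 1024
  s <- sin(2 * pi * 7 * (0:2047) / fs); r <- cos(2 * pi * 3 * (0:2047) / fs)
  rec <- toy_recording(rbind(Fz = s, nose = r))
  out <- rereference(rec)
  expect_equal(out$data["Fz", ], s - r, tolerance = 1e-12)
  expect_false("nose" %in% out$channels)

  # referencing a channel to itself zeroes it
  rec2 <- toy_recording(rbind(Fz = s, nose = s))
  expect_true(all(abs(rereference(rec2)$data) < 1e-12))

  # with a zeroed reference the operation is idempotent
  rec3 <- toy_recording(rbind(Fz = s, FCz = r, nose = numeric(2048)))
  once <- rereference(rec3, c("Fz", "FCz"), "nose")
  rec3b <- toy_recording(rbind(once$data, nose = numeric(2048)))
  twice <- rereference(rec3b, c("Fz", "FCz"), "nose")
  expect_equal(once$data, twice$data, tolerance = 1e-12)

  expect_error(rereference(rec, reference = "M1"), "not present")
  expect_error(rereference(rec, channels = "Pz"), "missing")
})

test_that("epoch segmentation is exact integer arithmetic with no drift", {
  fs <- 1024
  n <- round(180.5 * fs)
  ramp <- seq_len(n)  # sample index as signal: epochs index their own samples
  rec <- toy_recording(rbind(Fz = ramp, nose = numeric(n)))
  ep <- segment_assr_epochs(rec)
  expect_identical(dim(ep$data), c(115L, 2L, 1600L))
  for (k in c(1, 57, 115))
    expect_equal(ep$data[k, 1, ], ramp[((k - 1) * 1600 + 1):(k * 1600)])
  # one epoch from exactly one epoch length of data
  rec1 <- toy_recording(rbind(Fz = numeric(1600), nose = numeric(1600)))
  expect_identical(dim(segment_assr_epochs(rec1, n_epochs = NULL)$data)[1], 1L)
  expect_error(segment_assr_epochs(rec1, n_epochs = 2), "too short")
  # concatenating epochs loses no samples within the covered span
  expect_equal(as.numeric(t(ep$data[, 1, ])), ramp[1:(115 * 1600)])
})

test_that("range rejection flags exactly the contaminated epoch and is label-blind", {
  arr <- array(0, c(10, 2, 1600))
  arr[4, 1, 300:700] <- 150 * sin(seq(0, pi, length.out = 401))  # 150-uV blink
  ep <- toy_epochs(arr, channels = c("Fz", "FCz"))
  out <- reject_by_range(ep, cutoff_uV = 100)
  expect_identical(which(out$rejected), 4L)
  expect_equal(retention(out), 0.9)
  # infinite cutoff keeps everything
  expect_equal(retention(reject_by_range(ep, cutoff_uV = Inf)), 1)
  # rejection never consults condition labels
  ep2 <- ep; ep2$meta <- list(condition = "high")
  expect_identical(reject_by_range(ep2, 100)$rejected, out$rejected)
  # percentile rule rejects the top of the range distribution
  outp <- reject_by_range(ep, method = "percentile", percentile = 0.85)
  expect_true(outp$rejected[4])
})

test_that("the printed retention example and threshold boundary behave as specified", {
  expect_equal(round(100 * 104 / 115, 1), 90.4)
  expect_false(retention_check(c(1, 1, 1, 1)))
  expect_true(retention_check(c(1, 0.69, 1, 1)))
  expect_false(retention_check(c(0.70, 1)))  # rule is strictly 'less than'
})

test_that("re-referencing commutes with epoch segmentation", {
  d <- small_design(trials = 20)
  tr <- ground_truth("study1")
  rec <- simulate_recording(d, tr, stimulus_spec(), 1, 1, "low", seed = 4)
  a <- segment_assr_epochs(rereference(rec), n_epochs = 5)
  b <- segment_assr_epochs(rec, n_epochs = 5)
  nose <- match("nose", b$channels)
  for (ch in a$channels) {
    ci <- match(ch, b$channels)
    expect_equal(a$data[, match(ch, a$channels), ],
                 b$data[, ci, ] - b$data[, nose, ], tolerance = 1e-12)
  }
})
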