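mk_events <- function(codes, period = 2) {
  # widely spaced trials so windows are unambiguous
  times <- 0.2 + (seq_along(codes) - 1) * period
  data.frame(onset_sample = round(times * 1024) + 1L, time_s = times,
             code = paste0("stim_", codes), stringsAsFactors = FALSE)
}

test_that("response classification applies the 200-1000 ms window rule", {
  ev <- mk_events(c("target", "nontarget", "target", "nontarget"))
  no_resp <- classify_responses(ev, data.frame(time_s = numeric(0)), lead_in = 0)
  expect_identical(no_resp$hits, 0L)
  expect_identical(no_resp$false_alarms, 0L)

  # +0.5 s after the first target: a hit with that latency
  r <- classify_responses(ev, data.frame(time_s = ev$time_s[1] + 0.5),
                          lead_in = 0)
  expect_identical(r$hits, 1L)
  expect_equal(r$hit_rts, 0.5)

  # +1.2 s after a target and outside all other windows: a miss plus a false alarm
  r2 <- classify_responses(ev, data.frame(time_s = ev$time_s[1] + 1.2),
                           lead_in = 0)
  expect_identical(r2$hits, 0L)
  expect_identical(r2$misses, 2L)
  expect_identical(r2$false_alarms, 1L)

  # double press in one window counts once; boundary presses land inside
  r3 <- classify_responses(
    ev, data.frame(time_s = ev$time_s[1] + c(0.3, 0.6, 1.0)), lead_in = 0)
  expect_identical(r3$hits, 1L)
  expect_equal(r3$hit_rts, 0.3)
  expect_identical(r3$false_alarms, 0L)

  # overlapping windows are impossible by design and refused
  bad <- mk_events(c("target", "target"), period = 0.5)
  expect_error(classify_responses(bad, data.frame(time_s = 1), lead_in = 0),
               "overlapping")
})

test_that("d-prime matches inverse-normal arithmetic and stays finite at ceiling", {
  # hit rate .9, FA rate .1, no correction: qnorm(.9) - qnorm(.1)
  r <- compute_dprime(toy_counts(90, 10, 100, 100), correction = "none")
  expect_equal(r$dprime, 2.563103, tolerance = 1e-6)
  expect_equal(r$criterion, 0, tolerance = 1e-9)

  # perfect block: log-linear correction keeps d-prime finite;
  # frozen from the correction arithmetic qnorm(72.5/73) - qnorm(0.5/289)
  ceil <- compute_dprime(toy_counts(72, 0, 72, 288))
  expect_true(is.finite(ceil$dprime))
  expect_equal(ceil$dprime, 5.38868, tolerance = 1e-5)
  # without correction the same counts diverge
  expect_identical(compute_dprime(toy_counts(72, 0, 72, 288),
                                  correction = "none")$dprime, Inf)
  # equal rates give zero sensitivity
  expect_equal(compute_dprime(toy_counts(36, 144, 72, 288),
                              correction = "none")$dprime, 0)
})

test_that("d-prime is monotone in hits and antitone in false alarms", {
  base <- compute_dprime(toy_counts(50, 20, 72, 288))$dprime
  expect_gt(compute_dprime(toy_counts(60, 20, 72, 288))$dprime, base)
  expect_lt(compute_dprime(toy_counts(50, 40, 72, 288))$dprime, base)
})

test_that("reaction-time summaries follow their definition", {
  expect_equal(mean_rt(toy_counts(2, 0, 72, 288, hit_rts = c(0.4, 0.4)))$mean_s, 0.4)
  r <- mean_rt(toy_counts(2, 0, 72, 288, hit_rts = c(0.3, 0.5)))
  expect_equal(r$mean_s, 0.4)
  expect_identical(r$n, 2L)
  expect_warning(z <- mean_rt(toy_counts(0, 0, 72, 288)), "no hits")
  expect_true(is.na(z$mean_s))
})

test_that("PCU is the unweighted mean over sequences, order-invariant", {
  perfect <- toy_ospan(rep(2:6, each = 3))
  expect_equal(compute_pcu(perfect)$pcu, 1)

  # a length-4 sequence with 2 correct letters scores 0.5
  rec <- toy_ospan(c(2, 0, 1, 3, 3, 3, 4, 2, 4, 5, 5, 5, 6, 6, 6))
  props <- compute_pcu(rec)$per_sequence
  expect_equal(props[8], 0.5)
  # sequence proportions (1, 0, 0.5) on the short items: PCU averages
  # sequences, not letters, so short sequences carry full weight
  expect_equal(compute_pcu(rec)$pcu, 13 / 15)
  item_weighted <- sum(rec$n_correct) / sum(rec$length)
  expect_false(isTRUE(all.equal(compute_pcu(rec)$pcu, item_weighted)))

  shuffled <- rec[sample(15), ]
  expect_equal(compute_pcu(shuffled)$pcu, compute_pcu(rec)$pcu)

  expect_error(compute_pcu(rec[-1, ]), "15 sequences")
  bad <- rec; bad$n_correct[1] <- 5
  expect_error(compute_pcu(bad), "invalid")
})

test_that("simulated behaviour recovers the generating sensitivity", {
  # oracle: binomial simulation of hit/FA counts pushed through the same
  # log-linear z-transform, independent of the event machinery
  d <- study_design("study1")
  oracle_mean <- function(dp, crit, reps, seed) {
    set.seed(seed)
    mean(vapply(seq_len(reps), function(i) {
      h <- rbinom(1, 288, pnorm(dp / 2 - crit))
      f <- rbinom(1, 1152, pnorm(-dp / 2 - crit))
      qnorm((h + 0.5) / 289) - qnorm((f + 0.5) / 1153)
    }, 0))
  }
  pipeline_est <- function(dp, reps) vapply(seq_len(reps), function(i) {
    tr <- quiet_truth(dprime = c(low = dp, high = dp))
    blocks <- lapply(1:4, function(b) {
      ev <- generate_event_sequence(d, "low", i * 10 + b)
      classify_responses(ev, simulate_behavior(ev, tr, "low", i * 10 + b))
    })
    compute_dprime(pool_counts(blocks))$dprime
  }, 0)
  for (dp in c(2.607, 4.324)) {
    est <- pipeline_est(dp, 100)
    target <- oracle_mean(dp, 0.5, 4000, seed = round(dp * 100))
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - target), 3 * se + 0.01)
  }
})
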