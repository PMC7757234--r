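#' Classify button presses into hits and false alarms
#'
#' A press between 0.2 and 1.0 s after a target onset is that target's hit
#' (at most one hit per target: the first press in the window; extra presses
#' inside the same window are ignored). Every press outside all target
#' windows is a false alarm. Targets are guaranteed non-overlapping response
#' windows by the minimum-gap design; overlapping windows raise an error.
#'
#' @param events event table for the block(s).
#' @param responses `data.frame` with a `time_s` column of press times, as
#'   returned by [simulate_behavior()].
#' @param hit_window response window after target onset, seconds.
#' @param lead_in number of lead-in trials excluded from the nontarget count.
#' @return an object of class `detection_counts`: `hits`, `misses`,
#'   `false_alarms`, `correct_rejections`, `n_targets`, `n_nontargets`, and
#'   the hit latencies `hit_rts` (seconds).
#' @export
classify_responses <- function(events, responses, hit_window = c(0.2, 1.0),
                               lead_in = 7L) {
  cnt <- event_counts(events, drop_lead_in = TRUE, lead_in = lead_in)
  tg <- events$time_s[events$code == "stim_target"]
  if (length(tg) > 1 && any(diff(sort(tg)) < diff(hit_window)))
    stop("overlapping target response windows", call. = FALSE)
  press <- sort(responses$time_s)
  hit_rts <- numeric(0)
  used <- rep(FALSE, length(press))
  for (t0 in tg) {
    in_win <- which(!used & press >= t0 + hit_window[1] & press <= t0 + hit_window[2])
    if (length(in_win)) {
      hit_rts <- c(hit_rts, press[in_win[1]] - t0)
      used[in_win] <- TRUE   # extra presses in the window count once
    }
  }
  fas <- sum(!used)
  structure(list(hits = length(hit_rts),
                 misses = as.integer(cnt[["targets"]] - length(hit_rts)),
                 false_alarms = fas,
                 correct_rejections = as.integer(cnt[["nontargets"]] - fas),
                 n_targets = as.integer(cnt[["targets"]]),
                 n_nontargets = as.integer(cnt[["nontargets"]]),
                 hit_window = hit_window,
                 hit_rts = hit_rts),
            class = "detection_counts")
}

#' Pool detection counts across blocks
#'
#' @param ... `detection_counts` objects (or a single list of them).
#' @return a pooled `detection_counts`.
#' @export
pool_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "detection_counts")) xs <- xs[[1]]
  out <- xs[[1]]
  for (x in xs[-1]) {
    for (f in c("hits", "misses", "false_alarms", "correct_rejections",
                "n_targets", "n_nontargets"))
      out[[f]] <- out[[f]] + x[[f]]
    out$hit_rts <- c(out$hit_rts, x$hit_rts)
  }
  out
}

#' Detection sensitivity d-prime
#'
#' `d' = z(hit rate) - z(false-alarm rate)`. The default log-linear
#' correction adds 0.5 to the hit and false-alarm counts and 1 to the
#' denominators before the z-transform, keeping d' finite at ceiling
#' performance (perfect hit rates are routine in the low-load condition).
#'
#' @param counts a `detection_counts` object.
#' @param correction `"loglinear"` or `"none"`.
#' @return object of class `dprime_result` with `dprime`, `hit_rate`,
#'   `fa_rate`, `criterion`, `correction`.
#' @export
compute_dprime <- function(counts, correction = c("loglinear", "none")) {
  stopifnot(inherits(counts, "detection_counts"))
  correction <- match.arg(correction)
  if (correction == "loglinear") {
    h <- (counts$hits + 0.5) / (counts$n_targets + 1)
    f <- (counts$false_alarms + 0.5) / (counts$n_nontargets + 1)
  } else {
    h <- counts$hits / counts$n_targets
    f <- counts$false_alarms / counts$n_nontargets
  }
  structure(list(dprime = stats::qnorm(h) - stats::qnorm(f),
                 hit_rate = h, fa_rate = f,
                 criterion = -(stats::qnorm(h) + stats::qnorm(f)) / 2,
                 correction = correction),
            class = "dprime_result")
}

#' @export
print.dprime_result <- function(x, ...) {
  cat(sprintf("<dprime_result> d'=%.3f (hit %.3f, fa %.4f, c=%.3f, %s)\n",
              x$dprime, x$hit_rate, x$fa_rate, x$criterion, x$correction))
  invisible(x)
}

#' Mean and SD of hit reaction times
#'
#' @param counts a `detection_counts` object holding hit latencies.
#' @return list with `mean_s`, `sd_s`, `n`; zero hits yield `NA` values with
#'   a warning.
#' @export
mean_rt <- function(counts) {
  stopifnot(inherits(counts, "detection_counts"))
  if (!length(counts$hit_rts)) {
    warning("no hits: reaction time undefined")
    return(list(mean_s = NA_real_, sd_s = NA_real_, n = 0L))
  }
  list(mean_s = mean(counts$hit_rts),
       sd_s = stats::sd(counts$hit_rts),
       n = length(counts$hit_rts))
}

#' Partial-credit-unit working-memory score
#'
#' For each letter sequence, the proportion of letters recalled in the
#' correct position; the PCU is the unweighted mean of those proportions
#' across the 15 sequences, so a short sequence carries the same weight as a
#' long one (this distinguishes partial-credit-unit scoring from
#' item-weighted scoring).
#'
#' @param records `data.frame(sequence, length, n_correct)` as produced by
#'   [simulate_ospan()].
#' @return object of class `ospan_result` with `per_sequence` proportions and
#'   the scalar `pcu`.
#' @export
compute_pcu <- function(records) {
  need <- rep(2:6, each = 3)
  if (nrow(records) != length(need) ||
      !identical(sort(records$length), sort(need)))
    stop("expected 15 sequences: lengths 2-6, three of each", call. = FALSE)
  if (any(records$n_correct > records$length) || any(records$n_correct < 0))
    stop("invalid recall counts", call. = FALSE)
  prop <- records$n_correct / records$length
  structure(list(per_sequence = prop, pcu = mean(prop)),
            class = "ospan_result")
}
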