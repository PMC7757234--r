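#' Configuration of a full simulated study run
#'
#' Bundles design, ground truth, stimulus, preprocessing parameters, prior
#' specifications, and the master seed. A configuration plus its seed fully
#' determines every number [run_study()] produces. The defaults reproduce
#' the full study conditions; tests and examples pass smaller `n_subjects` /
#' `trials_per_block` to keep runtimes short (per-subject standard errors are
#' estimated from the sample, so scaled-down runs remain internally valid).
#'
#' @param study `"study1"` or `"study2"`.
#' @param seed master integer seed.
#' @param design optional [study_design()] override.
#' @param truth optional [ground_truth()] override.
#' @param stim optional [stimulus_spec()] override.
#' @param n_subjects,trials_per_block,blocks_per_condition convenience
#'   overrides applied to the default design.
#' @param n_assr_epochs steady-state epochs per block; `NULL` = as many as
#'   fit, capped at 115.
#' @param reject_cutoff_uV range-rejection cutoff for steady-state epochs.
#' @param erp_reject_cutoff_uV range-rejection cutoff for visual epochs.
#' @param assr_electrodes electrodes for the steady-state measures.
#' @param erp_electrodes electrodes for the P3 (default Cz, or Cz/CPz/Pz for
#'   the four-condition study).
#' @param priors named list of uniform prior bounds for the mean-difference
#'   Bayes factors.
#' @param bf_likelihood likelihood convention passed to [bf_uniform()].
#' @param jzs_scale Cauchy scale for contrast Bayes factors.
#' @param run_envelope compute the nested 2-Hz analysis (needs blocks of at
#'   least ~20 s).
#' @return an object of class `run_config`.
#' @export
run_config <- function(study = c("study1", "study2"), seed = 1,
                       design = NULL, truth = NULL, stim = NULL,
                       n_subjects = NULL, trials_per_block = NULL,
                       blocks_per_condition = NULL,
                       n_assr_epochs = NULL,
                       reject_cutoff_uV = 200, erp_reject_cutoff_uV = 500,
                       assr_electrodes = c("Fz", "FCz"),
                       erp_electrodes = NULL,
                       priors = list(H1 = c(-1, 1), H2 = c(0, 1), H3 = c(0, 0.2)),
                       bf_likelihood = "t", jzs_scale = 0.5,
                       run_envelope = TRUE) {
  study <- match.arg(study)
  if (is.null(design)) {
    args <- list(study = study)
    if (!is.null(n_subjects)) args$n_subjects <- n_subjects
    if (!is.null(trials_per_block)) args$trials_per_block <- trials_per_block
    if (!is.null(blocks_per_condition)) args$blocks_per_condition <- blocks_per_condition
    design <- do.call(study_design, args)
  }
  if (is.null(truth)) truth <- ground_truth(study)
  if (is.null(stim)) stim <- stimulus_spec()
  if (is.null(erp_electrodes))
    erp_electrodes <- if (study == "study2") c("Cz", "CPz", "Pz") else "Cz"
  structure(list(study = study, seed = as.integer(seed), design = design,
                 truth = truth, stim = stim, n_assr_epochs = n_assr_epochs,
                 reject_cutoff_uV = reject_cutoff_uV,
                 erp_reject_cutoff_uV = erp_reject_cutoff_uV,
                 assr_electrodes = assr_electrodes,
                 erp_electrodes = erp_electrodes,
                 priors = priors, bf_likelihood = bf_likelihood,
                 jzs_scale = jzs_scale, run_envelope = run_envelope),
            class = "run_config")
}

#' Run a complete simulated study
#'
#' Simulates every subject and block, preprocesses the EEG (0.1-Hz zero-phase
#' high-pass, nose re-referencing, epoching, blind range rejection), derives
#' all per-subject measures (spectral amplitude S/N/SmN/SNR and ITC SmN at
#' 40.96 Hz per block; miniblock-wise SmN for the within-block time analysis;
#' nested 2-Hz SmN of the 40-Hz envelope; visual P3 effect; pooled d' and
#' reaction times; partial-credit working-memory score; workload ratings for
#' the four-condition study), and assembles the group-level inference:
#' uniform-prior Bayes factors for each preregistered-style contrast,
#' flat-prior Bayesian correlations with working-memory capacity,
#' load-by-block and load-by-miniblock repeated-measures ANOVAs with
#' linear-trend JZS contrasts, and the 2-Hz modulation test.
#'
#' @param config a [run_config()].
#' @param verbose print per-subject progress to stderr.
#' @return an object of class `assr_study`: list with `subject_table` (tidy
#'   per-subject measures), `group` (contrast table, correlations, ANOVAs,
#'   2-Hz test, ratings summary), `flagged` (advisory retention flags), and
#'   `config`.
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  design <- config$design; truth <- config$truth; stim <- config$stim
  conds <- design$conditions
  rows <- list(); flagged <- logical(design$n_subjects)
  wmc_all <- numeric(design$n_subjects)

  for (s in seq_len(design$n_subjects)) {
    if (verbose) message("subject ", s, "/", design$n_subjects)
    res <- analyze_subject(config, s)
    rows[[s]] <- res$rows
    flagged[s] <- res$flagged
    wmc_all[s] <- res$wmc
  }
  subject_table <- do.call(rbind, rows)
  group <- group_inference(subject_table, config)
  structure(list(subject_table = subject_table, group = group,
                 flagged = flagged, config = config),
            class = "assr_study")
}

#' @export
print.assr_study <- function(x, ...) {
  cat(sprintf("<assr_study> %s: %d subjects, %d measure rows\n",
              x$config$study, x$config$design$n_subjects,
              nrow(x$subject_table)))
  cat("\nContrast Bayes factors (BF01):\n")
  print(x$group$contrasts, digits = 3, row.names = FALSE)
  if (!is.null(x$group$correlations)) {
    cat("\nWorking-memory correlations:\n")
    print(x$group$correlations, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

# simulate + measure one subject; returns tidy rows
analyze_subject <- function(config, s) {
  design <- config$design; truth <- config$truth; stim <- config$stim
  seed_s <- derive_seed(config$seed, s)
  conds <- design$conditions

  # latent subject draws: working-memory capacity, coupled (rho) to the
  # subject's idiosyncratic load effect on response amplitude
  lat <- with_seed(derive_seed(seed_s, 1), {
    z <- stats::rnorm(2)
    z2 <- truth$rho_wmc_load * z[1] + sqrt(1 - truth$rho_wmc_load^2) * z[2]
    list(wmc = min(1, max(0, truth$pcu_mean + truth$pcu_sd * z[1])),
         amp_dev = truth$subject_amp_sd * z2)
  })
  amp_s <- truth$assr_amp_uV
  if ("low" %in% conds) amp_s[["low"]] <- max(0, amp_s[["low"]] + lat$amp_dev / 2)
  if ("high" %in% conds) amp_s[["high"]] <- max(0, amp_s[["high"]] - lat$amp_dev / 2)

  block_conds <- block_order(design, seed_s)
  n_blocks <- length(block_conds)
  rows <- list(); ret <- numeric(n_blocks)
  counts_by_cond <- stats::setNames(vector("list", length(conds)), conds)
  erp_acc <- list()

  for (b in seq_len(n_blocks)) {
    cond <- block_conds[b]
    seed_b <- derive_seed(seed_s, 10 + b)
    events <- generate_event_sequence(design, cond, seed_b, stim$fs)
    responses <- simulate_behavior(events, truth, cond, seed_b)
    rec <- simulate_recording(design, truth, stim, s, b, cond, seed_b,
                              events = embed_responses(events, responses, stim$fs),
                              amp_override = amp_s[[cond]])
    rec <- rereference(highpass_filter(rec))

    ep <- segment_assr_epochs(rec, n_epochs = config$n_assr_epochs)
    ep <- reject_by_range(ep, config$reject_cutoff_uV,
                          channels = config$assr_electrodes)
    ret[b] <- retention(ep)

    smns <- lapply(config$assr_electrodes, function(e)
      compute_smn(amplitude_spectrum(mean_waveform(ep, e), ep$fs)))
    ismn <- itc_smn(compute_itc(ep, config$assr_electrodes))
    add <- function(measure, value, minute = NA_integer_)
      data.frame(subject = s, study = config$study, condition = cond,
                 block = b, minute = minute, measure = measure, value = value,
                 stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- rbind(
      add("amp_S", mean(vapply(smns, `[[`, 0, "S"))),
      add("amp_N", mean(vapply(smns, `[[`, 0, "N"))),
      add("amp_SmN", mean(vapply(smns, `[[`, 0, "SmN"))),
      add("amp_SNR", mean(vapply(smns, `[[`, 0, "SNR"))),
      add("itc_SmN", ismn$SmN),
      add("retention", ret[b]))

    # within-block time course: three contiguous miniblocks of epochs
    # (39/38/38 at the full 115, i.e. successive minutes of stimulation)
    n_ep <- dim(ep$data)[1]
    if (n_ep >= 6) {
      splits <- split(seq_len(n_ep), cut(seq_len(n_ep), 3, labels = FALSE))
      for (mi in 1:3) {
        sub <- ep; keep <- splits[[mi]]
        sub$data <- ep$data[keep, , , drop = FALSE]
        sub$rejected <- ep$rejected[keep]
        if (all(sub$rejected)) next
        v <- mean(vapply(config$assr_electrodes, function(e)
          compute_smn(amplitude_spectrum(mean_waveform(sub, e), ep$fs))$SmN, 0))
        rows[[length(rows) + 1]] <- add("amp_SmN_minute", v, minute = mi)
      }
    }

    if (config$run_envelope &&
        recording_duration(rec) >= design$tone_lead_s + 21) {
      env <- extract_40hz_envelope(rec, channels = config$assr_electrodes)
      if (nrow(env$data) >= 2)
        rows[[length(rows) + 1]] <- add("smn_2hz", nested_2hz_smn(env)$SmN)
    }

    if (cond != "no") {
      cc <- classify_responses(events, responses,
                               lead_in = design$lead_in_nontargets)
      counts_by_cond[[cond]] <- c(counts_by_cond[[cond]], list(cc))
    }

    vis <- segment_visual_epochs(rec, reject_cutoff_uV = config$erp_reject_cutoff_uV,
                                 channels = config$erp_electrodes)
    erp_acc[[cond]] <- c(erp_acc[[cond]], list(vis))

    if (config$study == "study2") {
      rat <- simulate_ratings(truth, cond, seed_b)
      for (k in seq_len(nrow(rat)))
        rows[[length(rows) + 1]] <-
          add(paste0("rating_", rat$scale[k]), rat$rating[k])
    }
  }

  # condition-level measures
  for (cond in conds) {
    add <- function(measure, value)
      data.frame(subject = s, study = config$study, condition = cond,
                 block = NA_integer_, minute = NA_integer_,
                 measure = measure, value = value, stringsAsFactors = FALSE)
    if (!is.null(counts_by_cond[[cond]])) {
      pooled <- pool_counts(counts_by_cond[[cond]])
      dp <- compute_dprime(pooled)
      rt <- mean_rt(pooled)
      rows[[length(rows) + 1]] <- rbind(
        add("dprime", dp$dprime),
        add("hit_rate", dp$hit_rate),
        add("fa_rate", dp$fa_rate),
        add("rt_mean", rt$mean_s))
    }
    if (!is.null(erp_acc[[cond]])) {
      p3 <- pooled_p3(erp_acc[[cond]], config$erp_electrodes)
      if (!is.null(p3))
        rows[[length(rows) + 1]] <- add("p3_effect", p3$effect_uV)
    }
  }

  ospan <- simulate_ospan(truth, seed_s, wmc = lat$wmc)
  rows[[length(rows) + 1]] <- data.frame(
    subject = s, study = config$study, condition = NA_character_,
    block = NA_integer_, minute = NA_integer_, measure = "pcu",
    value = compute_pcu(ospan)$pcu, stringsAsFactors = FALSE)

  list(rows = do.call(rbind, rows), flagged = retention_check(ret),
       wmc = lat$wmc)
}

# block-to-condition assignment: two-condition study alternates load with a
# random starting level; four-condition study randomises within sets of four
block_order <- function(design, seed_s) {
  conds <- design$conditions
  with_seed(derive_seed(seed_s, 2), {
    if (length(conds) == 2) {
      start <- sample(1:2, 1)
      rep(c(conds[start], conds[3 - start]),
          length.out = 2 * design$blocks_per_condition)
    } else {
      unlist(lapply(seq_len(design$blocks_per_condition),
                    function(i) sample(conds)))
    }
  })
}

# responses become events so recordings carry full provenance
embed_responses <- function(events, responses, fs) {
  if (!nrow(responses)) return(events)
  resp <- data.frame(onset_sample = round(responses$time_s * fs) + 1L,
                     time_s = responses$time_s, code = "response",
                     stringsAsFactors = FALSE)
  out <- rbind(events, resp)
  out[order(out$onset_sample), ]
}

# combine per-block visual epochs of one condition into class averages
# weighted by kept-epoch counts, then extract the P3 effect
pooled_p3 <- function(epoch_list, electrodes) {
  acc <- function(stim_class) {
    tot <- NULL; n <- 0; times <- NULL; chans <- NULL
    for (ep in epoch_list) {
      keep <- !ep$rejected & ep$stim_class == stim_class
      if (!any(keep)) next
      sm <- apply(ep$data[keep, , , drop = FALSE], c(2, 3), sum)
      tot <- if (is.null(tot)) sm else tot + sm
      n <- n + sum(keep); times <- ep$times; chans <- ep$channels
    }
    if (n == 0) return(NULL)
    structure(list(times = times, data = tot / n, channels = chans,
                   n_epochs = n, stim_class = stim_class),
              class = "erp_average")
  }
  tg <- acc("target"); ntg <- acc("nontarget")
  if (is.null(tg) || is.null(ntg)) return(NULL)
  p3_effect(tg, ntg, electrodes = electrodes)
}

# group-level inference over the subject table
group_inference <- function(tab, config) {
  conds <- config$design$conditions
  contrasts <- if (config$study == "study1") list(load = c("low", "high"))
    else list(load = c("low", "high"), task = c("no", "low"),
              combined = c("no", "high"))

  cond_means <- function(measure) {
    d <- tab[tab$measure == measure & !is.na(tab$condition), ]
    stats::aggregate(value ~ subject + condition, d, mean)
  }
  diff_scores <- function(measure, pair) {
    cm <- cond_means(measure)
    a <- cm[cm$condition == pair[1], c("subject", "value")]
    b <- cm[cm$condition == pair[2], c("subject", "value")]
    m <- merge(a, b, by = "subject")
    m$value.x - m$value.y
  }

  ## uniform-prior BFs for every contrast x measure x prior
  rows <- list()
  for (measure in c("amp_SmN", "itc_SmN")) {
    for (cn in names(contrasts)) {
      d <- diff_scores(measure, contrasts[[cn]])
      if (length(d) < 3) next
      ts <- ttest_summary(d)
      for (pn in names(config$priors)) {
        pr <- config$priors[[pn]]
        bf <- bf_uniform(ts$mean, ts$se, ts$n, pr[1], pr[2],
                         likelihood = config$bf_likelihood)
        rows[[length(rows) + 1]] <- data.frame(
          measure = measure, contrast = cn, prior = pn,
          mean = ts$mean, ci_l = ts$ci[1], ci_u = ts$ci[2],
          n = ts$n, bf01 = bf$bf01, stringsAsFactors = FALSE)
      }
    }
  }
  contrast_tab <- do.call(rbind, rows)

  ## flat-prior correlations of working memory with the load effect
  pcu <- tab[tab$measure == "pcu", c("subject", "value")]
  cor_rows <- list()
  if (nrow(pcu) >= 4 && "load" %in% names(contrasts)) {
    for (measure in c("amp_SmN", "itc_SmN")) {
      d <- cond_means(measure)
      a <- d[d$condition == contrasts$load[1], c("subject", "value")]
      b <- d[d$condition == contrasts$load[2], c("subject", "value")]
      m <- merge(merge(a, b, by = "subject"), pcu, by = "subject")
      if (nrow(m) < 4) next
      eff <- m$value.x - m$value.y
      r <- stats::cor(m$value, eff)
      bf <- bf_correlation(r, nrow(m))
      cor_rows[[length(cor_rows) + 1]] <- data.frame(
        measure = measure, r = r, n = nrow(m), bf01 = bf$bf01,
        stringsAsFactors = FALSE)
    }
  }
  correlations <- if (length(cor_rows)) do.call(rbind, cor_rows) else NULL

  ## time analyses: load x block and load x miniblock ANOVAs
  anovas <- list()
  pair <- contrasts[[length(contrasts)]]  # load (study1) / combined (study2)
  for (measure in c("amp_SmN", "itc_SmN")) {
    d <- tab[tab$measure == measure & tab$condition %in% pair &
               !is.na(tab$block), ]
    if (nrow(d)) {
      d <- d[order(d$subject, d$condition, d$block), ]
      d$brank <- stats::ave(d$block, d$subject, d$condition,
                            FUN = function(x) rank(x))
      an_d <- data.frame(subject = d$subject,
                         f1 = factor(d$condition, levels = pair),
                         f2 = d$brank, value = d$value)
      complete <- nrow(an_d) ==
        length(unique(an_d$subject)) * 2 * length(unique(an_d$f2))
      if (complete && length(unique(an_d$f2)) >= 2 &&
          length(unique(an_d$subject)) >= 3)
        anovas[[paste0(measure, "_by_block")]] <-
          rm_anova_interaction(an_d, jzs_scale = config$jzs_scale)
    }
  }
  dmin <- tab[tab$measure == "amp_SmN_minute" & tab$condition %in% pair, ]
  if (nrow(dmin)) {
    agg <- stats::aggregate(value ~ subject + condition + minute, dmin, mean)
    an_d <- data.frame(subject = agg$subject,
                       f1 = factor(agg$condition, levels = pair),
                       f2 = agg$minute, value = agg$value)
    complete <- nrow(an_d) == length(unique(an_d$subject)) * 2 * 3
    if (complete && length(unique(an_d$subject)) >= 3)
      anovas$amp_by_minute <- rm_anova_interaction(an_d,
                                                   jzs_scale = config$jzs_scale)
  }

  ## nested 2-Hz modulation: contrast test plus overall level
  smn2 <- NULL
  d2 <- tab[tab$measure == "smn_2hz", ]
  if (nrow(d2)) {
    lvl <- stats::aggregate(value ~ subject, d2, mean)
    out <- list(mean = mean(lvl$value), n = nrow(lvl))
    d <- diff_scores("smn_2hz", contrasts[[length(contrasts)]])
    if (length(d) >= 3) {
      ts <- ttest_summary(d)
      out$diff_mean <- ts$mean; out$diff_ci <- ts$ci
      out$diff_p <- 2 * stats::pt(-abs(ts$t), ts$df)
      out$diff_bf01 <- jzs_bf(ts$t, ts$n, config$jzs_scale)$bf01
    }
    smn2 <- out
  }

  ratings <- if (config$study == "study2") summarize_ratings(tab) else NULL

  list(contrasts = contrast_tab, correlations = correlations,
       anovas = anovas, smn_2hz = smn2, ratings = ratings)
}

#' Per-condition means of the workload ratings
#'
#' Descriptive means of the six Borg CR100 workload scales per condition
#' (the studies report no inferential statistics on the ratings).
#'
#' @param tab a subject table from [run_study()], or any tidy frame with
#'   `measure` columns named `rating_<scale>` plus `condition` and `value`.
#' @return `data.frame(scale, condition, mean)`.
#' @export
summarize_ratings <- function(tab) {
  d <- tab[grepl("^rating_", tab$measure), ]
  if (!nrow(d)) return(NULL)
  if (any(d$value < 0)) stop("negative ratings are invalid", call. = FALSE)
  d$scale <- sub("^rating_", "", d$measure)
  out <- stats::aggregate(value ~ scale + condition, d, mean)
  names(out)[3] <- "mean"
  out[order(out$scale, out$condition), ]
}
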