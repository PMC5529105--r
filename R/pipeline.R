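# Pipeline orchestration: synthesis -> analysis -> recovery suite, driven by
# a single JSON-serializable config. Every threshold actually applied is
# echoed into the run report so a report can be regenerated from its own
# provenance block.

#' Default pipeline configuration
#'
#' All analysis defaults restate the published procedure where one is
#' printed (event windows 100-300 ms from FP/CS and 150-350 ms from reward;
#' lick bins 0.1 s and cue window 0-1.3 s; classification cuts 1-10 Hz /
#' >0.45 ms and >40 Hz; alpha 0.05; persistence 15 and 50 ms) and are
#' documented generator conventions otherwise.
#'
#' @param seed Integer seed.
#' @return Nested named list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    synth = list(
      n_trials = 200, n_da = 2, n_snr = 1,
      inactivation = FALSE, mode = "none",
      psychometrics = FALSE, n_per_cell = 20
    ),
    windows = list(FP = c(0.1, 0.3), CS = c(0.1, 0.3), RW = c(0.15, 0.35)),
    bins = list(psth = 0.01, lick = 0.1, baseline = 0.1, onset = 0.01),
    baseline_window = c(-0.5, 0),
    search_window = c(0, 0.4),
    alpha = 0.05,
    criterion_k = 2,
    persistence_ms = c(15, 50),
    classification = list(da_rate_range = c(1, 10), width_cut = 0.45,
                          snr_rate_min = 40),
    lick = list(cs_window = c(0, 1.3), diff_window = c(0, 0.7),
                baseline_window = c(-1, 0)),
    psycho = list(guess_rate = 0.05, criterion_p = stats::pnorm(1),
                  neighbor_angle_deg = 45, variant = "sine_half_angle")
  )
}

validate_config <- function(config) {
  stopifnot(is.list(config), !is.null(config$seed))
  if (!is.null(config$synth$n_trials) && config$synth$n_trials < 1) {
    stop("config error: synth$n_trials must be >= 1")
  }
  for (w in config$windows) stopifnot(length(w) == 2, w[1] < w[2])
  stopifnot(config$alpha > 0, config$alpha < 1)
  invisible(config)
}

#' Synthesize a session bundle with ground truth
#'
#' Generates a session per the config, validates it, writes the on-disk
#' bundle via [write_session()] and drops the generator ground truth next to
#' it as `truth.json`. Deterministic per seed: identical config yields
#' byte-identical bundles.
#'
#' @param config See [default_config()].
#' @param out_dir Target bundle directory.
#' @return The generated `pavda_session`, invisibly.
#' @export
run_synth <- function(config = default_config(), out_dir) {
  validate_config(config)
  sy <- config$synth
  cfg <- trial_config(inactivation = isTRUE(sy$inactivation))
  mode <- inactivation_mode(sy$mode %||% "none")
  psycho <- if (isTRUE(sy$psychometrics)) psycho_params() else NULL
  sess <- generate_session(
    n_trials = sy$n_trials %||% 200,
    n_da = sy$n_da %||% 2, n_snr = sy$n_snr %||% 1,
    config = cfg, mode = mode, psycho = psycho,
    n_per_cell = sy$n_per_cell %||% 20,
    rng_seed = config$seed
  )
  write_session(sess, out_dir)
  jsonlite::write_json(sess$metadata$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sess)
}

#' Run the full analysis over a session bundle
#'
#' Sequences the analyses over one bundle: unit classification, event-window
#' firing rates with LR/SR Wilcoxon comparisons, per-unit response
#' latencies, the population discrimination-onset test (when at least 6
#' classified DA units are present), lick profiles and the behavioural test
#' battery, the before/during inactivation contrast when epoch labels are
#' present, and the deficit map when psychophysics is present. Tidy CSV and
#' JSON outputs are written under `out_dir`.
#'
#' @param config See [default_config()].
#' @param bundle_dir Session bundle directory (or a `pavda_session`).
#' @param out_dir Output directory; `NULL` to skip writing.
#' @return Run report (nested list), invisibly a `pavda_report`.
#' @export
run_analysis <- function(config = default_config(), bundle_dir,
                         out_dir = NULL) {
  validate_config(config)
  sess <- if (inherits(bundle_dir, "pavda_session")) bundle_dir
          else read_session(bundle_dir)
  trials <- sess$trials
  cl <- config$classification
  report <- list(config = config)

  # --- classification + per-unit window statistics + latency ---------------
  neurons <- list()
  for (id in names(sess$spikes)) {
    st <- sess$spikes[[id]]
    bs <- baseline_stats(st, trials, config$baseline_window,
                         config$bins$baseline)
    width <- spike_width(sess$waveforms[[id]][[1]])
    cls <- classify_neuron(bs["mean"], width,
                           da_rate_range = cl$da_rate_range,
                           width_cut = cl$width_cut,
                           snr_rate_min = cl$snr_rate_min, neuron_id = id)
    wr <- list()
    for (ev in names(config$windows)) {
      a <- window_rate(st, trials, align = ev, window = config$windows[[ev]],
                       condition = "LR")
      b <- window_rate(st, trials, align = ev, window = config$windows[[ev]],
                       condition = "SR")
      wr[[ev]] <- list(lr_mean = mean(a), sr_mean = mean(b))
    }
    lat <- response_latency(st, valid_trials(trials, condition = "LR"),
                            baseline = bs, bin_width = config$bins$psth,
                            criterion_k = config$criterion_k,
                            search_window = config$search_window)
    neurons[[id]] <- list(classification = cls, baseline = as.list(bs),
                          windows = wr, latency_ms = lat$latency_ms)
  }
  report$neurons <- neurons

  da_ids <- names(neurons)[vapply(neurons,
                                  function(n) n$classification$label == "DA",
                                  logical(1))]
  report$da_ids <- da_ids

  # --- population window comparisons (across DA units) ---------------------
  if (length(da_ids) >= 5) {
    pop <- list()
    for (ev in names(config$windows)) {
      a <- vapply(da_ids, function(id) neurons[[id]]$windows[[ev]]$lr_mean,
                  numeric(1))
      b <- vapply(da_ids, function(id) neurons[[id]]$windows[[ev]]$sr_mean,
                  numeric(1))
      pop[[ev]] <- compare_window_rates(a, b, test = "wilcoxon_signed_rank")
    }
    report$population_window_tests <- pop
  }

  # --- discrimination onset ------------------------------------------------
  if (length(da_ids) >= 6) {
    bw <- config$bins$onset
    win <- config$search_window
    lr <- t(vapply(da_ids, function(id)
      neuron_bin_rates(sess$spikes[[id]], trials, "LR",
                       bin_width = bw, window = win),
      numeric(round(diff(win) / bw))))
    sr <- t(vapply(da_ids, function(id)
      neuron_bin_rates(sess$spikes[[id]], trials, "SR",
                       bin_width = bw, window = win),
      numeric(round(diff(win) / bw))))
    bin_starts <- win[1] + (seq_len(ncol(lr)) - 1) * bw
    report$discrimination <- discrimination_onset(
      lr, sr, bin_starts, bw, alpha = config$alpha,
      persistence_ms = config$persistence_ms)
  }

  # --- behaviour -----------------------------------------------------------
  lk <- config$lick
  profile <- lick_rate_profile(sess$licks, trials,
                               bin_width = config$bins$lick)
  report$lick_profile <- profile
  report$behavior <- list(
    cr_lr = cr_rate(sess$licks, trials, "LR", lk$cs_window),
    cr_sr = cr_rate(sess$licks, trials, "SR", lk$cs_window),
    cr_vs_baseline_lr = test_cr_vs_baseline(sess$licks, trials, "LR",
                                            lk$cs_window,
                                            lk$baseline_window)
  )

  if (any(trials$epoch != "none")) {
    before <- cr_summary(sess$licks,
                         valid_trials(trials, epoch = "pre_inactivation"),
                         lk$diff_window)
    during <- cr_summary(sess$licks,
                         valid_trials(trials, epoch = "during_inactivation"),
                         lk$diff_window)
    report$inactivation <- list(before = before, during = during)
  }

  # --- deficit map ---------------------------------------------------------
  if (!is.null(sess$psychometrics)) {
    grid <- unique(sess$psychometrics[, c("ecc_deg", "dir_deg")])
    ps <- config$psycho
    report$deficit_map <- build_deficit_map(
      sess$psychometrics, grid,
      neighbor_angle_deg = ps$neighbor_angle_deg, variant = ps$variant,
      guess_rate = ps$guess_rate, criterion_p = ps$criterion_p)
  }

  if (!is.null(out_dir)) write_report(report, out_dir)
  class(report) <- "pavda_report"
  invisible(report)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  nrows <- lapply(names(report$neurons), function(id) {
    n <- report$neurons[[id]]
    data.frame(neuron_id = id, label = n$classification$label,
               baseline_hz = n$classification$baseline_rate,
               width_ms = n$classification$spike_width,
               latency_ms = n$latency_ms,
               fp_lr = n$windows$FP$lr_mean, fp_sr = n$windows$FP$sr_mean,
               cs_lr = n$windows$CS$lr_mean, cs_sr = n$windows$CS$sr_mean,
               rw_lr = n$windows$RW$lr_mean, rw_sr = n$windows$RW$sr_mean,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, nrows),
                   file.path(out_dir, "neurons.csv"), row.names = FALSE)

  prof <- report$lick_profile
  prof_df <- do.call(rbind, lapply(names(prof$rates), function(cond) {
    data.frame(condition = cond, bin_start = prof$bin_starts,
               rate = prof$rates[[cond]], stringsAsFactors = FALSE)
  }))
  utils::write.csv(prof_df, file.path(out_dir, "lick_profile.csv"),
                   row.names = FALSE)

  if (!is.null(report$deficit_map)) {
    utils::write.csv(report$deficit_map,
                     file.path(out_dir, "deficit_map.csv"),
                     row.names = FALSE)
  }

  summary <- report[setdiff(names(report), c("lick_profile", "neurons"))]
  summary$provenance <- list(
    seed = report$config$seed,
    package_version = as.character(utils::packageVersion("pavda")),
    r_version = R.version.string
  )
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' Run the parameter-recovery suite
#'
#' Executes scaled-down versions of the recovery experiments against their
#' own oracles (ground truth from the generators) and returns machine-
#' readable verdicts. Failures are verdicts, not errors.
#'
#' @param config See [default_config()]; `config$recovery$n_seeds` controls
#'   replication (default 10, enough for a smoke-level verdict).
#' @return `data.frame(check, value, criterion, pass)`.
#' @export
run_recovery_suite <- function(config = default_config()) {
  validate_config(config)
  n_seeds <- config$recovery$n_seeds %||% 10
  seed0 <- config$seed
  verdicts <- list()
  add <- function(check, value, criterion, pass) {
    verdicts[[length(verdicts) + 1L]] <<- data.frame(
      check = check, value = value, criterion = criterion, pass = pass,
      stringsAsFactors = FALSE)
  }

  # classification on a well-separated two-cluster population
  cfg <- trial_config(invalid_trial_prob = 0)
  trials <- generate_trials(40, cfg, seed0)
  ok <- TRUE
  for (i in 1:5) {
    for (kind in c("DA", "SNr")) {
      p <- neuron_params(kind)
      st <- generate_spike_train(trials, p, seed0 + i)
      bs <- baseline_stats(st, trials)
      w <- spike_width(generate_waveform(p, seed0 + i, noise_sd = 0.02))
      ok <- ok && classify_neuron(bs["mean"], w)$label == kind
    }
  }
  add("classification", as.numeric(ok), "all labels recovered", ok)

  # latency recovery on a small population
  hits <- 0L
  tot <- 0L
  for (s in seq_len(n_seeds)) {
    trials_s <- generate_trials(120, cfg, seed0 + s)
    pop <- sample_da_population(6, seed0 + s)
    for (i in seq_along(pop)) {
      st <- generate_spike_train(trials_s, pop[[i]], seed0 + 100 * s + i)
      bs <- baseline_stats(st, trials_s)
      lat <- response_latency(st, valid_trials(trials_s, condition = "LR"),
                              baseline = bs)
      tot <- tot + 1L
      if (!is.na(lat$latency_ms) &&
          abs(lat$latency_ms - pop[[i]]$response_latency) <= 10) {
        hits <- hits + 1L
      }
    }
  }
  frac <- hits / tot
  add("latency_recovery", frac, ">= 0.9 within one bin", frac >= 0.9)

  # discrimination onset with programmed divergence at 120 ms
  ok_runs <- 0L
  for (s in seq_len(n_seeds)) {
    trials_s <- generate_trials(120, cfg, seed0 + s)
    base <- neuron_params("DA", response_latency = 120)
    ids <- seq_len(8)
    mat <- function(cond) t(vapply(ids, function(i) {
      st <- generate_spike_train(trials_s, base, seed0 + 1000 * s + i)
      neuron_bin_rates(st, trials_s, cond)
    }, numeric(40)))
    lr <- mat("LR")
    sr <- mat("SR")
    res <- discrimination_onset(lr, sr, (0:39) * 0.01, 0.01)
    if (!is.na(res$onsets["onset_15"]) &&
        res$onsets["onset_15"] >= 120 && res$onsets["onset_15"] <= 145) {
      ok_runs <- ok_runs + 1L
    }
  }
  frac <- ok_runs / n_seeds
  add("onset_recovery", frac, ">= 0.9 onset in [120, 145] ms", frac >= 0.9)

  # behavioural inactivation contrast
  ok_runs <- 0L
  for (s in seq_len(n_seeds)) {
    bdiff <- ddiff <- numeric(13)
    for (k in 1:13) {
      tr <- generate_trials(80, cfg, seed0 + 17 * s + k)
      b_licks <- generate_licks(tr, rng_seed = seed0 + 31 * s + k)
      d_licks <- generate_licks(tr, mode =
                                  inactivation_mode("abolish_anticipation"),
                                rng_seed = seed0 + 53 * s + k)
      bdiff[k] <- cr_summary(b_licks, tr)$lr_minus_sr
      ddiff[k] <- cr_summary(d_licks, tr)$lr_minus_sr
    }
    eff <- inactivation_effect(bdiff, ddiff)
    if (eff$wilcoxon_before_vs_during$p_value < 0.05 &&
        eff$t_during_vs_zero$p_value > 0.05) {
      ok_runs <- ok_runs + 1L
    }
  }
  frac <- ok_runs / n_seeds
  add("inactivation_recovery", frac, ">= 0.9 qualitative pattern",
      frac >= 0.9)

  # psychometric threshold recovery
  ok_runs <- 0L
  for (s in seq_len(n_seeds)) {
    pp <- psycho_params(thresholds = 0.3,
                        grid = data.frame(ecc_deg = 10, dir_deg = 45))
    tr <- generate_psychometric_trials(pp, n_per_cell = 100,
                                       rng_seed = seed0 + s)
    agg <- stats::aggregate(tr$responded,
                            by = list(contrast = tr$contrast), FUN = sum)
    ntab <- table(tr$contrast)
    points <- data.frame(contrast = agg$contrast,
                         n = as.integer(ntab[as.character(agg$contrast)]),
                         n_correct = agg$x)
    fit <- fit_psychometric(points, guess_rate = pp$guess_rate,
                            criterion_p = pp$criterion_p)
    if (fit$converged &&
        abs(fit$threshold_michelson - 0.3) / 0.3 <= 0.1) {
      ok_runs <- ok_runs + 1L
    }
  }
  frac <- ok_runs / n_seeds
  add("psychometric_recovery", frac, ">= 0.9 within 10% relative error",
      frac >= 0.9)

  do.call(rbind, verdicts)
}
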