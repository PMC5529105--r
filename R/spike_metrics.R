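# Spike-train metrics: waveform width and cell-type classification, PSTHs,
# window firing rates and their statistics, baseline + k*SD response
# latency, and the sliding exact sign test for the onset of reward-value
# discrimination across a neuron population.

#' Trough-to-peak spike width
#'
#' Width is the time between the first negative local minimum of the
#' template and the next positive local maximum — the standard
#' extracellular criterion separating broad-spike dopamine neurons from
#' narrow-spike reticulata neurons.
#'
#' @param waveform A [waveform_template()].
#' @return Width in ms.
#' @details Only prominent extrema count: a candidate trough must reach half
#'   the global minimum and the following peak half the post-trough maximum,
#'   so measurement noise riding on the flat segments of an averaged
#'   template cannot masquerade as the trough or peak.
#' @export
spike_width <- function(waveform) {
  y <- waveform$samples
  n <- length(y)
  interior <- 2:(n - 1)
  is_min <- y[interior] <= y[interior - 1] & y[interior] <= y[interior + 1] &
    (y[interior] < y[interior - 1] | y[interior] < y[interior + 1])
  is_max <- y[interior] >= y[interior - 1] & y[interior] >= y[interior + 1] &
    (y[interior] > y[interior - 1] | y[interior] > y[interior + 1])
  mins <- interior[is_min & y[interior] < 0 &
                     y[interior] <= 0.5 * min(y)]
  if (length(mins) == 0) stop("unmeasurable waveform: no negative trough")
  trough <- mins[1]
  post_max <- max(y[trough:n])
  maxs <- interior[is_max & y[interior] > 0 &
                     y[interior] >= 0.5 * post_max]
  maxs <- maxs[maxs > trough]
  if (length(maxs) == 0) stop("unmeasurable waveform: no positive peak after trough")
  (maxs[1] - trough) * waveform$sample_interval_ms
}

#' Classify a unit from baseline rate and spike width
#'
#' Putative dopamine (DA): baseline within `da_rate_range` (1-10 Hz) and
#' width strictly greater than `width_cut` (0.45 ms). Reticulata (SNr):
#' baseline above `snr_rate_min` (40 Hz) and width at most `width_cut`.
#' Anything else is `unclassified` and is excluded from population
#' statistics.
#'
#' @param baseline_rate Baseline firing rate, Hz.
#' @param width Spike width, ms.
#' @param da_rate_range,width_cut,snr_rate_min Classification thresholds.
#' @param neuron_id Optional id carried into the result.
#' @return List with `neuron_id`, `label`, `baseline_rate`, `spike_width`.
#' @export
classify_neuron <- function(baseline_rate, width,
                            da_rate_range = c(1, 10), width_cut = 0.45,
                            snr_rate_min = 40, neuron_id = NA_character_) {
  stopifnot(is.finite(baseline_rate), is.finite(width),
            baseline_rate >= 0, width > 0)
  label <- if (baseline_rate >= da_rate_range[1] &&
               baseline_rate <= da_rate_range[2] && width > width_cut) {
    "DA"
  } else if (baseline_rate > snr_rate_min && width <= width_cut) {
    "SNr"
  } else {
    "unclassified"
  }
  list(neuron_id = neuron_id, label = label,
       baseline_rate = baseline_rate, spike_width = width)
}

count_in_windows <- function(spikes, starts, ends) {
  # spike count per [start, end) window; windows may overlap
  if (length(spikes) == 0) return(rep(0L, length(starts)))
  findInterval(ends, spikes, left.open = TRUE) -
    findInterval(starts, spikes, left.open = TRUE)
}

#' Baseline firing statistics
#'
#' Bins the pre-fixation-point baseline window of every valid trial into
#' `bin_width` bins, converts counts to rates and returns the mean and SD of
#' the per-trial-bin rates. The default window is the 0.5 s before FP onset,
#' the only epoch free of task events; these statistics anchor the
#' mean + k*SD latency criterion.
#'
#' @param spikes Spike-time vector, s.
#' @param trials Trial table.
#' @param baseline_window `(start, end)` in s relative to FP onset.
#' @param bin_width Bin width, s.
#' @param min_trials Minimum number of valid trials required.
#' @return `c(mean = Hz, sd = Hz)`; `(0, 0)` for an empty train.
#' @export
baseline_stats <- function(spikes, trials, baseline_window = c(-0.5, 0),
                           bin_width = 0.1, min_trials = 10) {
  tv <- valid_trials(trials)
  if (nrow(tv) < min_trials) {
    stop(sprintf("too few trials: %d valid, need >= %d", nrow(tv), min_trials))
  }
  if (length(spikes) == 0) return(c(mean = 0, sd = 0))
  edges <- seq(baseline_window[1], baseline_window[2], by = bin_width)
  rates <- unlist(lapply(tv$fp_onset, function(e) {
    count_in_windows(spikes, e + edges[-length(edges)], e + edges[-1]) /
      bin_width
  }))
  c(mean = mean(rates), sd = stats::sd(rates))
}

#' Peristimulus time histogram
#'
#' Event-aligned, trial-averaged firing rate:
#' `rate[b] = total spikes in bin b across trials / (n_trials * bin_width)`.
#' Invalid trials are excluded. Rates are computed per condition, so the
#' exact conservation identity
#' `sum(rates) * bin_width * n_trials == total spike count` holds for each.
#'
#' @param spikes Spike-time vector, s.
#' @param trials Trial table.
#' @param align `"FP"`, `"CS"` or `"RW"`.
#' @param condition Conditions to include (default both).
#' @param bin_width Bin width, s.
#' @param window `(start, end)` in s relative to the event.
#' @return Object of class `pavda_psth`: `align`, `bin_width`, `window`,
#'   `bin_starts`, `rates` (named list per condition, Hz), `n_trials`.
#' @export
psth <- function(spikes, trials, align = c("CS", "FP", "RW"),
                 condition = CONDITIONS, bin_width = 0.01,
                 window = c(-0.5, 1.0)) {
  align <- match.arg(align)
  stopifnot(window[1] < window[2], bin_width > 0)
  tv <- valid_trials(trials, condition = condition)
  if (nrow(tv) == 0) stop("empty selection: no valid trials")

  nb <- round((window[2] - window[1]) / bin_width)
  bin_starts <- window[1] + (seq_len(nb) - 1) * bin_width
  rates <- list()
  n_trials <- integer(0)
  for (cond in intersect(condition, unique(tv$condition))) {
    ev <- event_times(tv[tv$condition == cond, , drop = FALSE], align)
    ev <- ev[is.finite(ev)]
    counts <- rep(0, nb)
    for (e in ev) {
      counts <- counts + count_in_windows(spikes, e + bin_starts,
                                          e + bin_starts + bin_width)
    }
    rates[[cond]] <- counts / (length(ev) * bin_width)
    n_trials[cond] <- length(ev)
  }
  structure(list(align = align, bin_width = bin_width, window = window,
                 bin_starts = bin_starts, rates = rates,
                 n_trials = n_trials),
            class = "pavda_psth")
}

#' Per-trial window firing rates
#'
#' One value per valid trial: spike count in the half-open interval
#' `[event + start, event + end)` divided by the window length. The default
#' analysis windows are 100-300 ms after FP or CS onset and 150-350 ms after
#' reward delivery.
#'
#' @param spikes Spike-time vector, s.
#' @param trials Trial table.
#' @param align `"FP"`, `"CS"` or `"RW"`.
#' @param window `(start, end)` in s relative to the event.
#' @param condition Conditions to include.
#' @return Numeric vector of rates, Hz, one per valid trial.
#' @export
window_rate <- function(spikes, trials, align = c("CS", "FP", "RW"),
                        window = c(0.1, 0.3), condition = CONDITIONS) {
  align <- match.arg(align)
  stopifnot(window[1] < window[2])
  tv <- valid_trials(trials, condition = condition)
  ev <- event_times(tv, align)
  ev <- ev[is.finite(ev)]
  if (length(ev) == 0) stop("empty selection: no valid trials")
  count_in_windows(spikes, ev + window[1], ev + window[2]) /
    (window[2] - window[1])
}

#' Exact sign test
#'
#' Two-sided exact binomial sign test on paired differences. Zero
#' differences are dropped (the standard exact-test convention); if all
#' pairs tie, `p = 1` by convention. Two-sided p is
#' `2 * min(P(K <= k), P(K >= k))` capped at 1 under `K ~ Binom(n, 1/2)`.
#'
#' @param d Numeric vector of paired differences.
#' @param tail `"two_sided"`, `"greater"` (positive differences
#'   predominate) or `"less"`.
#' @return List with `statistic` (number of positive differences), `n`
#'   (non-zero pairs) and `p_value`.
#' @export
sign_test <- function(d, tail = c("two_sided", "greater", "less")) {
  tail <- match.arg(tail)
  d <- d[d != 0]
  n <- length(d)
  k <- sum(d > 0)
  if (n == 0) {
    return(list(statistic = NA_real_, n = 0L, p_value = 1))
  }
  p <- switch(tail,
    two_sided = min(1, 2 * min(stats::pbinom(k, n, 0.5),
                               1 - stats::pbinom(k - 1, n, 0.5))),
    greater = 1 - stats::pbinom(k - 1, n, 0.5),
    less = stats::pbinom(k, n, 0.5)
  )
  list(statistic = k, n = n, p_value = p)
}

#' Compare two sets of window rates
#'
#' Wraps the test battery used throughout the analyses: paired Wilcoxon
#' signed-rank, Welch two-sample t, one-sample (or paired) t, and the exact
#' sign test. Paired tests with all-zero differences return `p = 1`
#' (`p = 0.5` for a one-tailed t at the boundary) with a `no_variance` flag
#' rather than erroring.
#'
#' @param values_a First sample (or the only sample for `one_sample_t`).
#' @param values_b Second sample; `NULL` for a one-sample t against 0.
#' @param test One of `"wilcoxon_signed_rank"`, `"welch_t"`,
#'   `"one_sample_t"`, `"sign_test"`.
#' @param tail `"two_sided"`, `"greater"` (a > b) or `"less"`.
#' @param min_n Minimum pairs/samples.
#' @return List with `statistic`, `p_value`, `n`, and for degenerate paired
#'   input `no_variance = TRUE`.
#' @export
compare_window_rates <- function(values_a, values_b = NULL,
                                 test = c("wilcoxon_signed_rank", "welch_t",
                                          "one_sample_t", "sign_test"),
                                 tail = c("two_sided", "greater", "less"),
                                 min_n = 5) {
  test <- match.arg(test)
  tail <- match.arg(tail)
  alt <- switch(tail, two_sided = "two.sided", greater = "greater",
                less = "less")
  paired <- test %in% c("wilcoxon_signed_rank", "sign_test") ||
    (test == "one_sample_t" && !is.null(values_b))
  if (paired && !is.null(values_b) &&
      length(values_a) != length(values_b)) {
    stop("paired test requires equal lengths")
  }

  if (test == "welch_t") {
    if (length(values_a) < min_n || length(values_b) < min_n) {
      stop(sprintf("insufficient n: need >= %d per group", min_n))
    }
    ht <- stats::t.test(values_a, values_b, var.equal = FALSE,
                        alternative = alt)
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                n = c(length(values_a), length(values_b))))
  }

  d <- if (is.null(values_b)) values_a else values_a - values_b
  if (length(d) < min_n) {
    stop(sprintf("insufficient n: %d pairs, need >= %d", length(d), min_n))
  }

  if (test == "sign_test") {
    st <- sign_test(d, tail)
    return(list(statistic = st$statistic, p_value = st$p_value, n = st$n))
  }

  if (test == "one_sample_t") {
    if (stats::sd(d) == 0) {
      # degenerate: no variance; boundary conventions documented
      p <- if (mean(d) == 0) (if (tail == "two_sided") 1 else 0.5)
           else if ((tail == "greater" && mean(d) > 0) ||
                    (tail == "less" && mean(d) < 0) || tail == "two_sided") 0
           else 1
      return(list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                  p_value = p, n = length(d), no_variance = TRUE))
    }
    ht <- stats::t.test(d, mu = 0, alternative = alt)
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                n = length(d)))
  }

  # Wilcoxon signed-rank: drop zero differences; all-tied pairs -> p = 1
  nz <- d[d != 0]
  if (length(nz) == 0) {
    return(list(statistic = 0, p_value = 1, n = 0L, no_variance = TRUE))
  }
  ht <- suppressWarnings(stats::wilcox.test(nz, alternative = alt,
                                            exact = FALSE, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n = length(nz))
}

#' Response latency against a baseline mean + k*SD criterion
#'
#' Latency is the start time of the first PSTH bin in the search window
#' whose across-trial mean rate exceeds `baseline mean + k * SD`; undefined
#' (`NA`) if no bin does. The default search window 0-400 ms comfortably
#' covers the observed 60-160 ms latency range while staying clear of
#' reward delivery.
#'
#' @param spikes Spike-time vector, s.
#' @param trials Trial table (pre-filter by condition for a
#'   condition-specific latency).
#' @param align Event to align to (default `"CS"`).
#' @param baseline `(mean, sd)` in Hz, typically from [baseline_stats()].
#' @param bin_width PSTH bin width, s.
#' @param criterion_k SD multiplier (default 2).
#' @param search_window `(start, end)` s relative to the event.
#' @param condition Conditions to include.
#' @return List: `latency_ms` (or `NA`), `baseline_mean`, `baseline_sd`,
#'   `criterion_k`, `bin_width`, `threshold_hz`.
#' @export
response_latency <- function(spikes, trials, align = "CS",
                             baseline, bin_width = 0.01, criterion_k = 2,
                             search_window = c(0, 0.4),
                             condition = CONDITIONS) {
  stopifnot(baseline[2] >= 0)
  h <- psth(spikes, trials, align = align, condition = condition,
            bin_width = bin_width, window = search_window)
  # pool conditions with trial-count weights so the estimate uses all trials
  n <- h$n_trials
  pooled <- Reduce(`+`, Map(function(r, w) r * w, h$rates, as.list(n))) /
    sum(n)
  threshold <- baseline[1] + criterion_k * baseline[2]
  hit <- which(pooled > threshold)
  latency_ms <- if (length(hit) == 0) NA_real_ else
    h$bin_starts[hit[1]] * 1000
  list(latency_ms = latency_ms, baseline_mean = unname(baseline[1]),
       baseline_sd = unname(baseline[2]), criterion_k = criterion_k,
       bin_width = bin_width, threshold_hz = unname(threshold))
}

#' Per-neuron binned mean rates for the population discrimination test
#'
#' Across-trial mean firing rate per bin for one condition — one row of the
#' neurons x bins matrices consumed by [discrimination_onset()].
#'
#' @param spikes Spike-time vector, s.
#' @param trials Trial table.
#' @param condition `"LR"` or `"SR"`.
#' @param align Event (default `"CS"`).
#' @param bin_width Bin width, s.
#' @param window `(start, end)` s relative to the event.
#' @return Numeric vector of mean rates (Hz), one per bin.
#' @export
neuron_bin_rates <- function(spikes, trials, condition, align = "CS",
                             bin_width = 0.01, window = c(0, 0.4)) {
  h <- psth(spikes, trials, align = align, condition = condition,
            bin_width = bin_width, window = window)
  h$rates[[condition]]
}

#' Onset of reward-value discrimination across a neuron population
#'
#' Runs a two-sided exact sign test across neurons on the per-bin difference
#' of LR and SR mean rates, then finds, for each persistence requirement
#' `P`, the left edge of the earliest run of consecutive significant bins
#' whose total span strictly exceeds `P` ms. A minimum of 6 neurons is
#' required — the smallest n for which the two-sided sign test can reach
#' p < 0.05.
#'
#' @param rates_lr,rates_sr Matrices, neurons x bins, of per-neuron mean
#'   rates in the two conditions (see [neuron_bin_rates()]).
#' @param bin_starts Bin start times, s relative to the align event.
#' @param bin_width Bin width, s.
#' @param alpha Significance level per bin.
#' @param persistence_ms Persistence requirements, ms (default 15 and 50).
#' @return List: `p_values` per bin, `alpha`, `n_neurons`, `bin_starts`,
#'   and `onsets` — named numeric (ms, `NA` when undefined), one entry per
#'   persistence value (`onset_15`, `onset_50`, ...).
#' @export
discrimination_onset <- function(rates_lr, rates_sr, bin_starts,
                                 bin_width, alpha = 0.05,
                                 persistence_ms = c(15, 50)) {
  rates_lr <- as.matrix(rates_lr)
  rates_sr <- as.matrix(rates_sr)
  stopifnot(all(dim(rates_lr) == dim(rates_sr)),
            ncol(rates_lr) == length(bin_starts))
  n_neurons <- nrow(rates_lr)
  if (n_neurons < 6) {
    stop(sprintf(
      "underpowered: %d neurons; a two-sided sign test needs >= 6", n_neurons))
  }
  diffs <- rates_lr - rates_sr
  p_values <- apply(diffs, 2, function(d) sign_test(d)$p_value)

  sig <- p_values < alpha
  runs <- rle(sig)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L

  onsets <- stats::setNames(
    rep(NA_real_, length(persistence_ms)),
    sprintf("onset_%g", persistence_ms)
  )
  for (j in seq_along(persistence_ms)) {
    need <- persistence_ms[j] / 1000
    ok <- which(runs$values & runs$lengths * bin_width > need)
    if (length(ok) > 0) {
      onsets[j] <- bin_starts[run_start[ok[1]]] * 1000
    }
  }
  list(p_values = p_values, alpha = alpha, n_neurons = n_neurons,
       bin_starts = bin_starts, bin_width = bin_width, onsets = onsets)
}

#' Waveform stability across recording epochs
#'
#' Pairwise Pearson correlation of peak-normalized templates; the recording
#' counts as stable when the smallest pairwise correlation reaches the
#' threshold. Templates of unequal length are linearly resampled to the
#' shortest duration unless `resample = FALSE`.
#'
#' @param waveforms List of at least two [waveform_template()]s.
#' @param threshold Minimum pairwise correlation for stability.
#' @param resample Allow resampling of unequal-length templates.
#' @return List: `similarity` (correlation matrix), `stable` (logical).
#' @export
waveform_stability <- function(waveforms, threshold = 0.95,
                               resample = TRUE) {
  stopifnot(length(waveforms) >= 2)
  lens <- vapply(waveforms, function(w) length(w$samples), integer(1))
  durs <- vapply(waveforms,
                 function(w) (length(w$samples) - 1) * w$sample_interval_ms,
                 numeric(1))
  if (length(unique(lens)) > 1 || length(unique(durs)) > 1) {
    if (!resample) stop("length mismatch with resampling disabled")
    n_target <- min(lens)
    d_target <- min(durs)
    waveforms <- lapply(waveforms, function(w) {
      t_old <- (seq_along(w$samples) - 1) * w$sample_interval_ms
      t_new <- seq(0, d_target, length.out = n_target)
      waveform_template(stats::approx(t_old, w$samples, t_new)$y,
                        d_target / (n_target - 1), w$epoch_label)
    })
  }
  mats <- vapply(waveforms,
                 function(w) w$samples / max(abs(w$samples)),
                 numeric(length(waveforms[[1]]$samples)))
  similarity <- stats::cor(mats)
  off <- similarity[lower.tri(similarity)]
  list(similarity = similarity, stable = min(off) >= threshold)
}
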