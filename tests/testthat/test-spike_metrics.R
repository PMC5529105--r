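# Waveform width, classification, PSTH/window statistics, latency and
# discrimination onset, waveform stability.

test_that("spike_width measures trough-to-peak sample distance", {
  y <- rep(0, 50)
  y[10] <- -1   # first negative local minimum at sample 10
  y[34] <- 0.7  # next positive local maximum at sample 34
  wf <- waveform_template(y, 0.025)
  expect_equal(spike_width(wf), (34 - 10) * 0.025)  # 0.600 ms

  expect_error(spike_width(waveform_template(seq_len(20), 0.025)),
               "unmeasurable")
  # generator contract: programmed width recovered to within half a sample
  for (w in c(0.6, 0.25)) {
    wf <- generate_waveform(neuron_params("DA", waveform_width = w),
                            noise_sd = 0)
    expect_lte(abs(spike_width(wf) - w), 0.0125 + 1e-12)
  }
})

test_that("classify_neuron applies the rate/width criteria", {
  expect_identical(classify_neuron(5, 0.6)$label, "DA")
  expect_identical(classify_neuron(60, 0.25)$label, "SNr")
  expect_identical(classify_neuron(25, 0.6)$label, "unclassified")
  expect_identical(classify_neuron(5, 0.45)$label, "unclassified")  # not >
  expect_identical(classify_neuron(40, 0.25)$label, "unclassified") # not >
  expect_identical(classify_neuron(0.5, 0.6)$label, "unclassified") # < 1 Hz
})

test_that("baseline_stats handles deterministic and empty trains", {
  tr <- generate_trials(20, trial_config(invalid_trial_prob = 0),
                        rng_seed = 1)
  # one spike in every 0.1 s bin everywhere -> exactly (10 Hz, 0 Hz)
  st <- regular_train(0.1, max(tr$reward_time) + 1, offset = 0.05)
  bs <- baseline_stats(st, tr)
  expect_equal(unname(bs), c(10, 0))

  expect_equal(unname(baseline_stats(numeric(0), tr)), c(0, 0))
  expect_error(baseline_stats(st, tr[1:5, ]), "too few trials")

  # homogeneous Poisson: mean near the true rate
  tr2 <- generate_trials(200, trial_config(invalid_trial_prob = 0),
                         rng_seed = 2)
  p <- neuron_params("DA", fp_delta = 0, cs_delta_lr = 0, cs_delta_sr = 0,
                     rw_delta_predicted = 0, rw_delta_unpredicted = 0)
  st2 <- generate_spike_train(tr2, p, rng_seed = 2)
  bs2 <- baseline_stats(st2, tr2)
  expect_lt(abs(bs2["mean"] - 5), 3 * sqrt(5 / 0.1 / 1000))
  # SD of per-trial-bin Poisson rates ~ sqrt(lambda / bin)
  expect_lt(abs(bs2["sd"] - sqrt(5 / 0.1)), 1.5)
})

test_that("psth matches hand counts and conserves spike mass", {
  tr <- data.frame(trial_id = 1L, condition = "LR", field = "affected",
                   epoch = "none", fp_onset = 1, cs_onset = 2, cs_offset = 3,
                   reward_time = 3.3, reward_volume = 0.17,
                   ecc_deg = 10, dir_deg = 45, valid = TRUE)
  st <- c(2.005, 2.015)  # event + 5 ms and + 15 ms
  h <- psth(st, tr, align = "CS", bin_width = 0.01, window = c(0, 0.05))
  expect_equal(h$rates$LR, c(100, 100, 0, 0, 0))

  # conservation: sum(rates) * bin_width * n_trials == spike count in window
  s <- make_tiny_session(rng_seed = 21, n_trials = 40)
  for (cond in c("LR", "SR")) {
    h <- psth(s$spikes$da_01, s$trials, align = "CS", condition = cond,
              bin_width = 0.01, window = c(-0.2, 0.8))
    tv <- valid_trials(s$trials, condition = cond)
    total <- sum(vapply(tv$cs_onset, function(e)
      sum(s$spikes$da_01 >= e - 0.2 & s$spikes$da_01 < e + 0.8),
      numeric(1)))
    expect_equal(sum(h$rates[[cond]]) * h$bin_width * h$n_trials[[cond]],
                 total)
  }
  expect_error(psth(st, tr[0, ], align = "CS"), "empty selection")
})

test_that("window_rate counts half-open windows per valid trial", {
  tr <- data.frame(trial_id = 1L, condition = "LR", field = "affected",
                   epoch = "none", fp_onset = 1, cs_onset = 2, cs_offset = 3,
                   reward_time = 3.3, reward_volume = 0.17,
                   ecc_deg = 10, dir_deg = 45, valid = TRUE)
  st <- c(2.10, 2.15, 2.20, 2.25)
  expect_equal(window_rate(st, tr, align = "CS", window = c(0.1, 0.3)), 20)
  expect_equal(window_rate(numeric(0), tr, align = "CS",
                           window = c(0.1, 0.3)), 0)
  # boundary: spike exactly at window end is excluded, at start included
  expect_equal(window_rate(c(2.1, 2.3), tr, align = "CS",
                           window = c(0.1, 0.3)), 5)
})

test_that("sign test matches the exact binomial and handles ties", {
  expect_equal(sign_test(rep(1, 8))$p_value, 2 * 0.5^8)  # 0.0078125
  expect_equal(sign_test(numeric(0))$p_value, 1)
  expect_equal(sign_test(rep(0, 10))$p_value, 1)  # all ties dropped
  r <- compare_window_rates(1:8, 1:8, test = "sign_test")
  expect_equal(r$p_value, 1)

  # small-n property: equals exhaustive enumeration
  for (n in c(5, 7, 10)) {
    for (k in 0:n) {
      d <- c(rep(1, k), rep(-1, n - k))
      expect_equal(sign_test(d)$p_value, enum_sign_p(n, k))
    }
  }
})

test_that("welch t agrees with a permutation oracle on small fixtures", {
  # fixed n = 10 fixtures spanning a significant and a null-ish case
  set.seed(1)
  a <- round(rnorm(10, 5, 1), 2)
  b <- round(rnorm(10, 5.8, 1), 2)
  p_t <- compare_window_rates(a, b, test = "welch_t")$p_value
  expect_lt(abs(p_t - perm_p_two_sample(a, b)), 0.02)

  set.seed(5)
  a2 <- round(rnorm(10, 5, 1), 2)
  b2 <- round(rnorm(10, 5.8, 1), 2)
  expect_lt(abs(compare_window_rates(a2, b2, test = "welch_t")$p_value -
                  perm_p_two_sample(a2, b2)), 0.02)
})

test_that("degenerate paired inputs follow the documented conventions", {
  x <- c(1, 2, 3, 4, 5)
  r <- compare_window_rates(x, x, test = "wilcoxon_signed_rank")
  expect_equal(r$p_value, 1)
  expect_true(r$no_variance)
  r2 <- compare_window_rates(x, x, test = "one_sample_t", tail = "greater")
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 0.5)
  expect_error(compare_window_rates(1:3, 1:3, test = "sign_test"),
               "insufficient n")
  expect_error(compare_window_rates(1:4, 1:5, test = "sign_test"),
               "equal lengths")
})

test_that("response_latency finds the first supra-threshold bin", {
  # constructed step train: 5 Hz -> 30 Hz exactly 100 ms after each CS
  # (spikes placed mid-bin so binning is unambiguous)
  tr <- generate_trials(60, trial_config(invalid_trial_prob = 0),
                        rng_seed = 3)
  st <- sort(unlist(lapply(tr$cs_onset, function(e)
    seq(e + 0.105, e + 0.295, by = 0.01))))
  lat <- response_latency(st, tr, baseline = c(mean = 5, sd = 1))
  expect_equal(lat$latency_ms, 100)

  # flat train at baseline (SD from the per-trial-bin Poisson rule):
  # latency undefined
  st2 <- regular_train(0.2, max(tr$reward_time) + 1)
  lat2 <- response_latency(st2, tr, baseline = c(mean = 5, sd = sqrt(50)))
  expect_true(is.na(lat2$latency_ms))

  # monotone in criterion_k: larger k never earlier
  s <- make_tiny_session(rng_seed = 31, n_trials = 60)
  bs <- baseline_stats(s$spikes$da_01, s$trials)
  lats <- vapply(c(1, 2, 3, 5), function(k)
    response_latency(s$spikes$da_01,
                     valid_trials(s$trials, condition = "LR"),
                     baseline = bs, criterion_k = k)$latency_ms,
    numeric(1))
  defined <- !is.na(lats)
  expect_true(all(diff(lats[defined]) >= 0))
})

test_that("discrimination_onset applies persistence rules literally", {
  # 16 neurons, LR - SR > 0 in every bin from 120 ms, 1 ms bins
  nb <- 200
  bin_starts <- (seq_len(nb) - 1) / 1000
  sr <- matrix(10, nrow = 16, ncol = nb)
  lr <- sr
  lr[, bin_starts >= 0.120] <- 12
  res <- discrimination_onset(lr, sr, bin_starts, 0.001)
  expect_equal(unname(res$onsets["onset_15"]), 120)
  expect_equal(unname(res$onsets["onset_50"]), 120)
  expect_equal(res$p_values[bin_starts >= 0.120][1], 2 * 0.5^16)

  # identical inputs: no onset
  res2 <- discrimination_onset(sr, sr, bin_starts, 0.001)
  expect_true(all(is.na(res2$onsets)))

  # 10-bin significant runs with gaps never satisfy > 15 ms at 1 ms bins
  lr3 <- sr
  on <- rep(c(rep(TRUE, 10), rep(FALSE, 10)), length.out = nb)
  lr3[, on] <- 12
  res3 <- discrimination_onset(lr3, sr, bin_starts, 0.001)
  expect_true(is.na(res3$onsets["onset_15"]))

  expect_error(discrimination_onset(sr[1:5, ], lr[1:5, ], bin_starts, 0.001),
               "underpowered")
})

test_that("onset_50 never precedes onset_15 when both defined", {
  set.seed(44)
  for (rep in 1:20) {
    nb <- 60
    bin_starts <- (seq_len(nb) - 1) * 0.01
    sr <- matrix(rnorm(8 * nb, 10, 1), nrow = 8)
    lr <- sr + matrix(rnorm(8 * nb, 0.4, 1), nrow = 8)
    res <- discrimination_onset(lr, sr, bin_starts, 0.01)
    o15 <- res$onsets["onset_15"]
    o50 <- res$onsets["onset_50"]
    if (!is.na(o15) && !is.na(o50)) expect_gte(o50, o15)
    if (is.na(o15)) expect_true(is.na(o50))
  }
})

test_that("waveform_stability compares peak-normalized templates", {
  w <- generate_waveform(neuron_params("DA"), noise_sd = 0)
  res <- waveform_stability(list(w, w))
  expect_equal(res$similarity[1, 2], 1)
  expect_true(res$stable)

  neg <- waveform_template(-w$samples, w$sample_interval_ms)
  res2 <- waveform_stability(list(w, neg))
  expect_equal(res2$similarity[1, 2], -1)
  expect_false(res2$stable)

  # resampling path: same shape at half the sample rate still matches
  coarse <- waveform_template(w$samples[seq(1, 64, by = 2)],
                              w$sample_interval_ms * 2)
  res3 <- waveform_stability(list(w, coarse))
  expect_true(res3$stable)
  expect_error(waveform_stability(list(w, coarse), resample = FALSE),
               "length mismatch")

  # noisy templates at 5% of peak stay stable in nearly every draw
  ok <- vapply(1:40, function(s) {
    a <- generate_waveform(neuron_params("DA"), rng_seed = s, noise_sd = 0.05)
    b <- generate_waveform(neuron_params("DA"), rng_seed = s + 1000,
                           noise_sd = 0.05)
    waveform_stability(list(a, b))$stable
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
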