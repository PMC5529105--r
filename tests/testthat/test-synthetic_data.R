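# Generators: trial tables, spike trains, licks, waveforms, psychophysics,
# reversal datasets. Closed-form expectations come from the rectangular-bump
# Poisson model the generators implement.

test_that("generate_trials balances conditions and is deterministic", {
  tr <- generate_trials(200, rng_seed = 1)
  expect_identical(nrow(tr), 200L)
  expect_lte(abs(sum(tr$condition == "LR") - sum(tr$condition == "SR")), 1)
  # block-of-2 balance: every consecutive pair holds one of each
  blocks <- matrix(tr$condition, nrow = 2)
  expect_true(all(apply(blocks, 2, function(b) setequal(b, c("LR", "SR")))))

  tr2 <- generate_trials(2, rng_seed = 3)
  expect_setequal(tr2$condition, c("LR", "SR"))

  expect_identical(generate_trials(50, rng_seed = 9),
                   generate_trials(50, rng_seed = 9))
  expect_error(generate_trials(0), "n_trials")
})

test_that("trial tables respect the task schedule", {
  tr <- generate_trials(100, rng_seed = 2)
  expect_true(all(tr$fp_onset < tr$cs_onset))
  fix <- tr$cs_onset - tr$fp_onset
  expect_true(all(fix >= 0.7 & fix <= 1.2))
  expect_equal(tr$cs_offset - tr$cs_onset, rep(1.0, 100))
  lr <- tr$condition == "LR"
  expect_equal(tr$reward_time[lr], tr$cs_onset[lr] + 1.3)
  expect_equal(tr$reward_time[!lr], tr$cs_offset[!lr] + 1.5)
  expect_equal(unique(tr$reward_volume[lr]), 0.17)
  expect_equal(unique(tr$reward_volume[!lr]), 0.06)
  expect_length(validate_session(session(tr)), 0)
})

test_that("homogeneous limit: all-zero deltas give a plain Poisson train", {
  tr <- data.frame(trial_id = 1L, condition = "LR", field = "affected",
                   epoch = "none", fp_onset = 1, cs_onset = 2, cs_offset = 3,
                   reward_time = 3.3, reward_volume = 0.17,
                   ecc_deg = 10, dir_deg = 45, valid = TRUE)
  p <- neuron_params("DA", fp_delta = 0, cs_delta_lr = 0, cs_delta_sr = 0,
                     rw_delta_predicted = 0, rw_delta_unpredicted = 0)
  st <- generate_spike_train(tr, p, rng_seed = 4, t_end = 1000)
  expect_lt(abs(length(st) - 5000), 5 * sqrt(5000))
  expect_true(all(diff(st) > 0))
})

test_that("event-window rates match the programmed bump heights", {
  cfg <- trial_config(invalid_trial_prob = 0)
  tr <- generate_trials(300, cfg, rng_seed = 5)
  p <- neuron_params("DA", cs_delta_lr = 25, response_latency = 100,
                     response_duration = 200)
  st <- generate_spike_train(tr, p, rng_seed = 5)
  r <- window_rate(st, tr, align = "CS", window = c(0.1, 0.3),
                   condition = "LR")
  # mean count per trial is (5 + 25) * 0.2 = 6; SE of the mean rate:
  se <- sqrt(30 / 0.2 / length(r))
  expect_lt(abs(mean(r) - 30), 3 * se)

  base <- window_rate(st, tr, align = "FP", window = c(-0.5, 0))
  se_b <- sqrt(5 / 0.5 / length(base))
  expect_lt(abs(mean(base) - 5), 3 * se_b)
})

test_that("spike trains are reproducible and strictly increasing", {
  tr <- generate_trials(30, rng_seed = 6)
  p <- neuron_params("SNr")
  expect_identical(generate_spike_train(tr, p, 11),
                   generate_spike_train(tr, p, 11))
  st <- generate_spike_train(tr, p, 11)
  expect_true(all(diff(st) > 0))
  expect_error(generate_spike_train(tr[0, ], p, 1), "empty trial table")
})

test_that("lick generator produces LR > SR anticipation by default", {
  tr <- generate_trials(200, rng_seed = 7)
  licks <- generate_licks(tr, rng_seed = 7)
  lr <- cr_rate(licks, tr, "LR", window = c(0, 1.3))
  sr <- cr_rate(licks, tr, "SR", window = c(0, 1.3))
  expect_gt(lr, sr)
})

test_that("abolish_anticipation flattens the LR-SR contrast", {
  cfg <- trial_config(invalid_trial_prob = 0)
  diffs <- vapply(1:10, function(s) {
    tr <- generate_trials(200, cfg, rng_seed = s)
    licks <- generate_licks(tr, mode = inactivation_mode("abolish_anticipation"),
                            rng_seed = s)
    cr_summary(licks, tr)$lr_minus_sr
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.15)
})

test_that("zero baseline and anticipation leaves only post-reward licks", {
  tr <- generate_trials(50, trial_config(invalid_trial_prob = 0),
                        rng_seed = 8)
  bp <- behavior_params(lick_baseline = 0, lick_anticipatory_lr = 0,
                        lick_anticipatory_sr = 0, lick_post_reward = 6)
  licks <- generate_licks(tr, bp, rng_seed = 8)
  expect_gt(length(licks), 0)
  in_burst <- vapply(licks, function(t)
    any(t >= tr$reward_time & t < tr$reward_time + 1), logical(1))
  expect_true(all(in_burst))
})

test_that("inactivation mode invariants are enforced", {
  expect_error(inactivation_mode("none", cs_response_scale = 0),
               "mode 'none'")
  m <- inactivation_mode("abolish_anticipation")
  expect_identical(m$cs_response_scale, 0)
  expect_true(m$rw_unmasking)
})

test_that("waveform templates hit the programmed trough-to-peak width", {
  for (w in c(0.6, 0.25, 0.45)) {
    wf <- generate_waveform(neuron_params("DA", waveform_width = w),
                            rng_seed = 1, noise_sd = 0)
    expect_lte(abs(spike_width(wf) - w), 0.0125 + 1e-12)
  }
  w1 <- generate_waveform(neuron_params("DA"), rng_seed = 1, noise_sd = 0)
  w2 <- generate_waveform(neuron_params("DA"), rng_seed = 99, noise_sd = 0)
  expect_identical(w1$samples, w2$samples)  # noiseless: seed-independent
  expect_error(generate_waveform(neuron_params("DA", waveform_width = 0.03)),
               "not representable")
})

test_that("psychometric trial fractions follow the programmed curve", {
  grid <- data.frame(ecc_deg = 10, dir_deg = 45)
  pp <- psycho_params(thresholds = 0.3, slope = 3, guess_rate = 0.05,
                      grid = grid)
  # at threshold contrast the correct fraction approaches the d'=2 criterion
  tr <- generate_psychometric_trials(pp, n_per_cell = 4000,
                                     contrasts = 0.3, rng_seed = 9)
  expect_lt(abs(mean(tr$responded) - pnorm(1)), 0.02)
  # asymptote and floor
  hi <- generate_psychometric_trials(psycho_params(thresholds = 0.3,
                                                   slope = 20, grid = grid),
                                     n_per_cell = 500, contrasts = 0.89,
                                     rng_seed = 9)
  expect_gt(mean(hi$responded), 0.98)
  lo <- generate_psychometric_trials(psycho_params(thresholds = 0.3,
                                                   slope = 20, grid = grid),
                                     n_per_cell = 2000, contrasts = 0.02,
                                     rng_seed = 9)
  expect_lt(abs(mean(lo$responded) - 0.05), 0.02)
})

test_that("reversal dataset relaxes exponentially and crosses as computed", {
  # learning_rate 1: fully reversed on the first day after the switch
  rev1 <- generate_reversal_dataset(7, switch_days = 4, learning_rate = 1,
                                    rng_seed = 1, n_trials = 60)
  rc1 <- reversal_curve(rev1)
  expect_identical(rc1$crossover_day, 5L)

  # learning_rate 0: ordering never inverts
  rev0 <- generate_reversal_dataset(8, switch_days = 4, learning_rate = 0,
                                    rng_seed = 1, n_trials = 60)
  expect_true(is.na(reversal_curve(rev0)$crossover_day))

  # learning_rate 0.5, switch day 10: the relaxation u_d = 2 + 2*(1/2)^(d-9)
  # and l_d = 4 - 2*(1/2)^(d-9) are equal at d = 10 and strictly inverted
  # from d = 11, so the crossover lands in [11, 13]
  rev5 <- generate_reversal_dataset(16, switch_days = 10,
                                    learning_rate = 0.5, rng_seed = 2,
                                    n_trials = 150)
  rc5 <- reversal_curve(rev5)
  expect_true(rc5$crossover_day >= 11 && rc5$crossover_day <= 13)
})

test_that("generate_session carries complete ground truth", {
  s <- generate_session(n_trials = 12, n_da = 2, n_snr = 1, rng_seed = 3)
  truth <- s$metadata$truth
  expect_named(truth$neurons, c("da_01", "da_02", "snr_01"))
  expect_true(all(vapply(truth$neurons[1:2],
                         function(n) n$response_latency >= 60 &&
                           n$response_latency <= 160, logical(1))))
  expect_identical(truth$rng_seed, 3)
})
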