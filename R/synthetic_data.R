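# Synthetic session generator. Emulates the statistical structure of a
# conditioning/recording day — interleaved large-reward (LR) and small-reward
# (SR) trials, low-rate broad-spike dopamine-like and high-rate narrow-spike
# SNr-like units with event-locked rectangular rate bumps, anticipatory lick
# point processes, and contrast-graded saccade-detection trials — with known
# ground truth for parameter-recovery tests.

#' Neuron simulation parameters
#'
#' Rate model: an inhomogeneous Poisson process whose intensity is the
#' baseline plus rectangular event-locked bumps. Each bump starts
#' `response_latency` ms after its event and lasts `response_duration` ms;
#' its height is the per-event delta. Reward bumps use
#' `rw_delta_predicted` when the preceding cue announced the reward and
#' `rw_delta_unpredicted` when it did not (e.g. under collicular
#' inactivation with reward unmasking).
#'
#' Defaults for `kind = "DA"` follow the recording criteria for putative
#' dopamine neurons (low baseline, broad spike); `kind = "SNr"` emulates the
#' fast-firing narrow-spike reticulata units used as the contrast class.
#' Bump amplitudes are generator conventions, documented in the methods
#' vignette.
#'
#' @param kind `"DA"` or `"SNr"`.
#' @param baseline_rate Baseline rate, Hz (> 0).
#' @param fp_delta,cs_delta_lr,cs_delta_sr,rw_delta_predicted,rw_delta_unpredicted
#'   Bump heights, Hz (each >= `-baseline_rate`).
#' @param response_latency Bump onset after the event, ms.
#' @param response_duration Bump length, ms.
#' @param waveform_width Trough-to-peak width of the spike template, ms.
#' @return A named list of class `pavda_neuron_params`.
#' @export
neuron_params <- function(kind = c("DA", "SNr"),
                          baseline_rate = NULL,
                          fp_delta = NULL,
                          cs_delta_lr = NULL,
                          cs_delta_sr = NULL,
                          rw_delta_predicted = NULL,
                          rw_delta_unpredicted = NULL,
                          response_latency = 100,
                          response_duration = 200,
                          waveform_width = NULL) {
  kind <- match.arg(kind)
  def <- if (kind == "DA") {
    list(baseline_rate = 5, fp_delta = 15, cs_delta_lr = 25,
         cs_delta_sr = 10, rw_delta_predicted = 5,
         rw_delta_unpredicted = 25, waveform_width = 0.6)
  } else {
    list(baseline_rate = 60, fp_delta = 0, cs_delta_lr = -20,
         cs_delta_sr = -20, rw_delta_predicted = 0,
         rw_delta_unpredicted = 0, waveform_width = 0.25)
  }
  p <- list(
    kind = kind,
    baseline_rate = baseline_rate %||% def$baseline_rate,
    fp_delta = fp_delta %||% def$fp_delta,
    cs_delta_lr = cs_delta_lr %||% def$cs_delta_lr,
    cs_delta_sr = cs_delta_sr %||% def$cs_delta_sr,
    rw_delta_predicted = rw_delta_predicted %||% def$rw_delta_predicted,
    rw_delta_unpredicted = rw_delta_unpredicted %||% def$rw_delta_unpredicted,
    response_latency = response_latency,
    response_duration = response_duration,
    waveform_width = waveform_width %||% def$waveform_width
  )
  stopifnot(p$baseline_rate > 0, p$response_duration > 0,
            p$response_latency >= 0)
  deltas <- c(p$fp_delta, p$cs_delta_lr, p$cs_delta_sr,
              p$rw_delta_predicted, p$rw_delta_unpredicted)
  if (any(deltas < -p$baseline_rate)) {
    stop("rate deltas must be >= -baseline_rate")
  }
  structure(p, class = "pavda_neuron_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Licking simulation parameters
#'
#' Poisson lick process: `lick_baseline` everywhere, a condition-specific
#' anticipatory rate from `anticipation_onset` s after cue onset until reward
#' delivery, and `lick_post_reward` for 1 s after reward. An 80 ms refractory
#' period is enforced by thinning.
#'
#' @param lick_baseline,lick_anticipatory_lr,lick_anticipatory_sr,lick_post_reward
#'   Rates in events/s (>= 0).
#' @param anticipation_onset Seconds after cue onset at which anticipatory
#'   licking begins.
#' @param invalid_trial_prob Probability a generated trial is marked invalid
#'   (fixation break), in `[0, 1)`.
#' @return Named list of class `pavda_behavior_params`.
#' @export
behavior_params <- function(lick_baseline = 0.5,
                            lick_anticipatory_lr = 4,
                            lick_anticipatory_sr = 2,
                            lick_post_reward = 6,
                            anticipation_onset = 0.3,
                            invalid_trial_prob = 0.05) {
  p <- list(lick_baseline = lick_baseline,
            lick_anticipatory_lr = lick_anticipatory_lr,
            lick_anticipatory_sr = lick_anticipatory_sr,
            lick_post_reward = lick_post_reward,
            anticipation_onset = anticipation_onset,
            invalid_trial_prob = invalid_trial_prob)
  stopifnot(all(unlist(p[1:4]) >= 0),
            invalid_trial_prob >= 0, invalid_trial_prob < 1)
  structure(p, class = "pavda_behavior_params")
}

#' Reversible-inactivation mode for the generators
#'
#' Emulates local muscimol inactivation of the colliculus. Behaviourally,
#' `"abolish_anticipation"` removes all anticipatory licking (both cue types
#' fall back to baseline) and `"nonselective_anticipation"` makes both cue
#' types evoke the large-reward anticipatory rate (position discrimination
#' lost). Neurally, `cs_response_scale` multiplies the cue-evoked rate bump
#' and `rw_unmasking` switches reward bumps to the unpredicted amplitude on
#' during-inactivation trials.
#'
#' @param mode One of `"none"`, `"abolish_anticipation"`,
#'   `"nonselective_anticipation"`.
#' @param cs_response_scale Multiplier in `[0, 1]` on the cue rate delta.
#' @param rw_unmasking Logical; reward responses become unpredicted-sized.
#' @return Named list of class `pavda_inactivation_mode`.
#' @export
inactivation_mode <- function(mode = c("none", "abolish_anticipation",
                                       "nonselective_anticipation"),
                              cs_response_scale = if (mode == "none") 1 else 0,
                              rw_unmasking = mode != "none") {
  mode <- match.arg(mode)
  if (mode == "none" && (cs_response_scale != 1 || isTRUE(rw_unmasking))) {
    stop("mode 'none' requires cs_response_scale = 1 and rw_unmasking = FALSE")
  }
  stopifnot(cs_response_scale >= 0, cs_response_scale <= 1)
  structure(list(mode = mode, cs_response_scale = cs_response_scale,
                 rw_unmasking = isTRUE(rw_unmasking)),
            class = "pavda_inactivation_mode")
}

#' Trial-timing configuration for the generator
#'
#' Defaults restate the task: fixation period uniform on 0.7-1.2 s, cue
#' presented for 1.0 s (1.7 s available), LR reward 1.3 s after cue onset and
#' SR reward 1.5 s after cue offset, cue positions at 10 degrees eccentricity
#' in the upper (+45) and lower (-45) quadrant.
#'
#' @param fixation_range Uniform range of the fixation period, s.
#' @param cs_duration Cue duration(s), s; one value, or several sampled
#'   per trial.
#' @param iti Inter-trial interval, s.
#' @param invalid_trial_prob Probability of a fixation-break trial.
#' @param field `"affected"` or `"intact"` (which hemifield the cues are in).
#' @param inactivation Logical; when `TRUE` the first `n_pre_trials` trials
#'   are labelled `pre_inactivation` and the remainder `during_inactivation`.
#' @param n_pre_trials Number of pre-injection trials in inactivation
#'   sessions (about 60 cue presentations in the emulated experiments).
#' @param lr_position,sr_position `(eccentricity deg, direction deg)` of the
#'   two cues.
#' @return Named list of class `pavda_trial_config`.
#' @export
trial_config <- function(fixation_range = c(0.7, 1.2),
                         cs_duration = 1.0,
                         iti = 2.0,
                         invalid_trial_prob = 0.05,
                         field = "affected",
                         inactivation = FALSE,
                         n_pre_trials = 60,
                         lr_position = c(10, 45),
                         sr_position = c(10, -45)) {
  stopifnot(length(fixation_range) == 2, fixation_range[1] <= fixation_range[2],
            all(cs_duration > 0), iti >= 0,
            invalid_trial_prob >= 0, invalid_trial_prob < 1,
            field %in% FIELDS)
  structure(list(fixation_range = fixation_range, cs_duration = cs_duration,
                 iti = iti, invalid_trial_prob = invalid_trial_prob,
                 field = field, inactivation = inactivation,
                 n_pre_trials = n_pre_trials,
                 lr_position = lr_position, sr_position = sr_position),
            class = "pavda_trial_config")
}

#' Generate a trial table
#'
#' LR and SR trials are pseudo-randomly interleaved, balanced within blocks
#' of two (so the counts never differ by more than one). Fixation durations
#' are uniform on the configured range; reward times are stored explicitly
#' per the task schedule. Each trial is independently marked invalid with
#' probability `config$invalid_trial_prob`. Deterministic for a fixed seed.
#'
#' @param n_trials Number of trials (>= 1); a daily session has about 200.
#' @param config A [trial_config()].
#' @param rng_seed Integer seed.
#' @return Trial table `data.frame`.
#' @export
generate_trials <- function(n_trials, config = trial_config(), rng_seed = 1) {
  if (n_trials < 1) stop("n_trials must be >= 1")
  set.seed(rng_seed)

  n_blocks <- ceiling(n_trials / 2)
  cond <- unlist(lapply(seq_len(n_blocks), function(b) sample(CONDITIONS)))
  cond <- cond[seq_len(n_trials)]

  fix <- stats::runif(n_trials, config$fixation_range[1],
                      config$fixation_range[2])
  dur <- if (length(config$cs_duration) == 1) {
    rep(config$cs_duration, n_trials)
  } else {
    sample(config$cs_duration, n_trials, replace = TRUE)
  }
  valid <- stats::runif(n_trials) >= config$invalid_trial_prob

  # lay trials end to end on the session clock
  fp_onset <- numeric(n_trials)
  t <- 1.0
  for (i in seq_len(n_trials)) {
    fp_onset[i] <- t
    trial_len <- fix[i] + dur[i] +
      (if (cond[i] == "SR") SR_REWARD_DELAY else 0) + 1.0
    t <- t + trial_len + config$iti
  }
  cs_onset <- fp_onset + fix
  cs_offset <- cs_onset + dur
  reward_time <- ifelse(cond == "LR", cs_onset + LR_REWARD_DELAY,
                        cs_offset + SR_REWARD_DELAY)
  ecc <- ifelse(cond == "LR", config$lr_position[1], config$sr_position[1])
  dir <- ifelse(cond == "LR", config$lr_position[2], config$sr_position[2])

  epoch <- if (config$inactivation) {
    ifelse(seq_len(n_trials) <= config$n_pre_trials,
           "pre_inactivation", "during_inactivation")
  } else {
    rep("none", n_trials)
  }

  data.frame(
    trial_id = seq_len(n_trials),
    condition = cond,
    field = config$field,
    epoch = epoch,
    fp_onset = fp_onset,
    cs_onset = cs_onset,
    cs_offset = cs_offset,
    reward_time = reward_time,
    reward_volume = ifelse(cond == "LR", LR_VOLUME, SR_VOLUME),
    ecc_deg = ecc,
    dir_deg = dir,
    valid = valid,
    stringsAsFactors = FALSE
  )
}

# Piecewise-constant-rate Poisson sampler by thinning. `bumps` is a
# data.frame(start, end, delta); rate(t) = base + sum of overlapping deltas,
# floored at 0.
sample_piecewise_poisson <- function(base, bumps, t_end) {
  if (nrow(bumps) == 0) {
    if (base <= 0) return(numeric(0))
    n <- stats::rpois(1, base * t_end)
    return(sort(stats::runif(n, 0, t_end)))
  }
  # step function of the summed deltas via an event sweep; the thinning
  # envelope is the true maximum of the rate, not the sum of all bumps
  ev_t <- c(bumps$start, bumps$end)
  ev_d <- c(bumps$delta, -bumps$delta)
  o <- order(ev_t)
  ev_t <- ev_t[o]
  ev_d <- cumsum(ev_d[o])
  lambda_max <- base + max(0, max(ev_d))
  if (lambda_max <= 0) return(numeric(0))

  n_cand <- stats::rpois(1, lambda_max * t_end)
  cand <- sort(stats::runif(n_cand, 0, t_end))
  if (length(cand) == 0) return(numeric(0))
  idx <- findInterval(cand, ev_t)
  delta_at <- ifelse(idx == 0, 0, ev_d[pmax(idx, 1)])
  rate <- pmax(base + delta_at, 0)
  cand[stats::runif(length(cand)) < rate / lambda_max]
}

strictly_increasing <- function(times) {
  # quantize to the bundle's 1 microsecond resolution, then push collisions
  # (exact ties or sub-microsecond gaps) forward by 1 microsecond steps
  times <- round(times, 6)
  if (length(times) < 2) return(times)
  repeat {
    bad <- which(diff(times) < 1e-6 - 1e-12) + 1L
    if (length(bad) == 0) break
    times[bad] <- round(times[bad - 1L] + 1e-6, 6)
    times <- sort(times)
  }
  times
}

ms <- function(x) x / 1000

#' Generate a spike train for a trial table
#'
#' Inhomogeneous Poisson process by thinning. The intensity is
#' `baseline_rate` plus one rectangular bump per event (fixation-point onset,
#' cue onset, reward) on every valid trial: onset at
#' `event + response_latency`, length `response_duration`, height the
#' per-event delta from `params`. Reward bumps use the predicted amplitude
#' when the cue response was intact on that trial and the unpredicted one
#' under inactivation with reward unmasking. Invalid (fixation-break) trials
#' contribute baseline only. Ties are broken by +1 microsecond jitter so
#' spike times are strictly increasing.
#'
#' @param trials Trial table (from [generate_trials()]).
#' @param params A [neuron_params()].
#' @param rng_seed Integer seed.
#' @param mode Optional [inactivation_mode()], applied to trials in the
#'   `during_inactivation` epoch.
#' @param t_end Session end time, s (default: 2 s past the last event).
#' @return Numeric vector of spike times, s.
#' @export
generate_spike_train <- function(trials, params, rng_seed = 1, mode = NULL,
                                 t_end = NULL) {
  if (nrow(trials) == 0) stop("empty trial table")
  set.seed(rng_seed)
  mode <- mode %||% inactivation_mode("none")
  t_end <- t_end %||% (max(trials$reward_time, trials$cs_offset,
                           na.rm = TRUE) + 2)

  lat <- ms(params$response_latency)
  dur <- ms(params$response_duration)
  tv <- trials[trials$valid, , drop = FALSE]

  during <- tv$epoch == "during_inactivation"
  cs_scale <- ifelse(during, mode$cs_response_scale, 1)
  cs_delta <- ifelse(tv$condition == "LR", params$cs_delta_lr,
                     params$cs_delta_sr) * cs_scale
  rw_delta <- ifelse(during & mode$rw_unmasking,
                     params$rw_delta_unpredicted, params$rw_delta_predicted)

  bumps <- rbind(
    data.frame(start = tv$fp_onset + lat, delta = params$fp_delta),
    data.frame(start = tv$cs_onset + lat, delta = cs_delta),
    data.frame(start = tv$reward_time[is.finite(tv$reward_time)] + lat,
               delta = rw_delta[is.finite(tv$reward_time)])
  )
  bumps$end <- bumps$start + dur
  bumps <- bumps[bumps$delta != 0, , drop = FALSE]

  st <- sample_piecewise_poisson(params$baseline_rate, bumps, t_end)
  strictly_increasing(st)
}

#' Generate a lick-event record for a trial table
#'
#' Poisson point process with the [behavior_params()] rate profile:
#' baseline everywhere; a condition-specific anticipatory rate from
#' `anticipation_onset` after cue onset until reward delivery on valid
#' trials; a 1 s post-reward burst. Under `"abolish_anticipation"` both
#' anticipatory rates fall to baseline; under `"nonselective_anticipation"`
#' both cue types use the LR anticipatory rate. An 80 ms refractory period
#' (below the 100 ms analysis bin) is enforced by thinning.
#'
#' @param trials Trial table.
#' @param params A [behavior_params()].
#' @param mode An [inactivation_mode()]; applied to `during_inactivation`
#'   trials, or to all trials when the whole session is an inactivation
#'   session with no epoch labels.
#' @param rng_seed Integer seed.
#' @param anticipatory_rates Optional per-trial vector overriding the
#'   condition-derived anticipatory rate (used by the reversal-learning
#'   generator, where the rate follows cue position during relearning).
#' @param refractory_s Minimum inter-lick interval, s.
#' @param t_end Session end time, s.
#' @return Numeric vector of lick times, s.
#' @export
generate_licks <- function(trials, params = behavior_params(),
                           mode = inactivation_mode("none"), rng_seed = 1,
                           anticipatory_rates = NULL, refractory_s = 0.08,
                           t_end = NULL) {
  if (nrow(trials) == 0) stop("empty trial table")
  set.seed(rng_seed + 104729L)  # decouple from the spike stream
  t_end <- t_end %||% (max(trials$reward_time, trials$cs_offset,
                           na.rm = TRUE) + 2)

  tv <- trials[trials$valid & is.finite(trials$reward_time), , drop = FALSE]
  if (is.null(anticipatory_rates)) {
    ant <- ifelse(tv$condition == "LR", params$lick_anticipatory_lr,
                  params$lick_anticipatory_sr)
  } else {
    ant <- anticipatory_rates[trials$valid & is.finite(trials$reward_time)]
  }
  affected <- if (any(tv$epoch != "none")) tv$epoch == "during_inactivation"
              else rep(mode$mode != "none", nrow(tv))
  if (mode$mode == "abolish_anticipation") {
    ant[affected] <- params$lick_baseline
  } else if (mode$mode == "nonselective_anticipation") {
    ant[affected] <- params$lick_anticipatory_lr
  }

  ant_start <- tv$cs_onset + params$anticipation_onset
  bumps <- rbind(
    data.frame(start = ant_start, end = tv$reward_time,
               delta = ant - params$lick_baseline),
    data.frame(start = tv$reward_time, end = tv$reward_time + 1,
               delta = params$lick_post_reward - params$lick_baseline)
  )
  bumps <- bumps[bumps$delta != 0 & bumps$end > bumps$start, , drop = FALSE]

  licks <- sample_piecewise_poisson(params$lick_baseline, bumps, t_end)
  if (length(licks) > 1 && refractory_s > 0) {
    keep <- logical(length(licks))
    last <- -Inf
    for (i in seq_along(licks)) {
      if (licks[i] - last >= refractory_s) {
        keep[i] <- TRUE
        last <- licks[i]
      }
    }
    licks <- licks[keep]
  }
  licks
}

#' Generate a biphasic spike-waveform template
#'
#' Builds a template with a negative trough followed by a positive peak whose
#' trough-to-peak time equals `params$waveform_width` to within half a
#' sample: the trough is snapped to the sample grid and each extremum is a
#' raised-cosine lobe narrow enough that the lobes never overlap, so the
#' continuous extrema sit exactly at the programmed times. Optional additive
#' Gaussian noise.
#'
#' @param params A [neuron_params()] (only `waveform_width` is used).
#' @param rng_seed Integer seed (noise only).
#' @param sample_interval_ms Sampling interval, ms.
#' @param n_samples Template length in samples.
#' @param noise_sd SD of additive noise, in units of the trough amplitude (1).
#' @param epoch_label Label stored on the template.
#' @return A [waveform_template()].
#' @export
generate_waveform <- function(params, rng_seed = 1,
                              sample_interval_ms = 0.025, n_samples = 64,
                              noise_sd = 0, epoch_label = "") {
  w <- params$waveform_width
  dt <- sample_interval_ms
  if (w <= 2 * dt) stop("width not representable at this sample rate")
  t <- (seq_len(n_samples) - 1) * dt
  t_trough <- round(0.4 / dt) * dt
  t_peak <- t_trough + w
  if (t_peak >= t[n_samples] - dt) stop("width not representable: template too short")

  lobe <- function(center, half_width, amp) {
    y <- numeric(n_samples)
    in_lobe <- abs(t - center) <= half_width
    y[in_lobe] <- amp * 0.5 * (1 + cos(pi * (t[in_lobe] - center) / half_width))
    y
  }
  hw <- 0.4 * w  # lobes span 80% of the width in total: no overlap
  samples <- lobe(t_trough, hw, -1) + lobe(t_peak, hw, 0.7)
  if (noise_sd > 0) {
    set.seed(rng_seed)
    samples <- samples + stats::rnorm(n_samples, 0, noise_sd)
  }
  waveform_template(samples, dt, epoch_label)
}

#' Psychophysics simulation parameters
#'
#' One contrast-detection threshold (the Michelson contrast at which
#' sensitivity reaches the d' = 2 criterion) per visual-field location, plus
#' a common log-contrast slope and guess rate. Default grids follow the two
#' tested layouts: 3 directions x 3 eccentricities and 5 x 4, directions
#' evenly spaced in the hemifield, eccentricities 5-20 degrees.
#'
#' @param thresholds Numeric vector in (0,1), one per grid row (recycled).
#' @param slope Log-contrast slope of the psychometric function.
#' @param guess_rate Lower asymptote in `[0, 1)`.
#' @param grid `data.frame(ecc_deg, dir_deg)` of target locations.
#' @param criterion_p Proportion correct defining the d' = 2 threshold
#'   (default `pnorm(1)`, the equal-variance yes/no mapping `Phi(d'/2)`).
#' @return Named list of class `pavda_psycho_params`.
#' @export
psycho_params <- function(thresholds = 0.3, slope = 3, guess_rate = 0.05,
                          grid = psycho_grid("3x3"),
                          criterion_p = stats::pnorm(1)) {
  stopifnot(nrow(grid) > 0, all(thresholds > 0 & thresholds < 1),
            guess_rate >= 0, guess_rate < 1,
            criterion_p > guess_rate, criterion_p < 1)
  structure(list(thresholds = rep_len(thresholds, nrow(grid)), slope = slope,
                 guess_rate = guess_rate, grid = grid,
                 criterion_p = criterion_p),
            class = "pavda_psycho_params")
}

#' Standard target grids for saccade-detection testing
#'
#' @param layout `"3x3"` (3 directions x 3 eccentricities) or `"5x4"`
#'   (5 directions x 4 eccentricities); directions evenly spaced across the
#'   hemifield, eccentricities from `{5, 10, 15, 20}` degrees.
#' @return `data.frame(ecc_deg, dir_deg)`.
#' @export
psycho_grid <- function(layout = c("3x3", "5x4")) {
  layout <- match.arg(layout)
  if (layout == "3x3") {
    dirs <- c(-45, 0, 45)
    eccs <- c(5, 10, 15)
  } else {
    dirs <- c(-60, -30, 0, 30, 60)
    eccs <- c(5, 10, 15, 20)
  }
  expand.grid(ecc_deg = eccs, dir_deg = dirs, KEEP.OUT.ATTRS = FALSE)
}

#' Simulate contrast-graded saccade-detection trials
#'
#' For each grid location and contrast, draws `n_per_cell` Bernoulli trials
#' with success probability
#' `guess + (1 - guess) * Phi(slope * (log c - log threshold) + z2)`,
#' where `z2` places the probability exactly at the d' = 2 criterion when
#' `c = threshold`. Correct trials land near the target (0.5 degree scatter);
#' incorrect trials are recorded as non-responses (scored incorrect
#' downstream).
#'
#' @param params A [psycho_params()].
#' @param n_per_cell Trials per location x contrast.
#' @param contrasts Michelson contrasts in (0,1); default 7 log-spaced values
#'   over the tested 0.02-0.9 range.
#' @param rng_seed Integer seed.
#' @return `data.frame` with columns
#'   `ecc_deg, dir_deg, contrast, endpoint_x, endpoint_y, responded`.
#' @export
generate_psychometric_trials <- function(params, n_per_cell = 20,
                                         contrasts = default_contrasts(),
                                         rng_seed = 1) {
  stopifnot(all(contrasts > 0 & contrasts < 1))
  if (nrow(params$grid) == 0) stop("empty grid")
  set.seed(rng_seed)
  g <- params$guess_rate
  z2 <- stats::qnorm((params$criterion_p - g) / (1 - g))

  rows <- list()
  for (i in seq_len(nrow(params$grid))) {
    ecc <- params$grid$ecc_deg[i]
    dir <- params$grid$dir_deg[i]
    thr <- params$thresholds[i]
    target <- polar_to_cart(ecc, dir)
    for (ct in contrasts) {
      p <- g + (1 - g) *
        stats::pnorm(params$slope * (log(ct) - log(thr)) + z2)
      correct <- stats::runif(n_per_cell) < p
      ex <- ifelse(correct, target[1] + stats::rnorm(n_per_cell, 0, 0.5),
                   NA_real_)
      ey <- ifelse(correct, target[2] + stats::rnorm(n_per_cell, 0, 0.5),
                   NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        ecc_deg = ecc, dir_deg = dir, contrast = ct,
        endpoint_x = ex, endpoint_y = ey, responded = correct,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' @rdname generate_psychometric_trials
#' @export
default_contrasts <- function() {
  # rounded to the bundle's 6-decimal serialization so sessions round-trip
  round(exp(seq(log(0.02), log(0.9), length.out = 7)), 6)
}

#' Generate a reversal-learning dataset
#'
#' One session per day. The reward assignment of the two cue positions
#' (upper/lower quadrant) switches on each day in `switch_days`; the
#' anticipatory lick rate attached to each *position* relaxes exponentially
#' toward its newly assigned value with per-day fraction `learning_rate`,
#' applied overnight — the switch day itself is still performed with the
#' pre-switch rates, and with `learning_rate = 1` the day after the switch
#' is already fully reversed. Emulates gradual relearning.
#'
#' @param n_days Number of daily sessions.
#' @param switch_days Days (1-based) on which the assignment flips.
#' @param learning_rate Per-day relaxation fraction in `[0, 1]`.
#' @param rng_seed Integer seed.
#' @param n_trials Trials per day.
#' @param params [behavior_params()] supplying the asymptotic rates.
#' @param config [trial_config()] for the daily trial tables.
#' @return List of `pavda_session`; each has `metadata$day`,
#'   `metadata$assignment` (`"upper_LR"` or `"upper_SR"`) and
#'   `metadata$switch_day` flags.
#' @export
generate_reversal_dataset <- function(n_days, switch_days = integer(0),
                                      learning_rate = 0.5, rng_seed = 1,
                                      n_trials = 100,
                                      params = behavior_params(),
                                      config = trial_config()) {
  stopifnot(all(switch_days >= 1 & switch_days <= n_days),
            learning_rate >= 0, learning_rate <= 1)
  upper_is_lr <- TRUE
  rate_upper <- params$lick_anticipatory_lr
  rate_lower <- params$lick_anticipatory_sr

  sessions <- vector("list", n_days)
  for (day in seq_len(n_days)) {
    if (day %in% switch_days) upper_is_lr <- !upper_is_lr

    day_cfg <- config
    if (!upper_is_lr) {  # swap cue positions with the assignment
      day_cfg$lr_position <- config$sr_position
      day_cfg$sr_position <- config$lr_position
    }
    trials <- generate_trials(n_trials, day_cfg, rng_seed + day)
    ant <- ifelse(trials$dir_deg > 0, rate_upper, rate_lower)
    licks <- generate_licks(trials, params, rng_seed = rng_seed + day,
                            anticipatory_rates = ant)
    sessions[[day]] <- session(
      trials, licks = licks,
      metadata = list(day = day,
                      assignment = if (upper_is_lr) "upper_LR" else "upper_SR",
                      switch_day = day %in% switch_days)
    )

    # licking relaxes toward the day's assignment overnight: the switch day
    # itself is performed with the pre-switch rates
    target_upper <- if (upper_is_lr) params$lick_anticipatory_lr
                    else params$lick_anticipatory_sr
    target_lower <- if (upper_is_lr) params$lick_anticipatory_sr
                    else params$lick_anticipatory_lr
    rate_upper <- rate_upper + learning_rate * (target_upper - rate_upper)
    rate_lower <- rate_lower + learning_rate * (target_lower - rate_lower)
  }
  sessions
}

#' Sample a synthetic dopamine-neuron population
#'
#' Draws per-neuron cue-response latencies uniform on 60-160 ms (the observed
#' spread of individual latencies) around otherwise shared [neuron_params()].
#'
#' @param n Number of neurons.
#' @param rng_seed Integer seed.
#' @param base [neuron_params()] template.
#' @param latency_range Uniform range for per-neuron latencies, ms.
#' @return List of [neuron_params()], one per neuron, with names `da_01`, ...
#' @export
sample_da_population <- function(n, rng_seed = 1,
                                 base = neuron_params("DA"),
                                 latency_range = c(60, 160)) {
  set.seed(rng_seed)
  lat <- stats::runif(n, latency_range[1], latency_range[2])
  pop <- lapply(seq_len(n), function(i) {
    p <- base
    p$response_latency <- lat[i]
    p
  })
  names(pop) <- sprintf("da_%02d", seq_len(n))
  pop
}

#' Generate a complete synthetic session with ground truth
#'
#' Convenience wrapper tying the generators together: one trial table,
#' `n_da` dopamine-like and `n_snr` reticulata-like units (spike trains plus
#' waveform templates), a lick record, and optional saccade psychophysics.
#' The returned object carries the generating parameters in
#' `metadata$truth` so recovery tests can compare estimates to ground truth.
#'
#' @param n_trials Trials in the session.
#' @param n_da,n_snr Numbers of units of each kind.
#' @param config [trial_config()].
#' @param behavior [behavior_params()].
#' @param mode [inactivation_mode()].
#' @param psycho Optional [psycho_params()]; `NULL` for no psychophysics.
#' @param n_per_cell Psychophysics trials per location x contrast.
#' @param rng_seed Integer seed.
#' @param waveform_noise_sd Noise SD on the stored waveform templates.
#' @return A `pavda_session`.
#' @export
generate_session <- function(n_trials = 200, n_da = 2, n_snr = 1,
                             config = trial_config(),
                             behavior = behavior_params(),
                             mode = inactivation_mode("none"),
                             psycho = NULL, n_per_cell = 20,
                             rng_seed = 1, waveform_noise_sd = 0.02) {
  trials <- generate_trials(n_trials, config, rng_seed)
  spikes <- list()
  waveforms <- list()
  truth_neurons <- list()

  pop <- c(sample_da_population(n_da, rng_seed),
           stats::setNames(replicate(n_snr, neuron_params("SNr"),
                                     simplify = FALSE),
                           if (n_snr > 0) sprintf("snr_%02d", seq_len(n_snr))
                           else character(0)))
  for (i in seq_along(pop)) {
    id <- names(pop)[i]
    p <- pop[[i]]
    spikes[[id]] <- generate_spike_train(trials, p, rng_seed + i, mode)
    waveforms[[id]] <- list(
      generate_waveform(p, rng_seed + i, noise_sd = waveform_noise_sd,
                        epoch_label = "before")
    )
    truth_neurons[[id]] <- unclass(p)
  }
  licks <- generate_licks(trials, behavior, mode, rng_seed)
  ps <- if (!is.null(psycho)) {
    generate_psychometric_trials(psycho, n_per_cell, rng_seed = rng_seed)
  }

  truth <- list(
    rng_seed = rng_seed,
    trial_config = unclass(config),
    behavior = unclass(behavior),
    inactivation = unclass(mode),
    neurons = truth_neurons
  )
  if (!is.null(psycho)) {
    truth$psycho <- list(thresholds = psycho$thresholds,
                         slope = psycho$slope,
                         guess_rate = psycho$guess_rate,
                         criterion_p = psycho$criterion_p,
                         grid = psycho$grid)
  }
  session(trials, spikes, waveforms, licks, ps,
          metadata = list(subject = "synthetic", date = "1970-01-01",
                          field = config$field,
                          inactivation = config$inactivation,
                          truth = truth))
}
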