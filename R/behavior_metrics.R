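# Conditioned-licking quantification: cue-aligned lick-rate profiles,
# cue-window rates, the paired/unpaired test battery, reversible-inactivation
# contrasts and reversal-learning summaries.

#' Cue-aligned lick-rate profile
#'
#' Licks are counted in `bin_width` bins (default 0.1 s) across the valid
#' trials of each condition and converted to rates:
#' `rate[b] = total licks in bin b / (n_trials * bin_width)`. The default
#' window -1 to +3.5 s spans the pre-cue baseline through both reward
#' deliveries.
#'
#' @param licks Lick-time vector, s.
#' @param trials Trial table.
#' @param condition Conditions to include (default both).
#' @param bin_width Bin width, s.
#' @param window `(start, end)` s relative to cue onset.
#' @return Object of class `pavda_lick_profile`: `bin_width`, `window`,
#'   `bin_starts`, `rates` (named list per condition, licks/s), `n_trials`.
#' @export
lick_rate_profile <- function(licks, trials, condition = CONDITIONS,
                              bin_width = 0.1, window = c(-1, 3.5)) {
  stopifnot(window[1] < window[2], bin_width > 0)
  tv <- valid_trials(trials, condition = condition)
  if (nrow(tv) == 0) stop("empty selection: no valid trials")
  nb <- round((window[2] - window[1]) / bin_width)
  bin_starts <- window[1] + (seq_len(nb) - 1) * bin_width
  rates <- list()
  n_trials <- integer(0)
  for (cond in intersect(condition, unique(tv$condition))) {
    ev <- tv$cs_onset[tv$condition == cond]
    counts <- rep(0, nb)
    for (e in ev) {
      counts <- counts + count_in_windows(licks, e + bin_starts,
                                          e + bin_starts + bin_width)
    }
    rates[[cond]] <- counts / (length(ev) * bin_width)
    n_trials[cond] <- length(ev)
  }
  structure(list(bin_width = bin_width, window = window,
                 bin_starts = bin_starts, rates = rates,
                 n_trials = n_trials),
            class = "pavda_lick_profile")
}

#' Cue-window conditioned-response rate
#'
#' Session-level licking rate: mean over valid trials of the lick count in
#' `[cs_onset + w0, cs_onset + w1)` divided by the window length. The
#' standard windows are 0-1.3 s (cue presentation up to the large-reward
#' delivery) and 0-0.7 s (for inactivation contrasts, clear of all reward
#' events under both cue durations).
#'
#' @param licks Lick-time vector, s.
#' @param trials Trial table.
#' @param condition Conditions to include.
#' @param window `(start, end)` s relative to cue onset.
#' @return Licks/s (scalar).
#' @export
cr_rate <- function(licks, trials, condition = CONDITIONS,
                    window = c(0, 1.3)) {
  mean(per_trial_lick_rates(licks, trials, condition, window))
}

per_trial_lick_rates <- function(licks, trials, condition, window) {
  stopifnot(window[1] < window[2])
  tv <- valid_trials(trials, condition = condition)
  if (nrow(tv) == 0) stop("empty selection: no valid trials")
  count_in_windows(licks, tv$cs_onset + window[1], tv$cs_onset + window[2]) /
    (window[2] - window[1])
}

#' Conditioned licking versus pre-cue baseline
#'
#' Pairs each valid trial's cue-window lick rate with its own baseline rate
#' over the 1 s before cue onset and applies a one-tailed paired t-test for
#' cue > baseline. With identical rates on every trial the statistic is 0
#' and the one-tailed p is reported as 0.5 (boundary convention, flagged
#' `no_variance`).
#'
#' @param licks Lick-time vector, s.
#' @param trials Trial table.
#' @param condition Conditions to include.
#' @param window Cue window, s relative to cue onset.
#' @param baseline_window Baseline window, s relative to cue onset.
#' @return List with `statistic`, `p_value`, `n` (see
#'   [compare_window_rates()]).
#' @export
test_cr_vs_baseline <- function(licks, trials, condition = CONDITIONS,
                                window = c(0, 1.3),
                                baseline_window = c(-1, 0)) {
  cs <- per_trial_lick_rates(licks, trials, condition, window)
  base <- per_trial_lick_rates(licks, trials, condition, baseline_window)
  compare_window_rates(cs, base, test = "one_sample_t", tail = "greater")
}

#' Large- versus small-reward licking across sessions
#'
#' Two-sided Wilcoxon signed-rank test on paired per-session cue-window
#' rates. Identical lists return `p = 1` (tie convention).
#'
#' @param session_rates_lr,session_rates_sr Paired per-session rates.
#' @return List with `statistic` (W), `p_value`, `n`.
#' @export
test_lr_vs_sr_sessions <- function(session_rates_lr, session_rates_sr) {
  if (length(session_rates_lr) != length(session_rates_sr)) {
    stop("unequal lengths: sessions must be paired")
  }
  compare_window_rates(session_rates_lr, session_rates_sr,
                       test = "wilcoxon_signed_rank")
}

#' Affected- versus intact-field licking
#'
#' Two-sided Welch two-sample t-test on independent per-session rates from
#' the two hemifields.
#'
#' @param rates_affected,rates_intact Per-session rates (independent).
#' @return List with `statistic` (t), `p_value`, `n`.
#' @export
test_affected_vs_intact <- function(rates_affected, rates_intact) {
  compare_window_rates(rates_affected, rates_intact, test = "welch_t")
}

#' Per-session LR-SR licking-rate difference
#'
#' @param licks Lick-time vector, s.
#' @param trials Trial table (pre-filter by epoch for before/during
#'   contrasts).
#' @param window Cue window, s (default 0-0.7 s: free of reward events in
#'   both conditions under either cue duration).
#' @return List: `lr`, `sr`, `lr_minus_sr` (licks/s), `window`.
#' @export
cr_summary <- function(licks, trials, window = c(0, 0.7)) {
  lr <- cr_rate(licks, trials, condition = "LR", window = window)
  sr <- cr_rate(licks, trials, condition = "SR", window = window)
  list(lr = lr, sr = sr, lr_minus_sr = lr - sr, window = window)
}

#' Inactivation effect on the conditioned-response contrast
#'
#' Given paired per-session LR-SR licking-rate differences before and
#' during local inactivation, reports (i) a two-sided Wilcoxon signed-rank
#' test of before versus during and (ii) a one-sample t-test of the
#' during-inactivation differences against zero. All-zero during values are
#' flagged `no_variance` rather than producing a degenerate t.
#'
#' @param before,during Numeric vectors of per-session `lr_minus_sr`
#'   (licks/s), paired by session; lists of [cr_summary()] results are also
#'   accepted.
#' @return List: `wilcoxon_before_vs_during`, `t_during_vs_zero`, `n`.
#' @export
inactivation_effect <- function(before, during) {
  pick <- function(x) {
    if (is.list(x)) vapply(x, function(s) s$lr_minus_sr, numeric(1))
    else as.numeric(x)
  }
  b <- pick(before)
  d <- pick(during)
  if (length(b) != length(d)) stop("before/during must be paired")
  list(
    wilcoxon_before_vs_during =
      compare_window_rates(b, d, test = "wilcoxon_signed_rank"),
    t_during_vs_zero =
      compare_window_rates(d, test = "one_sample_t"),
    n = length(b)
  )
}

#' Reversal-learning summary
#'
#' Groups cue-window licking by cue screen position (upper versus lower
#' quadrant, by the sign of `dir_deg`) — not by reward size — for each daily
#' session, and finds the crossover day: the first day at or after an
#' assignment switch on which the position ordering is inverted relative to
#' the pre-switch ordering and stays inverted on the following day
#' (sustained-for-2-days rule; a bookkeeping definition, documented as
#' such). Undefined (`NA`) when no sustained inversion occurs.
#'
#' @param daily_sessions List of `pavda_session`, each with
#'   `metadata$assignment` (`"upper_LR"`/`"upper_SR"`) and
#'   `metadata$switch_day`.
#' @param window Cue window for [cr_rate()], s.
#' @return List: `curve` — `data.frame(day, assignment, rate_upper,
#'   rate_lower)` — and `crossover_day` (`NA` if none).
#' @export
reversal_curve <- function(daily_sessions, window = c(0, 1.3)) {
  n <- length(daily_sessions)
  rows <- lapply(seq_len(n), function(i) {
    s <- daily_sessions[[i]]
    if (is.null(s$metadata$assignment)) {
      stop(sprintf("session %d: missing assignment label", i))
    }
    up <- s$trials$dir_deg > 0
    data.frame(
      day = s$metadata$day %||% i,
      assignment = s$metadata$assignment,
      switch_day = isTRUE(s$metadata$switch_day),
      rate_upper = cr_rate(s$licks, s$trials[up, , drop = FALSE],
                           window = window),
      rate_lower = cr_rate(s$licks, s$trials[!up, , drop = FALSE],
                           window = window),
      stringsAsFactors = FALSE
    )
  })
  curve <- do.call(rbind, rows)

  crossover <- NA_integer_
  switches <- which(curve$switch_day)
  if (length(switches) > 0) {
    sw <- switches[1]
    if (sw > 1) {
      pre_order <- sign(curve$rate_upper[sw - 1] - curve$rate_lower[sw - 1])
      for (d in sw:nrow(curve)) {
        inv <- sign(curve$rate_upper[d] - curve$rate_lower[d]) == -pre_order
        nxt <- d < nrow(curve) &&
          sign(curve$rate_upper[d + 1] - curve$rate_lower[d + 1]) == -pre_order
        if (inv && nxt) {
          crossover <- curve$day[d]
          break
        }
      }
    }
  }
  list(curve = curve, crossover_day = crossover)
}
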