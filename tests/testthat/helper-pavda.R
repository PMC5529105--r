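# Shared fixtures and independent oracles. Everything is built in code at
# test time; no stored data.

# a small but complete valid session
make_tiny_session <- function(rng_seed = 7, n_trials = 20) {
  generate_session(n_trials = n_trials, n_da = 1, n_snr = 1,
                   rng_seed = rng_seed)
}

# Exhaustive-enumeration oracle for the two-sided exact sign test: the
# fraction of all 2^n equally likely sign patterns whose positive count is
# at least as extreme (in |k - n/2|) as the observed one.
enum_sign_p <- function(n, k) {
  counts <- rowSums(expand.grid(rep(list(c(0L, 1L)), n)))
  mean(abs(counts - n / 2) >= abs(k - n / 2))
}

# Permutation oracle for the two-sided two-sample location test, using the
# studentized (Welch) statistic on each of 1e4 relabellings.
perm_p_two_sample <- function(a, b, n_perm = 1e4, seed = 42) {
  set.seed(seed)
  welch_stat <- function(x, y) {
    (mean(x) - mean(y)) /
      sqrt(var(x) / length(x) + var(y) / length(y))
  }
  pooled <- c(a, b)
  obs <- abs(welch_stat(a, b))
  na <- length(a)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), na)
    if (abs(welch_stat(pooled[idx], pooled[-idx])) >= obs - 1e-12) {
      hits <- hits + 1L
    }
  }
  hits / n_perm
}

# Deterministic spike train: one spike per `step` seconds over [0, t_end)
regular_train <- function(step, t_end, offset = step / 2) {
  seq(offset, t_end, by = step)
}
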