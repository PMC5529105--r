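# Session data model: trial table, spike trains, waveform templates, lick
# events, saccade psychophysics. All event times are seconds on one session
# clock; analyses align by subtraction.

TRIAL_COLUMNS <- c(
  "trial_id", "condition", "field", "epoch", "fp_onset", "cs_onset",
  "cs_offset", "reward_time", "reward_volume", "ecc_deg", "dir_deg", "valid"
)

CONDITIONS <- c("LR", "SR")
FIELDS <- c("affected", "intact")
EPOCHS <- c("pre_inactivation", "during_inactivation", "none")

PSYCHO_COLUMNS <- c("ecc_deg", "dir_deg", "contrast",
                    "endpoint_x", "endpoint_y", "responded")

# Reward schedule defaults: the large reward is delivered 1.3 s after cue
# onset (i.e. during the cue), the small reward 1.5 s after cue offset.
LR_REWARD_DELAY <- 1.3
SR_REWARD_DELAY <- 1.5
LR_VOLUME <- 0.17
SR_VOLUME <- 0.06

#' Construct a spike waveform template
#'
#' An averaged extracellular spike waveform, used for trough-to-peak width
#' measurement and for across-epoch stability checks.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units), at least 16
#'   samples.
#' @param sample_interval_ms Milliseconds between consecutive samples (> 0).
#' @param epoch_label Free-text label, e.g. `"before"`, `"after-injection"`.
#' @return An object of class `pavda_waveform`.
#' @export
waveform_template <- function(samples, sample_interval_ms, epoch_label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 16L) stop("waveform needs >= 16 samples")
  if (!is.finite(sample_interval_ms) || sample_interval_ms <= 0) {
    stop("sample_interval_ms must be > 0")
  }
  structure(
    list(samples = samples,
         sample_interval_ms = as.numeric(sample_interval_ms),
         epoch_label = as.character(epoch_label)),
    class = "pavda_waveform"
  )
}

#' Construct a session object
#'
#' Bundles the trial table, spike trains, waveform templates, lick events and
#' optional saccade-psychophysics trials for one recording/behaviour day.
#' Construction does not validate; see [validate_session()].
#'
#' @param trials Trial table (`data.frame`, columns as in [read_session()]).
#' @param spikes Named list, `neuron_id -> numeric vector` of spike times (s).
#' @param waveforms Named list, `neuron_id -> list` of [waveform_template()]s.
#' @param licks Numeric vector of lick-event times (s).
#' @param psychometrics Optional `data.frame` of saccade-detection trials
#'   (columns `ecc_deg, dir_deg, contrast, endpoint_x, endpoint_y, responded`)
#'   or `NULL`.
#' @param metadata Named list (subject id, date, field tested, inactivation
#'   flag, ...).
#' @return Object of class `pavda_session`.
#' @export
session <- function(trials, spikes = list(), waveforms = list(),
                    licks = numeric(0), psychometrics = NULL,
                    metadata = list()) {
  structure(
    list(trials = trials, spikes = spikes, waveforms = waveforms,
         licks = as.numeric(licks), psychometrics = psychometrics,
         metadata = metadata),
    class = "pavda_session"
  )
}

#' @export
print.pavda_session <- function(x, ...) {
  cat(sprintf(
    "<pavda_session> %d trials (%d valid), %d neurons, %d licks%s\n",
    nrow(x$trials), sum(x$trials$valid), length(x$spikes), length(x$licks),
    if (is.null(x$psychometrics)) "" else
      sprintf(", %d psychophysics trials", nrow(x$psychometrics))
  ))
  invisible(x)
}

#' Validate a session against the data-model invariants
#'
#' Checks every structural rule the analyses rely on: event ordering within
#' each trial, the explicit reward schedule, monotone spike and lick times,
#' waveform bookkeeping and psychophysics ranges. Reports rather than raises:
#' the return value is a character vector of human-readable violations, empty
#' when the session is clean. It is total — arbitrary malformed field values
#' yield violations, not errors.
#'
#' @param sess A `pavda_session`.
#' @param lr_reward_delay,sr_reward_delay Expected reward latencies (s) from
#'   CS onset (LR) and CS offset (SR).
#' @param cs_durations Allowed CS durations (s); `NULL` to skip the check.
#' @param tol Numeric tolerance (s) for the schedule checks.
#' @return Character vector of violation descriptions (empty if valid).
#' @export
validate_session <- function(sess, lr_reward_delay = LR_REWARD_DELAY,
                             sr_reward_delay = SR_REWARD_DELAY,
                             cs_durations = c(1.0, 1.7), tol = 1e-6) {
  v <- character(0)
  say <- function(...) v <<- c(v, sprintf(...))

  tr <- sess$trials
  if (!is.data.frame(tr)) {
    return("trials: not a data.frame")
  }
  missing_cols <- setdiff(TRIAL_COLUMNS, names(tr))
  if (length(missing_cols) > 0) {
    return(sprintf("trials: missing columns: %s",
                   paste(missing_cols, collapse = ", ")))
  }

  for (i in seq_len(nrow(tr))) {
    id <- tr$trial_id[i]
    if (!tr$condition[i] %in% CONDITIONS) {
      say("trial %s: unknown condition '%s'", id, tr$condition[i])
    }
    if (!tr$field[i] %in% FIELDS) {
      say("trial %s: unknown field '%s'", id, tr$field[i])
    }
    if (!tr$epoch[i] %in% EPOCHS) {
      say("trial %s: unknown epoch '%s'", id, tr$epoch[i])
    }
    fp <- tr$fp_onset[i]; on <- tr$cs_onset[i]; off <- tr$cs_offset[i]
    if (!all(is.finite(c(fp, on, off))) || !(fp < on && on < off)) {
      say("trial %s: event order violated (fp_onset < cs_onset < cs_offset)", id)
      next
    }
    if (!is.null(cs_durations) &&
        !any(abs((off - on) - cs_durations) <= tol)) {
      say("trial %s: CS duration %.6f s not in {%s}", id, off - on,
          paste(cs_durations, collapse = ", "))
    }
    rw <- tr$reward_time[i]
    if (is.finite(rw)) {
      expected <- if (identical(tr$condition[i], "LR")) on + lr_reward_delay
                  else off + sr_reward_delay
      if (tr$condition[i] %in% CONDITIONS && abs(rw - expected) > tol) {
        say("trial %s: reward_time %.6f != scheduled %.6f for %s", id, rw,
            expected, tr$condition[i])
      }
    }
  }

  check_times <- function(x, what) {
    if (length(x) == 0) return(invisible())
    if (anyNA(x) || any(!is.finite(x))) say("%s: non-finite times", what)
    else {
      if (any(x < 0)) say("%s: negative times", what)
      if (any(diff(x) <= 0)) say("%s: times not strictly increasing", what)
    }
  }

  for (id in names(sess$spikes)) check_times(sess$spikes[[id]],
                                             sprintf("neuron %s", id))
  if (length(sess$licks) > 0) {
    if (any(!is.finite(sess$licks))) say("licks: non-finite times")
    else {
      if (any(sess$licks < 0)) say("licks: negative times")
      if (any(diff(sess$licks) < 0)) say("licks: times decreasing")
    }
  }

  for (id in names(sess$waveforms)) {
    if (!id %in% names(sess$spikes)) {
      say("neuron %s: waveform without spike train", id)
    }
    for (w in sess$waveforms[[id]]) {
      if (!inherits(w, "pavda_waveform")) {
        say("neuron %s: waveform entry is not a waveform_template", id)
      }
    }
  }
  orphan <- setdiff(names(sess$spikes), names(sess$waveforms))
  for (id in orphan) say("neuron %s: spike train without waveform", id)

  ps <- sess$psychometrics
  if (!is.null(ps)) {
    miss <- setdiff(PSYCHO_COLUMNS, names(ps))
    if (length(miss) > 0) {
      say("psychometrics: missing columns: %s", paste(miss, collapse = ", "))
    } else {
      bad <- which(!(ps$contrast > 0 & ps$contrast < 1))
      for (i in bad) say("psychometrics row %d: contrast outside (0,1)", i)
      bad <- which(!(ps$ecc_deg > 0))
      for (i in bad) say("psychometrics row %d: eccentricity <= 0", i)
    }
  }
  v
}

fmt_num <- function(x) {
  # fixed 6-decimal serialization; empty marker for missing reward times
  ifelse(is.finite(x), sprintf("%.6f", x), "")
}

#' Write a session bundle to disk
#'
#' Lays the session out as a directory of plain-text files:
#' `trials.csv`, `licks.csv`, `spikes/<id>.csv`, `waveforms/<id>.json`,
#' optional `psychometrics.csv`, and `metadata.json`. Numeric event times are
#' written with 6 decimal places (microsecond resolution), so the byte layout
#' is deterministic for a given session. Refuses to write a session that fails
#' [validate_session()].
#'
#' @param sess A valid `pavda_session`.
#' @param path Target directory (created if needed).
#' @param ... Passed to [validate_session()].
#' @return `path`, invisibly.
#' @export
write_session <- function(sess, path, ...) {
  problems <- validate_session(sess, ...)
  if (length(problems) > 0) {
    stop("refusing to write invalid session:\n  ",
         paste(problems, collapse = "\n  "))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "spikes"), showWarnings = FALSE)
  dir.create(file.path(path, "waveforms"), showWarnings = FALSE)

  tr <- sess$trials[, TRIAL_COLUMNS, drop = FALSE]
  num_cols <- c("fp_onset", "cs_onset", "cs_offset", "reward_time",
                "reward_volume", "ecc_deg", "dir_deg")
  out <- tr
  for (cl in num_cols) out[[cl]] <- fmt_num(tr[[cl]])
  out$valid <- ifelse(tr$valid, "true", "false")
  utils::write.csv(out, file.path(path, "trials.csv"),
                   row.names = FALSE, quote = FALSE)

  utils::write.csv(data.frame(lick_time = fmt_num(sess$licks)),
                   file.path(path, "licks.csv"),
                   row.names = FALSE, quote = FALSE)

  for (id in names(sess$spikes)) {
    utils::write.csv(data.frame(spike_time = fmt_num(sess$spikes[[id]])),
                     file.path(path, "spikes", paste0(id, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  for (id in names(sess$waveforms)) {
    wl <- sess$waveforms[[id]]
    obj <- list(
      sample_interval_ms = wl[[1]]$sample_interval_ms,
      epochs = lapply(wl, function(w)
        list(label = w$epoch_label, samples = round(w$samples, 6)))
    )
    jsonlite::write_json(obj, file.path(path, "waveforms",
                                        paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }

  if (!is.null(sess$psychometrics)) {
    ps <- sess$psychometrics[, PSYCHO_COLUMNS, drop = FALSE]
    out <- ps
    for (cl in c("ecc_deg", "dir_deg", "contrast",
                 "endpoint_x", "endpoint_y")) {
      out[[cl]] <- fmt_num(ps[[cl]])
    }
    out$responded <- ifelse(ps$responded, "true", "false")
    utils::write.csv(out, file.path(path, "psychometrics.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  jsonlite::write_json(sess$metadata, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a session bundle from disk
#'
#' Inverse of [write_session()]. Raises `"malformed bundle"` when a required
#' file is absent, `"invalid spike train"` on non-monotone spike times and
#' `"invalid trial table"` on unknown condition labels; any remaining
#' invariant violations are raised with their [validate_session()] messages.
#'
#' @param path Bundle directory.
#' @return A `pavda_session`.
#' @export
read_session <- function(path) {
  need <- c("trials.csv", "licks.csv", "metadata.json")
  for (f in need) {
    if (!file.exists(file.path(path, f))) {
      stop(sprintf("malformed bundle: missing %s", f))
    }
  }

  tr <- utils::read.csv(file.path(path, "trials.csv"),
                        colClasses = "character")
  miss <- setdiff(TRIAL_COLUMNS, names(tr))
  if (length(miss) > 0) {
    stop("malformed bundle: trials.csv missing columns ",
         paste(miss, collapse = ", "))
  }
  if (nrow(tr) > 0 && !all(tr$condition %in% CONDITIONS)) {
    stop("invalid trial table: unknown condition label")
  }
  num <- function(x) ifelse(x == "", NA_real_, suppressWarnings(as.numeric(x)))
  trials <- data.frame(
    trial_id = as.integer(tr$trial_id),
    condition = tr$condition,
    field = tr$field,
    epoch = tr$epoch,
    fp_onset = num(tr$fp_onset),
    cs_onset = num(tr$cs_onset),
    cs_offset = num(tr$cs_offset),
    reward_time = num(tr$reward_time),
    reward_volume = num(tr$reward_volume),
    ecc_deg = num(tr$ecc_deg),
    dir_deg = num(tr$dir_deg),
    valid = tr$valid == "true",
    stringsAsFactors = FALSE
  )

  lk <- utils::read.csv(file.path(path, "licks.csv"),
                        colClasses = "character")
  licks <- if (nrow(lk) == 0) numeric(0) else as.numeric(lk$lick_time)

  spikes <- list()
  spike_dir <- file.path(path, "spikes")
  if (dir.exists(spike_dir)) {
    for (f in sort(list.files(spike_dir, pattern = "\\.csv$"))) {
      id <- sub("\\.csv$", "", f)
      sp <- utils::read.csv(file.path(spike_dir, f), colClasses = "character")
      st <- if (nrow(sp) == 0) numeric(0) else as.numeric(sp$spike_time)
      if (length(st) > 1 && any(diff(st) <= 0)) {
        stop(sprintf("invalid spike train: neuron %s not strictly increasing",
                     id))
      }
      spikes[[id]] <- st
    }
  }

  waveforms <- list()
  wf_dir <- file.path(path, "waveforms")
  if (dir.exists(wf_dir)) {
    for (f in sort(list.files(wf_dir, pattern = "\\.json$"))) {
      id <- sub("\\.json$", "", f)
      obj <- jsonlite::read_json(file.path(wf_dir, f), simplifyVector = TRUE)
      waveforms[[id]] <- lapply(seq_len(nrow(obj$epochs)), function(i) {
        waveform_template(obj$epochs$samples[[i]], obj$sample_interval_ms,
                          obj$epochs$label[i])
      })
    }
  }

  ps <- NULL
  ps_file <- file.path(path, "psychometrics.csv")
  if (file.exists(ps_file)) {
    raw <- utils::read.csv(ps_file, colClasses = "character")
    ps <- data.frame(
      ecc_deg = num(raw$ecc_deg), dir_deg = num(raw$dir_deg),
      contrast = num(raw$contrast),
      endpoint_x = num(raw$endpoint_x), endpoint_y = num(raw$endpoint_y),
      responded = raw$responded == "true",
      stringsAsFactors = FALSE
    )
  }

  metadata <- jsonlite::read_json(file.path(path, "metadata.json"),
                                  simplifyVector = TRUE)

  sess <- session(trials, spikes, waveforms, licks, ps, metadata)
  problems <- validate_session(sess)
  if (length(problems) > 0) {
    stop("malformed bundle:\n  ", paste(problems, collapse = "\n  "))
  }
  sess
}

#' Keep only the valid trials of a trial table
#'
#' Trials where fixation was broken before CS offset are flagged invalid at
#' acquisition time and excluded from every downstream statistic.
#'
#' @param trials Trial table.
#' @param condition Optional condition filter (`"LR"` or `"SR"`).
#' @param epoch Optional epoch filter.
#' @param field Optional visual-field filter.
#' @return The filtered trial table.
#' @export
valid_trials <- function(trials, condition = NULL, epoch = NULL,
                         field = NULL) {
  keep <- trials$valid
  if (!is.null(condition)) keep <- keep & trials$condition %in% condition
  if (!is.null(epoch)) keep <- keep & trials$epoch %in% epoch
  if (!is.null(field)) keep <- keep & trials$field %in% field
  trials[keep, , drop = FALSE]
}

event_times <- function(trials, align = c("FP", "CS", "RW")) {
  align <- match.arg(align)
  switch(align,
         FP = trials$fp_onset,
         CS = trials$cs_onset,
         RW = trials$reward_time)
}
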