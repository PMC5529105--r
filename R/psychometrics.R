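# Saccade scoring, contrast-unit conversion, maximum-likelihood psychometric
# fitting with a d' = 2 threshold criterion, and visual-field deficit maps.

#' Michelson to Weber contrast
#'
#' With a target brighter than the background,
#' `L = background * (1 + m) / (1 - m)` and the Weber contrast
#' `(L - background) / background` reduces to `2 m / (1 - m)`; the
#' background luminance cancels.
#'
#' @param m Michelson contrast in `[0, 1)`.
#' @param background Background luminance, cd/m^2 (> 0; only validated — the
#'   result does not depend on it).
#' @return Weber contrast (unitless, >= 0).
#' @export
michelson_to_weber <- function(m, background = 1.0) {
  stopifnot(all(m >= 0), all(m < 1), background > 0)
  2 * m / (1 - m)
}

#' Weber to Michelson contrast
#'
#' Algebraic inverse of [michelson_to_weber()]: `m = w / (2 + w)`.
#'
#' @param w Weber contrast (>= 0).
#' @return Michelson contrast in `[0, 1)`.
#' @export
weber_to_michelson <- function(w) {
  stopifnot(all(w >= 0))
  w / (2 + w)
}

#' Convert polar target coordinates to Cartesian degrees
#'
#' @param ecc_deg Eccentricity, degrees.
#' @param dir_deg Direction, degrees from the horizontal axis.
#' @return `c(x, y)` in degrees (or a 2-column matrix for vector input).
#' @export
polar_to_cart <- function(ecc_deg, dir_deg) {
  th <- dir_deg * pi / 180
  if (length(ecc_deg) == 1 && length(dir_deg) == 1) {
    c(ecc_deg * cos(th), ecc_deg * sin(th))
  } else {
    cbind(x = ecc_deg * cos(th), y = ecc_deg * sin(th))
  }
}

#' Scoring-window radius around a saccade target
#'
#' The target window is a circle of half the distance to the neighbouring
#' target. Two printed formula variants exist: `"sine_half_angle"`
#' (`ecc * sin(angle / 2)`, the true half chord-distance and the default)
#' and `"half_sine"` (`ecc * sin(angle) / 2`). A subject-specific
#' `radius_override` replaces the formula entirely.
#'
#' @param ecc_deg Target eccentricity, degrees.
#' @param neighbor_angle_deg Angle between neighbouring targets, degrees.
#' @param variant `"sine_half_angle"` or `"half_sine"`.
#' @param radius_override Fixed radius in degrees, or `NULL`.
#' @return Radius in degrees.
#' @export
saccade_window_radius <- function(ecc_deg, neighbor_angle_deg = 45,
                                  variant = c("sine_half_angle",
                                              "half_sine"),
                                  radius_override = NULL) {
  if (!is.null(radius_override)) return(radius_override)
  variant <- match.arg(variant)
  r <- switch(variant,
    sine_half_angle = ecc_deg * sin(neighbor_angle_deg / 2 * pi / 180),
    half_sine = ecc_deg * sin(neighbor_angle_deg * pi / 180) / 2
  )
  stopifnot(all(r > 0))
  r
}

#' Score a saccade endpoint against its target window
#'
#' Correct iff the Euclidean distance between the endpoint and the target
#' (in Cartesian degrees) is at most the window radius. Non-responses are
#' scored incorrect upstream.
#'
#' @param endpoint `c(x, y)` in degrees.
#' @param target `c(ecc_deg, dir_deg)` polar target position.
#' @param radius Window radius, degrees (see [saccade_window_radius()]).
#' @return Logical.
#' @export
saccade_correct <- function(endpoint, target, radius) {
  tc <- polar_to_cart(target[1], target[2])
  sqrt(sum((endpoint - tc)^2)) <= radius
}

#' Maximum-likelihood psychometric fit with a d' = 2 threshold
#'
#' Fits a cumulative Gaussian in log contrast,
#' `p(c) = g + (1 - g - lapse) * Phi(s * (log c - mu))`, by binomial maximum
#' likelihood with the guess rate `g` fixed and `lapse <= 0.05` fixed. The
#' threshold is the contrast at which the fitted proportion correct equals
#' the d' = 2 criterion probability — `Phi(d'/2) = 0.8413` under the
#' equal-variance yes/no mapping, configurable for other d' models. A fit
#' whose threshold falls outside the tested contrast range (or whose
#' optimizer fails) is returned with `converged = FALSE` and the threshold
#' clamped to the range boundary.
#'
#' @param points `data.frame(contrast, n, n_correct)`; at least 3 distinct
#'   contrasts and 30 trials total.
#' @param guess_rate Fixed lower asymptote.
#' @param lapse Fixed lapse rate (upper asymptote `1 - lapse`), at most 0.05.
#' @param criterion_p Proportion correct defining the threshold.
#' @return List of class `pavda_psycho_fit`: `threshold_michelson`, `slope`,
#'   `guess_rate`, `lapse`, `criterion_p`, `n_trials`, `converged`,
#'   `log_lik`.
#' @export
fit_psychometric <- function(points, guess_rate = 0.05, lapse = 0,
                             criterion_p = stats::pnorm(1)) {
  stopifnot(all(c("contrast", "n", "n_correct") %in% names(points)),
            lapse >= 0, lapse <= 0.05, guess_rate >= 0, guess_rate < 1,
            criterion_p > guess_rate, criterion_p < 1 - lapse)
  if (length(unique(points$contrast)) < 3) {
    stop("need >= 3 distinct contrasts")
  }
  if (sum(points$n) < 30) stop("need >= 30 trials in total")
  frac <- points$n_correct / points$n
  if (all(points$n_correct == points$n) || all(points$n_correct == 0)) {
    stop("degenerate data: all correct or all incorrect at every contrast")
  }

  lc <- log(points$contrast)
  span <- 1 - guess_rate - lapse
  nll <- function(par) {
    p <- guess_rate + span * stats::pnorm(exp(par[2]) * (lc - par[1]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(points$n_correct * log(p) +
           (points$n - points$n_correct) * log(1 - p))
  }
  init <- c(stats::median(lc), log(2))
  opt <- try(stats::optim(init, nll, method = "Nelder-Mead",
                          control = list(maxit = 2000)), silent = TRUE)
  if (inherits(opt, "try-error")) {
    return(structure(list(threshold_michelson = NA_real_, slope = NA_real_,
                          guess_rate = guess_rate, lapse = lapse,
                          criterion_p = criterion_p,
                          n_trials = sum(points$n), converged = FALSE,
                          log_lik = NA_real_),
                     class = "pavda_psycho_fit"))
  }
  mu <- opt$par[1]
  slope <- exp(opt$par[2])
  q <- (criterion_p - guess_rate) / span
  threshold <- exp(mu + stats::qnorm(q) / slope)

  rng <- range(points$contrast)
  converged <- opt$convergence == 0 && is.finite(threshold) &&
    threshold >= rng[1] && threshold <= rng[2]
  if (!is.finite(threshold)) {
    threshold <- rng[2]
  } else if (threshold < rng[1]) {
    threshold <- rng[1]
  } else if (threshold > rng[2]) {
    threshold <- rng[2]
  }
  structure(list(threshold_michelson = threshold, slope = slope,
                 guess_rate = guess_rate, lapse = lapse,
                 criterion_p = criterion_p, n_trials = sum(points$n),
                 converged = converged, log_lik = -opt$value),
            class = "pavda_psycho_fit")
}

#' Build a visual-field deficit map
#'
#' Scores every saccade-detection trial (non-responses incorrect; responses
#' correct iff the endpoint lands inside the target window), aggregates per
#' location x contrast, fits each location with [fit_psychometric()] and
#' tabulates the d' = 2 contrast thresholds over the grid — higher
#' thresholds mark the lesion-affected field.
#'
#' @param psychometrics `data.frame` of trials (`ecc_deg, dir_deg, contrast,
#'   endpoint_x, endpoint_y, responded`).
#' @param grid `data.frame(ecc_deg, dir_deg)`; every cell must have trials.
#' @param neighbor_angle_deg Angle between neighbouring targets, degrees.
#' @param variant Window-radius formula variant.
#' @param radius_override Optional fixed window radius, degrees.
#' @param guess_rate,criterion_p Passed to [fit_psychometric()].
#' @return `data.frame(ecc_deg, dir_deg, threshold_michelson,
#'   threshold_weber, slope, n, converged)`.
#' @export
build_deficit_map <- function(psychometrics, grid,
                              neighbor_angle_deg = 45,
                              variant = "sine_half_angle",
                              radius_override = NULL,
                              guess_rate = 0.05,
                              criterion_p = stats::pnorm(1)) {
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ecc <- grid$ecc_deg[i]
    dir <- grid$dir_deg[i]
    cell <- psychometrics[psychometrics$ecc_deg == ecc &
                            psychometrics$dir_deg == dir, , drop = FALSE]
    if (nrow(cell) == 0) {
      stop(sprintf("empty cell: no trials at (ecc %g, dir %g)", ecc, dir))
    }
    radius <- saccade_window_radius(ecc, neighbor_angle_deg, variant,
                                    radius_override)
    correct <- vapply(seq_len(nrow(cell)), function(j) {
      if (!isTRUE(cell$responded[j]) || is.na(cell$endpoint_x[j])) {
        return(FALSE)
      }
      saccade_correct(c(cell$endpoint_x[j], cell$endpoint_y[j]),
                      c(ecc, dir), radius)
    }, logical(1))
    agg <- stats::aggregate(correct,
                            by = list(contrast = cell$contrast),
                            FUN = function(x) c(n = length(x),
                                                n_correct = sum(x)))
    points <- data.frame(contrast = agg$contrast,
                         n = agg$x[, "n"],
                         n_correct = agg$x[, "n_correct"])
    fit <- fit_psychometric(points, guess_rate = guess_rate,
                            criterion_p = criterion_p)
    data.frame(ecc_deg = ecc, dir_deg = dir,
               threshold_michelson = fit$threshold_michelson,
               threshold_weber =
                 if (is.na(fit$threshold_michelson)) NA_real_
                 else michelson_to_weber(fit$threshold_michelson),
               slope = fit$slope, n = fit$n_trials,
               converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
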