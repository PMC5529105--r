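# Contrast conversion, saccade scoring, psychometric fitting, deficit maps.

test_that("michelson/weber conversions reproduce the printed pairs", {
  expect_equal(signif(michelson_to_weber(0.87), 3), 13.4)
  expect_equal(signif(michelson_to_weber(0.94), 3), 31.3)
  expect_equal(michelson_to_weber(0.9), 18.0)
  expect_equal(round(michelson_to_weber(0.02), 2), 0.04)
  expect_equal(michelson_to_weber(0), 0)
  # background-invariant
  expect_equal(michelson_to_weber(0.5, background = 1),
               michelson_to_weber(0.5, background = 40))
  expect_error(michelson_to_weber(1), "m < 1")
})

test_that("weber_to_michelson inverts to 12 digits and is monotone", {
  expect_equal(weber_to_michelson(0), 0)
  w <- c(0.04, 1, 13.3846153846, 31.3, 100)
  expect_equal(michelson_to_weber(weber_to_michelson(w)), w,
               tolerance = 1e-12)
  m <- seq(0, 0.99, by = 0.01)
  y <- michelson_to_weber(m)
  expect_true(all(diff(y) > 0))          # strictly increasing
  expect_true(all(diff(diff(y)) > 0))    # convex
})

test_that("saccade scoring windows follow both formula variants", {
  expect_equal(saccade_window_radius(10, 90, "sine_half_angle"),
               10 * sin(pi / 4))
  expect_equal(saccade_window_radius(10, 90, "half_sine"), 5)
  expect_equal(saccade_window_radius(10, 45, radius_override = 22.5), 22.5)

  target <- c(10, 45)
  r <- saccade_window_radius(10, 90, "sine_half_angle")  # ~7.07 deg
  expect_true(saccade_correct(polar_to_cart(10, 45), target, r))
  # endpoint 7 degrees off target is still inside a 7.07 degree window
  tc <- polar_to_cart(10, 45)
  expect_true(saccade_correct(tc + c(7, 0), target, r))
  expect_false(saccade_correct(tc + c(r + 0.01, 0), target, r))
})

test_that("saccade_correct is rotation-equivariant", {
  set.seed(77)
  for (i in 1:50) {
    ecc <- runif(1, 3, 20)
    dir <- runif(1, -90, 90)
    off <- rnorm(2, 0, 4)
    rot <- runif(1, 0, 360)
    r <- 5
    ep <- polar_to_cart(ecc, dir) + off
    th <- rot * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    expect_identical(
      saccade_correct(ep, c(ecc, dir), r),
      saccade_correct(as.numeric(R %*% ep), c(ecc, dir + rot), r)
    )
  }
})

test_that("fit_psychometric recovers a programmed threshold", {
  pp <- psycho_params(thresholds = 0.3,
                      grid = data.frame(ecc_deg = 10, dir_deg = 45))
  ok <- vapply(1:10, function(s) {
    tr <- generate_psychometric_trials(pp, n_per_cell = 100, rng_seed = s)
    agg <- aggregate(tr$responded, by = list(contrast = tr$contrast),
                     FUN = sum)
    nt <- as.integer(table(tr$contrast)[as.character(agg$contrast)])
    fit <- fit_psychometric(data.frame(contrast = agg$contrast, n = nt,
                                       n_correct = agg$x),
                            guess_rate = pp$guess_rate)
    fit$converged && abs(fit$threshold_michelson - 0.3) / 0.3 <= 0.1
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("fit_psychometric rejects or flags pathological data", {
  pts <- data.frame(contrast = c(0.1, 0.3, 0.5), n = c(20, 20, 20),
                    n_correct = c(20, 20, 20))
  expect_error(fit_psychometric(pts), "degenerate")
  pts$n_correct <- c(0, 0, 0)
  expect_error(fit_psychometric(pts), "degenerate")
  expect_error(fit_psychometric(pts[1:2, ]), "3 distinct")
  expect_error(fit_psychometric(
    data.frame(contrast = c(0.1, 0.3, 0.5), n = c(5, 5, 5),
               n_correct = c(1, 3, 5))), "30 trials")

  # flat curve pinned at the criterion probability: threshold unresolvable
  # within the tested range, flagged not converged
  flat <- data.frame(contrast = exp(seq(log(0.05), log(0.8), length.out = 5)),
                     n = 200)
  flat$n_correct <- round(0.5 * flat$n)
  fit <- fit_psychometric(flat, guess_rate = 0.05)
  expect_false(fit$converged)
})

test_that("deficit map recovers an affected/intact threshold contrast", {
  grid <- expand.grid(ecc_deg = 10, dir_deg = c(-45, 45))
  # lesion-like: the upper location is 3x less sensitive
  pp <- psycho_params(thresholds = c(0.1, 0.3), grid = grid)
  tr <- generate_psychometric_trials(pp, n_per_cell = 100, rng_seed = 5)
  map <- build_deficit_map(tr, grid, neighbor_angle_deg = 90)
  expect_true(all(map$converged))
  ratio <- map$threshold_michelson[map$dir_deg == 45] /
    map$threshold_michelson[map$dir_deg == -45]
  expect_gt(ratio, 3 * 0.7)
  expect_lt(ratio, 3 * 1.3)

  # uniform field: thresholds agree within a tolerant CI
  ppu <- psycho_params(thresholds = 0.2, grid = grid)
  tru <- generate_psychometric_trials(ppu, n_per_cell = 100, rng_seed = 6)
  mapu <- build_deficit_map(tru, grid, neighbor_angle_deg = 90)
  expect_lt(abs(diff(mapu$threshold_michelson)) / 0.2, 0.3)

  # missing cell named in the error
  expect_error(
    build_deficit_map(tr[tr$dir_deg == 45, ], grid, neighbor_angle_deg = 90),
    "ecc 10, dir -45")
})

test_that("threshold recovery error shrinks with trials per contrast", {
  pp <- psycho_params(thresholds = 0.3,
                      grid = data.frame(ecc_deg = 10, dir_deg = 45))
  med_err <- vapply(c(25, 100, 400), function(n_cell) {
    errs <- vapply(1:8, function(s) {
      tr <- generate_psychometric_trials(pp, n_per_cell = n_cell,
                                         rng_seed = 1000 + s)
      agg <- aggregate(tr$responded, by = list(contrast = tr$contrast),
                       FUN = sum)
      nt <- as.integer(table(tr$contrast)[as.character(agg$contrast)])
      fit <- fit_psychometric(data.frame(contrast = agg$contrast, n = nt,
                                         n_correct = agg$x),
                              guess_rate = pp$guess_rate)
      abs(fit$threshold_michelson - 0.3) / 0.3
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) <= 0.02))  # monotone non-increasing (slack)
})
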