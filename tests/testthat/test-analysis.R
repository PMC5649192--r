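make_series <- function(conc, start = 0) {
  data.frame(bin_start_min = start + seq_along(conc) - 1,
             concentration = conc)
}

test_that("baseline statistics are plain mean and sd over the window", {
  s <- make_series(rep(130.6, 20))
  b <- baseline_stats(s, c(0, 15))
  expect_equal(b$mean, 130.6)
  expect_equal(b$sd, 0)
  expect_equal(b$n, 15)
  expect_error(baseline_stats(s, c(100, 115)), "outside")
  expect_error(baseline_stats(make_series(1), c(0, 1)), "at least 2")
  # the reported reference pair round-trips through the report format
  fmt <- sprintf("%.1f +/- %.1f (n = %d)", 130.6, 8.3, 15L)
  expect_match(fmt, "130.6 \\+/- 8.3 \\(n = 15\\)")
})

test_that("baseline mean from synthetic tap water is unbiased", {
  inst <- clean_instrument()
  es <- generate_event_stream(constant_trajectory(130.6, duration_min = 16),
                              inst, population_model(), "SG",
                              duration_min = 15, seed = 31)
  bs <- bin_stream(es, gate_set(), inst)
  b <- baseline_stats(bs, c(0, 15))
  lambda <- expected_events_per_window(130.6, inst, 60000)
  se_mean <- sqrt(lambda / 15) * 2 / 14
  expect_lt(abs(b$mean - 130.6), 3 * se_mean)
})

test_that("onset detection finds the first sustained excursion", {
  flat <- make_series(rep(100, 30))
  b <- baseline_stats(make_series(rnorm(15, 100, 2)), c(0, 15))
  expect_true(is.na(detect_onset(make_series(rep(b$mean, 30)), b)))
  # a +10 sd step at bin 20 with k = 3, min_consecutive = 1
  stepped <- make_series(c(rep(100, 20), rep(100 + 10 * 2, 10)))
  b2 <- structure(list(mean = 100, sd = 2, n = 15, window = c(0, 15)),
                  class = "baseline_stats")
  expect_equal(detect_onset(stepped, b2, k_sigma = 3, min_consecutive = 1),
               20)
  expect_equal(detect_onset(stepped, b2, k_sigma = 3, min_consecutive = 2),
               20)
  # downward excursions are detected too
  dropped <- make_series(c(rep(100, 20), rep(60, 10)))
  expect_equal(detect_onset(dropped, b2, direction = "down"), 20)
  # zero-sd baseline: any deviation triggers
  b0 <- structure(list(mean = 100, sd = 0, n = 15, window = c(0, 15)),
                  class = "baseline_stats")
  tiny <- make_series(c(rep(100, 16), rep(100.01, 14)))
  expect_equal(detect_onset(tiny, b0, min_consecutive = 1), 16)
})

test_that("onset is monotone in the detection threshold", {
  set.seed(11)
  conc <- c(rnorm(15, 100, 3), 100 + cumsum(runif(20, 0, 4)))
  s <- make_series(conc)
  b <- baseline_stats(s, c(0, 15))
  onsets <- sapply(c(1, 2, 3, 5), function(k)
    detect_onset(s, b, k_sigma = k, min_consecutive = 1))
  onsets <- onsets[!is.na(onsets)]
  expect_true(all(diff(onsets) >= 0))
})

test_that("linear rate fit recovers an exact slope", {
  t <- 0:15
  s <- make_series(600 - 10.6 * (t + 0.5))
  fit <- fit_linear_rate(s, c(0, 16))
  expect_equal(fit$slope, -10.6, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit_linear_rate(make_series(rep(5, 10)), c(0, 10))$slope, 0)
  expect_error(fit_linear_rate(make_series(c(1, 2)), c(0, 2)), "at least 3")
})

test_that("washout fit recovers exact and noisy exponentials", {
  t <- 0:34
  exact <- make_series(130.6 + 424 * exp(-0.2 * (t + 0.5)), start = 46)
  fit <- fit_washout(exact, c(46, 81), floor_guess = 120)
  expect_true(fit$converged)
  expect_equal(fit$rate, 0.2, tolerance = 1e-6)
  expect_equal(fit$asymptote, 130.6, tolerance = 1e-4)

  flat <- fit_washout(make_series(rep(130.6, 35), start = 46), c(46, 81))
  expect_false(flat$converged)
  expect_match(flat$message, "unidentifiable")

  # Poisson-noise recovery across a small seed battery (full battery in the
  # acceptance suite)
  inst <- instrument_model()
  truth <- 130.6 + 424 * exp(-0.2 * (t + 0.5))
  for (seed in 1:10) {
    set.seed(seed)
    counts <- rpois(35, expected_events_per_window(truth, inst, 60000))
    noisy <- make_series(concentration_from_count(counts, inst, 60))
    f <- fit_washout(noisy, c(0, 35), floor_guess = 130)
    expect_true(f$converged)
    expect_lt(abs(f$rate - 0.2) / 0.2, 0.2)
  }
})

test_that("derived quantities reproduce the printed arithmetic", {
  expect_equal(round(percent_reduction(383.3, 19.6)), 95)
  expect_equal(percent_reduction(100, 100), 0)
  fi <- fold_increase(679.4, 130.6)
  expect_equal(fi$ratio, 679.4 / 130.6)
  expect_equal(fi$fold, 5)
  expect_equal(fold_increase(383.3, 99.6)$fold, 4)
  expect_equal(volume_changes(0.2, 15), 3)
  expect_error(percent_reduction(0, 1), "> 0")
  expect_error(fold_increase(1, 0), "> 0")
  # scale invariance
  for (c in c(0.1, 3, 1e4)) {
    expect_equal(percent_reduction(383.3 * c, 19.6 * c),
                 percent_reduction(383.3, 19.6))
    expect_equal(fold_increase(679.4 * c, 130.6 * c)$ratio,
                 fold_increase(679.4, 130.6)$ratio)
  }
  d <- derived_quantities(before = 383.3, after = 19.6,
                          peak = 679.4, baseline = 130.6,
                          dilution_rate = 0.2, elapsed = 15)
  expect_named(d, c("percent_reduction", "fold_ratio", "fold",
                    "volume_changes"))
})

test_that("comparison report measures residuals and lag", {
  tr <- predict_tcc_series(experiment_config())
  mid <- 0:79
  meas <- make_series(trajectory_interp(tr, mid + 0.5))
  rep0 <- compare_to_prediction(meas, tr)
  expect_equal(rep0$rmse, 0, tolerance = 1e-12)
  expect_equal(rep0$lag_min, 0)
  expect_equal(rep0$max_abs_residual, 0, tolerance = 1e-12)

  # measured lagging the prediction by one bin shows as a 1-min lag
  lagged <- make_series(trajectory_interp(tr, pmax(mid - 0.5, 0)))
  rep1 <- compare_to_prediction(lagged, tr)
  expect_equal(rep1$lag_min, 1)

  # sign symmetry: measured/predicted swap negates residuals, keeps RMSE
  shifted <- meas
  shifted$concentration <- meas$concentration + rnorm(80, 0, 5)
  ra <- compare_to_prediction(shifted, tr)
  flipped <- make_series(2 * trajectory_interp(tr, mid + 0.5) -
                           shifted$concentration)
  rb <- compare_to_prediction(flipped, tr)
  expect_equal(ra$rmse, rb$rmse, tolerance = 1e-10)
  expect_equal(ra$residuals$residual, -rb$residuals$residual,
               tolerance = 1e-10)

  expect_error(compare_to_prediction(make_series(1:3, start = 500), tr),
               "overlap")
})
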