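test_that("expected event rate links concentration to counts", {
  inst <- instrument_model()
  # 130.6 cells/ul, 1:2 stain dilution, 14 ul/min, 100 ms window
  expect_equal(expected_events_per_window(130.6, inst, 100),
               130.6 / 2 * 14 / 60000 * 100)
  expect_equal(expected_events_per_window(0, inst, 100), 0)
  expect_equal(expected_events_per_window(130.6, inst, 60000),
               600 * expected_events_per_window(130.6, inst, 100))
  expect_error(expected_events_per_window(-1, inst, 100), ">= 0")
})

test_that("event streams are reproducible, sorted, and Poisson in count", {
  tr <- constant_trajectory(130.6, duration_min = 16)
  inst <- clean_instrument()
  s1 <- generate_event_stream(tr, inst, population_model(), "SG",
                              duration_min = 15, seed = 7)
  s2 <- generate_event_stream(tr, inst, population_model(), "SG",
                              duration_min = 15, seed = 7)
  expect_identical(s1$events, s2$events)
  expect_false(is.unsorted(s1$events$time_ms))
  expect_true(all(s1$events$fl1 > 0 & s1$events$fl3 > 0))

  # total count within 3 Poisson standard deviations of 15 x ~914
  lambda <- expected_events_per_window(130.6, inst, 60000) * 15
  expect_lt(abs(nrow(s1$events) - lambda), 3 * sqrt(lambda))

  # per-window dispersion consistent with a Poisson process
  counts <- table(factor(floor(s1$events$time_ms / 100), levels = 0:8999))
  expect_equal(mean(counts), lambda / 9000, tolerance = 0.05)
  dispersion <- stats::var(as.numeric(counts)) / mean(counts)
  expect_gt(dispersion, 0.9)
  expect_lt(dispersion, 1.1)
})

test_that("degenerate generator inputs behave", {
  inst <- clean_instrument()
  empty <- generate_event_stream(constant_trajectory(0, icc = 0), inst,
                                 population_model(), "SG",
                                 duration_min = 5, seed = 1)
  expect_equal(nrow(empty$events), 0)
  expect_error(
    generate_event_stream(constant_trajectory(100, duration_min = 5),
                          instrument_model(), population_model(), "SG",
                          duration_min = 20, seed = 1),
    "shorter")
  expect_error(
    generate_event_stream(constant_trajectory(100), instrument_model(),
                          population_model(), "SG", duration_min = 15),
    "seed")
})

test_that("fluorescence clusters are ordered as configured", {
  pops <- population_model()
  lna <- sample_fluorescence(pops, "lna", "SG", 1e4, seed = 3)
  hna <- sample_fluorescence(pops, "hna", "SG", 1e4, seed = 4)
  expect_lt(median(lna$fl1), median(hna$fl1))
  # PI-positive (damaged) cells sit above intact cells on the red channel
  dam <- sample_fluorescence(pops, "damaged", "SG+PI", 1e4, seed = 5)
  intact <- rbind(sample_fluorescence(pops, "lna", "SG+PI", 5e3, seed = 6),
                  sample_fluorescence(pops, "hna", "SG+PI", 5e3, seed = 7))
  expect_gt(median(dam$fl3), median(intact$fl3))
  expect_equal(nrow(sample_fluorescence(pops, "lna", "SG", 0)), 0)
  expect_error(sample_fluorescence(pops, "algae", "SG", 10), "unknown")
  expect_error(sample_fluorescence(pops, "damaged", "SG", 10), "unknown")
})

test_that("staining delay shifts the measured signal in time", {
  # step trajectory: concentration doubles at minute 5; with a 2-min delay
  # the acquired stream must step at minute 7
  tt <- 0:20
  tr <- constant_trajectory(100, duration_min = 20)
  tr$tcc <- ifelse(tt < 5, 100, 200)
  tr$icc <- tr$tcc
  inst <- instrument_model(background_event_rate = 0, staining_delay_min = 2)
  es <- generate_event_stream(tr, inst, population_model(), "SG",
                              duration_min = 12, seed = 9)
  counts <- table(factor(floor(es$events$time_ms / 60000), levels = 0:11))
  early <- mean(counts[1:6])   # acquisition minutes 0-5 see the old level
  late <- mean(counts[9:12])
  expect_equal(unname(late / early), 2, tolerance = 0.15)
})
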