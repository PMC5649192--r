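# one full default replay shared by the structural tests in this file
replay_dir <- file.path(tempdir(), "replay-test")
replay <- run_replay(seed = 1, out_dir = replay_dir)

test_that("replay produces the full set of artifacts with a manifest", {
  files <- replay$manifest$files
  expect_setequal(
    files$stage,
    c("trajectory", "prediction", "events_sg", "events_sgpi", "binned_tcc",
      "binned_icc", "comparison", "analysis", "meta_sg", "meta_sgpi"))
  expect_true(all(file.exists(file.path(replay_dir, files$path))))
  expect_true(all(nchar(files$md5) == 32))
  expect_equal(attr(replay$tcc_series, "staining_mode"), "SG")
  expect_equal(attr(replay$icc_series, "staining_mode"), "SG+PI")
})

test_that("replay is deterministic under a fixed seed", {
  again <- run_replay(seed = 1, out_dir = file.path(tempdir(), "replay-b"))
  expect_equal(replay$manifest$files$md5, again$manifest$files$md5)
  other <- run_replay(seed = 99, out_dir = file.path(tempdir(), "replay-c"))
  expect_false(all(replay$manifest$files$md5 == other$manifest$files$md5))
})

test_that("replay recovers the experiment's headline dynamics", {
  a <- replay$analysis
  # baseline near the configured tap water values
  expect_equal(a$tcc_baseline_mean, 130.6, tolerance = 0.03)
  expect_equal(a$icc_baseline_mean, 99.6, tolerance = 0.03)
  expect_equal(a$baseline_n, 15)
  # contamination onset within 2 bins of reactor minute 16
  expect_lt(abs(a$tcc_onset_min - 16), 2.5)
  # ICC collapse below 30 cells/ul within 4 min of chlorine arrival
  expect_lte(a$icc_collapse_min, 34)
  # chlorination TCC decline near the configured empirical rate
  expect_equal(a$tcc_chlorination_slope, -10.6, tolerance = 0.25)
  # washout rate near the dilution rate
  expect_true(a$washout_converged)
  expect_equal(a$washout_rate, 0.2, tolerance = 0.2 * 0.2)
  expect_equal(a$comparison_lag_min, 0)
})
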