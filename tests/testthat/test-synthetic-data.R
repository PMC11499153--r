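# Generators: deterministic under a seed, ground truth consistent with
# the forward models they wrap.

test_that("noiseless voltage traces invert exactly to the forward model", {
  cal <- IsmCalibration(v0 = 10, slope = 58)
  cfg <- curveSimConfig(noise_sigma_rel = 0, drift_mV_per_min = 0,
                        seed = 5)
  sim <- simulateDiffusionTrace(cfg, cal)
  back <- voltageToConcentration(sim$voltage_mV, cal)
  expect_equal(back, curveConc(sim$truth), tolerance = 1e-9)
})

test_that("the same seed reproduces the identical trace", {
  cfg <- curveSimConfig(noise_sigma_rel = 0.05, seed = 17)
  s1 <- simulateDiffusionTrace(cfg)
  s2 <- simulateDiffusionTrace(cfg)
  expect_identical(s1$voltage_mV, s2$voltage_mV)
  s3 <- simulateDiffusionTrace(curveSimConfig(noise_sigma_rel = 0.05,
                                              seed = 18))
  expect_false(identical(s1$voltage_mV, s3$voltage_mV))
})

test_that("phantom voxel count follows the programmed volume within 3%", {
  sim <- simulateCellSeries(smallCellConfig(seed = 2))
  rel <- sim$soma_voxels / sim$soma_voxels[2]
  expect_lt(max(abs(rel / (sim$truth@vol_pct / 100) - 1)), 0.03)
})

test_that("a static phantom measures ~100% at every timepoint", {
  cfg <- cellSimConfig(field_px = c(64, 64), n_slices = 18,
                       soma_axes_um = c(5, 4.5, 3.5),
                       volume_profile_pct = c(100, 100, 100, 100),
                       timepoints_min = c(-5, 0, 5, 10),
                       n_baseline = 2L, snr = 1e4, read_noise_sd = 0,
                       bleach_per_stack = 0, drift_px_per_frame = c(0, 0),
                       seed = 1)
  sim <- simulateCellSeries(cfg)
  # with no programmed bleach the baseline slope's sign is chance, so the
  # capping warning may or may not fire; it is not what this test checks
  vt <- suppressWarnings(
    analyzeCellSeries(sim$its, seed_point = round(sim$center_px[2, ])))
  expect_lt(max(abs(volPercent(vt) - 100)), 2)
})

test_that("same cell seed reproduces stacks; bleaching scales raw trend", {
  c1 <- smallCellConfig(seed = 6)
  s1 <- simulateCellSeries(c1)
  s2 <- simulateCellSeries(c1)
  expect_identical(s1$its@stacks[[1]], s2$its@stacks[[1]])
  # doubling the bleach rate steepens the raw intensity decline
  trend <- function(b) {
    sim <- simulateCellSeries(smallCellConfig(seed = 6,
                                              bleach_per_stack = b))
    tot <- vapply(sim$its@stacks, sum, 0)
    coef(lm(tot ~ seq_along(tot)))[2]
  }
  t1 <- trend(0.02); t2 <- trend(0.04)
  expect_lt(t2, t1)   # both negative, the faster bleach more so
})

test_that("calibration generator feeds the fit and flags bad grids", {
  truth <- IsmCalibration(v0 = -4, slope = 59, interference = 0.05)
  ser <- simulateCalibration(truth, noise_mV = 0)
  fit <- fitCalibration(ser)
  expect_lt(abs(fit@slope - 59), 1e-6)
  one <- simulateCalibration(truth, noise_mV = 0, concentrations_mM = 1)
  expect_error(fitCalibration(one), "4 points")
})

test_that("config validation rejects impossible phantoms", {
  expect_error(cellSimConfig(soma_axes_um = c(30, 30, 4),
                             field_px = c(64, 64)), "larger than the field")
  expect_error(cellSimConfig(volume_profile_pct = c(100, 100, 150, 100),
                             timepoints_min = c(-5, 0, 5, 10),
                             n_baseline = 3L), "exactly 100")
})
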