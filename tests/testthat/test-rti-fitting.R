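# Inverse fitting: agar calibration of (n, D), tissue fits of
# (alpha, lambda, k'), and the voltage-trace preprocessing.

test_that("agar fit recovers (n, D) from a clean curve within 0.5%", {
  cfg <- stdSource()
  truth <- freeMediumParams(D = 1.2e-5, n_transport = 0.35)
  curve <- pulseCurve(stdGrid(), cfg, truth, medium = "agar")
  fit <- fitAgar(curve)
  expect_true(isConverged(fit))
  expect_lt(abs(transportNumber(fit) / 0.35 - 1), 0.005)
  expect_lt(abs(freeDiffusion(fit) / 1.2e-5 - 1), 0.005)
})

test_that("agar fit tolerates 2% multiplicative noise within 5%", {
  cfg <- stdSource()
  truth <- freeMediumParams(D = 1.2e-5, n_transport = 0.35)
  clean <- pulseCurve(stdGrid(), cfg, truth, medium = "agar")
  set.seed(21)
  noisy <- DiffusionCurve(curveTimes(clean),
                          pmax(curveConc(clean) *
                                 (1 + rnorm(length(curveConc(clean)),
                                            0, 0.02)), 0),
                          source = cfg, medium = "agar")
  fit <- fitAgar(noisy)
  expect_lt(abs(transportNumber(fit) / 0.35 - 1), 0.05)
  expect_lt(abs(freeDiffusion(fit) / 1.2e-5 - 1), 0.05)
})

test_that("a flat curve yields converged = FALSE", {
  cfg <- stdSource(c_baseline_mM = 0)
  flat <- DiffusionCurve(stdGrid(), rep(0, length(stdGrid())),
                         source = cfg, medium = "agar", baseline_mM = 0)
  fit <- fitAgar(flat)
  expect_false(isConverged(fit))
  curve <- DiffusionCurve(stdGrid()[stdGrid() > 5],
                          rep(0.1, sum(stdGrid() > 5)), source = stdSource())
  expect_error(fitAgar(curve), "agar")
})

test_that("tissue fit recovers (alpha, lambda, k') within 1% noiseless", {
  cfg <- stdSource()
  truth <- stdTissueParams()
  curve <- pulseCurve(stdGrid(), cfg, truth)
  fit <- fitTissue(curve, n_transport = 0.3, D = 1.2e-5)
  expect_true(isConverged(fit))
  expect_lt(abs(volumeFraction(fit) / 0.19 - 1), 0.01)
  expect_lt(abs(tortuosity(fit) / 1.6 - 1), 0.01)
  expect_lt(abs(uptakeRate(fit) / 5e-3 - 1), 0.01)
  # the optimizer never beats the generating parameters on clean data
  sse_truth <- sum((curveConc(curve) - curveConc(
    pulseCurve(curveTimes(curve), cfg, truth)))^2)
  expect_lte(sse_truth, fitSSE(fit) + 1e-9)
})

test_that("a free-medium curve fitted in tissue mode pins the bounds", {
  cfg <- stdSource()
  free <- freeMediumParams(D = 1.2e-5, n_transport = 0.3)
  curve <- pulseCurve(stdGrid(), cfg, free, medium = "tissue")
  fit <- fitTissue(curve, n_transport = 0.3, D = 1.2e-5)
  expect_gt(volumeFraction(fit), 0.99)
  expect_lt(tortuosity(fit), 1.01)
  expect_lt(uptakeRate(fit), 1e-4)
  expect_true(any(fit@diagnostics$bound_flags))
})

test_that("fits are invariant to time-grid resampling", {
  cfg <- stdSource()
  truth <- stdTissueParams()
  f10 <- fitTissue(pulseCurve(stdGrid(10), cfg, truth), 0.3, 1.2e-5)
  f2 <- fitTissue(pulseCurve(stdGrid(2), cfg, truth), 0.3, 1.2e-5)
  expect_lt(abs(volumeFraction(f2) / volumeFraction(f10) - 1), 0.005)
  expect_lt(abs(tortuosity(f2) / tortuosity(f10) - 1), 0.005)
})

test_that("noisy replicates keep median alpha and lambda errors <= 5%", {
  errs <- vapply(1:15, function(s) {
    fit <- noisyTissueFit(seed = s)
    c(abs(volumeFraction(fit) / 0.19 - 1), abs(tortuosity(fit) / 1.6 - 1))
  }, numeric(2))
  expect_lt(median(errs[1, ]), 0.05)
  expect_lt(median(errs[2, ]), 0.05)
})

test_that("agar-calibration error propagates modestly into tissue fits", {
  cfg <- stdSource()
  agar_truth <- freeMediumParams(D = 1.2e-5, n_transport = 0.3)
  tissue_truth <- stdTissueParams()
  clean_agar <- pulseCurve(stdGrid(), cfg, agar_truth, medium = "agar")
  alpha_err <- vapply(1:5, function(s) {
    set.seed(100 + s)
    noisy <- DiffusionCurve(curveTimes(clean_agar),
                            pmax(curveConc(clean_agar) *
                                   (1 + rnorm(length(stdGrid()), 0, 0.02)),
                                 0), source = cfg, medium = "agar")
    el <- fitAgar(noisy)
    tf <- fitTissue(pulseCurve(stdGrid(), cfg, tissue_truth),
                    n_transport = transportNumber(el),
                    D = freeDiffusion(el))
    abs(volumeFraction(tf) / 0.19 - 1)
  }, 0)
  expect_lt(median(alpha_err), 0.15)
})

test_that("preprocessCurve converts, baselines and validates traces", {
  cal <- IsmCalibration(v0 = 10, slope = 58)
  cfg <- stdSource()
  t <- stdGrid()
  # constant pre-pulse voltage at 0.1 mM maps to a 0.1 mM baseline
  v <- rep(nikolskiVoltage(0.1, cal), length(t))
  cv <- preprocessCurve(v, t, cal, cfg)
  expect_equal(curveBaseline(cv), 0.1, tolerance = 1e-12)
  # full round trip: simulated voltage trace -> curve -> recovered params
  fit <- noisyTissueFit(seed = 7)
  expect_true(isConverged(fit))
  expect_lt(abs(volumeFraction(fit) / 0.19 - 1), 0.10)
  # a trace starting mid-pulse has no baseline window
  expect_error(preprocessCurve(v[t > 5], t[t > 5], cal, cfg), "baseline")
})
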