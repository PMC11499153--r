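# Forward model: source rate, point-source solution, pulse superposition.

test_that("source rate follows Q = I n / (z F) and is linear in current", {
  cfg <- SourceConfig(i_step_nA = 200, i_bias_nA = 0)
  expect_equal(sourceRate(cfg, n_transport = 0.5),
               200e-9 * 0.5 / 96485, tolerance = 1e-12)
  expect_equal(sourceRate(cfg, n_transport = 0), 0)
  cfg2 <- SourceConfig(i_step_nA = 200, i_bias_nA = 20)
  expect_equal(sourceRate(cfg2, 0.4, use_step_only = TRUE) /
                 sourceRate(cfg2, 0.4, use_step_only = FALSE),
               180 / 200)
  expect_error(SourceConfig(i_step_nA = 10, i_bias_nA = 20), "i_step")
  expect_error(sourceRate(cfg, n_transport = 1.5), "transport")
})

test_that("free-medium reduction matches the erfc closed form", {
  Q <- 1.2e-12
  D <- 1.2e-5
  p <- freeMediumParams(D = D)
  rs <- umToCm(seq(30, 200, length.out = 10))
  ts <- seq(0.5, 120, length.out = 10)
  for (r in rs) {
    got <- concentrationOn(r, ts, Q, p)
    want <- freeMediumConc(r, ts, Q, D)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # zero released at t = 0
  expect_identical(concentrationOn(umToCm(100), 0, Q, p), 0)
  # steady state Q/(4 pi D r)
  expect_equal(steadyState(umToCm(100), Q, p),
               Q / (4 * pi * D * umToCm(100)), tolerance = 1e-12)
})

test_that("tissue model matches the radial finite-difference solver", {
  set.seed(11)
  for (i in 1:3) {
    p <- DiffusionParams(alpha = runif(1, 0.08, 0.5),
                         lam = runif(1, 1, 2.2),
                         kprime = runif(1, 0, 0.02),
                         D = runif(1, 0.8e-5, 1.6e-5))
    r <- umToCm(runif(1, 50, 150))
    ts <- sort(runif(4, 1, 72))
    Q <- 1e-12
    fd <- solveRadialDiffusionFD(r, ts, Q, p)[, 1]
    cf <- concentrationOn(r, ts, Q, p)
    expect_lt(max(abs(fd / cf - 1)), 0.01)
  }
})

test_that("concentration is monotone in t, r, k' and alpha", {
  Q <- 1e-12
  r <- umToCm(80)
  ts <- seq(1, 60, by = 1)
  p <- DiffusionParams(0.2, 1.6, 5e-3)
  expect_true(all(diff(concentrationOn(r, ts, Q, p)) > 0))
  rs <- umToCm(seq(40, 160, by = 10))
  byR <- vapply(rs, function(rr) concentrationOn(rr, 24, Q, p), 0)
  expect_true(all(diff(byR) < 0))
  ks <- seq(0, 0.05, by = 0.005)
  byK <- vapply(ks, function(k)
    concentrationOn(r, 24, Q, DiffusionParams(0.2, 1.6, k)), 0)
  expect_true(all(diff(byK) < 0))
  as <- seq(0.05, 1, by = 0.05)
  byA <- vapply(as, function(a)
    concentrationOn(r, 24, Q, DiffusionParams(a, 1.6, 5e-3)), 0)
  expect_true(all(diff(byA) < 0))
})

test_that("pulse response superposes, is continuous and decays fully", {
  cfg <- SourceConfig()
  p <- stdTissueParams()
  Q <- sourceRate(cfg, p@n_transport)
  dur <- cfg@duration_s
  # exact superposition identity at t > dur
  ts <- seq(dur + 0.1, 3 * dur, by = 1.7)
  lhs <- concentrationPulse(t = ts, cfg = cfg, p = p) +
    concentrationOn(cfg@r, ts - dur, Q, p)
  rhs <- cfg@c_baseline + concentrationOn(cfg@r, ts, Q, p)
  expect_equal(lhs, rhs, tolerance = 1e-14)
  # continuity at the pulse end
  eps <- 1e-6
  expect_equal(concentrationPulse(t = dur - eps, cfg = cfg, p = p),
               concentrationPulse(t = dur + eps, cfg = cfg, p = p),
               tolerance = 1e-6)
  # long after the pulse only the baseline remains
  expect_equal(concentrationPulse(t = 1e7, cfg = cfg, p = p),
               cfg@c_baseline, tolerance = 1e-12 * cfg@c_baseline)
  # free medium, t = 2 dur: difference of two erfc terms, by hand
  pf <- freeMediumParams(D = 1.2e-5, n_transport = 0.3)
  Qf <- sourceRate(cfg, 0.3)
  t2 <- 2 * dur
  hand <- Qf / (4 * pi * pf@D * cfg@r) *
    (pracma::erfc(cfg@r / (2 * sqrt(pf@D * t2))) -
     pracma::erfc(cfg@r / (2 * sqrt(pf@D * (t2 - dur)))))
  expect_equal(concentrationPulse(t = t2, cfg = cfg, p = pf) -
                 cfg@c_baseline, hand, tolerance = 1e-12)
})

test_that("steady state is the large-time limit and scales as 1/r", {
  p <- DiffusionParams(0.19, 1.6, 5e-3)
  Q <- 1e-12
  r <- umToCm(100)
  expect_equal(concentrationOn(r, 1e6, Q, p), steadyState(r, Q, p),
               tolerance = 1e-6)
  p0 <- DiffusionParams(0.19, 1.6, 0)
  expect_equal(steadyState(2 * r, Q, p0) / steadyState(r, Q, p0), 0.5,
               tolerance = 1e-12)
  expect_equal(steadyState(r, Q, p0),
               Q * p0@lam^2 / (4 * pi * p0@D * p0@alpha * r),
               tolerance = 1e-12)
})

test_that("inadmissible inputs are rejected and outputs stay finite", {
  p <- DiffusionParams(0.19, 1.6, 5e-3)
  expect_error(concentrationOn(0, 1, 1e-12, p), "unphysical")
  expect_error(concentrationOn(umToCm(0.5), 1, 1e-12, p), "unphysical")
  expect_error(concentrationOn(umToCm(100), -1, 1e-12, p), ">= 0")
  expect_error(DiffusionParams(0, 1.6, 0), "alpha")
  expect_error(DiffusionParams(0.2, 0.9, 0), "lam")
  # strong-uptake regime that overflows a naive exp * erfc product
  px <- DiffusionParams(0.05, 3, 0.1, D = 5e-6)
  v <- concentrationOn(umToCm(150), c(0.01, 0.1, 1, 10, 1e4), 1e-12, px)
  expect_true(all(is.finite(v)) && all(v >= 0))
  expect_equal(v[5], steadyState(umToCm(150), 1e-12, px), tolerance = 1e-9)
})
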