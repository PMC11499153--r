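# Shared fixture builders. Curves use the standard protocol (200 nA /
# 24 s step on a 20 nA bias, 0.1 mM background, r = 100 um) unless a test
# says otherwise.

stdSource <- function(...) SourceConfig(...)

stdTissueParams <- function(n_transport = 0.3)
  DiffusionParams(alpha = 0.19, lam = 1.6, kprime = 5e-3, D = 1.2e-5,
                  n_transport = n_transport)

stdGrid <- function(rate_hz = 10) seq(-10, 72, by = 1 / rate_hz)

# one noisy tissue fit through the full voltage pipeline; returns the
# fitted FitResult and the generating params
noisyTissueFit <- function(seed, noise = 0.02,
                           params = stdTissueParams(),
                           cal = IsmCalibration(v0 = 10, slope = 58)) {
  cfg <- curveSimConfig(params_true = params, noise_sigma_rel = noise,
                        seed = seed)
  sim <- simulateDiffusionTrace(cfg, cal)
  curve <- preprocessCurve(sim$voltage_mV, sim$times_s, cal,
                           cfg$source, medium = "tissue")
  fitTissue(curve, n_transport = params@n_transport, D = params@D)
}

# small, fast phantom (fewer slices and timepoints than the full protocol)
smallCellConfig <- function(...) {
  cellSimConfig(field_px = c(64, 64), n_slices = 20,
                soma_axes_um = c(5, 4.5, 3.5),
                volume_profile_pct = c(100, 100, 180, 100),
                timepoints_min = c(-5, 0, 5, 25),
                n_baseline = 2L, ...)
}
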