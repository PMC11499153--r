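## Synthetic RTI inputs with known ground truth: diffusion voltage traces
## and ISM calibration series.

#' Configuration for a simulated diffusion trace
#'
#' Defaults reproduce the standard recording conditions: a 200 nA / 24 s
#' step on a 20 nA bias, 0.1 mM TMA+ background, 100 um separation,
#' tissue parameters in the grey-matter regime (alpha = 0.19,
#' lambda = 1.6, k' = 5e-3 1/s), 10 Hz sampling, 10 s of pre-pulse
#' baseline and a decay window of two pulse durations.
#'
#' @param params_true generating \code{\linkS4class{DiffusionParams}}.
#' @param source generating \code{\linkS4class{SourceConfig}}.
#' @param sample_rate_hz sampling rate of the trace.
#' @param noise_sigma_rel relative sd of the multiplicative Gaussian noise
#'   applied to the concentration signal (electrode noise scales with the
#'   signal).
#' @param drift_mV_per_min linear baseline drift added to the voltage.
#' @param baseline_s pre-pulse baseline duration, s (>= 5 s needed by
#'   \code{\link{preprocessCurve}}).
#' @param decay_mult recorded post-pulse decay, in pulse durations.
#' @param seed RNG seed; the same seed yields the identical trace.
#' @return a validated config (classed list \code{"CurveSimConfig"}).
#' @export
curveSimConfig <- function(params_true = DiffusionParams(
                             alpha = 0.19, lam = 1.6, kprime = 5e-3,
                             D = 1.2e-5, n_transport = 0.3),
                           source = SourceConfig(),
                           sample_rate_hz = 10,
                           noise_sigma_rel = 0.02,
                           drift_mV_per_min = 0,
                           baseline_s = 10,
                           decay_mult = 2,
                           seed = 1L) {
  stopifnot(is(params_true, "DiffusionParams"), is(source, "SourceConfig"),
            sample_rate_hz > 0, noise_sigma_rel >= 0, baseline_s >= 5)
  structure(list(params_true = params_true, source = source,
                 sample_rate_hz = sample_rate_hz,
                 noise_sigma_rel = noise_sigma_rel,
                 drift_mV_per_min = drift_mV_per_min,
                 baseline_s = baseline_s, decay_mult = decay_mult,
                 seed = as.integer(seed)),
            class = "CurveSimConfig")
}

#' Simulate one raw ISM voltage trace
#'
#' Evaluates the pulse forward model on the configured time grid,
#' applies multiplicative Gaussian noise to the concentration, converts to
#' voltage through the Nikolski transfer function and adds linear drift.
#' The noiseless ground-truth curve is returned alongside so every
#' downstream stage has an oracle.
#'
#' @param cfg a \code{\link{curveSimConfig}}.
#' @param cal the \code{\linkS4class{IsmCalibration}} used to voltage-encode
#'   the trace.
#' @return list with \code{times_s}, \code{voltage_mV} (the noisy raw
#'   trace), \code{truth} (noiseless \code{\linkS4class{DiffusionCurve}}),
#'   \code{params_true} and \code{config}.
#' @examples
#' sim <- simulateDiffusionTrace(curveSimConfig(seed = 42))
#' curve <- preprocessCurve(sim$voltage_mV, sim$times_s,
#'                          IsmCalibration(v0 = 10, slope = 58),
#'                          sim$config$source)
#' @export
simulateDiffusionTrace <- function(cfg,
                                   cal = IsmCalibration(v0 = 10,
                                                        slope = 58)) {
  stopifnot(inherits(cfg, "CurveSimConfig"), is(cal, "IsmCalibration"))
  dur <- cfg$source@duration_s
  t <- seq(-cfg$baseline_s, (1 + cfg$decay_mult) * dur,
           by = 1 / cfg$sample_rate_hz)
  truth <- pulseCurve(t, cfg$source, cfg$params_true, medium = "tissue")
  conc <- curveConc(truth)
  noisy <- withr::with_seed(cfg$seed, {
    c_n <- conc * (1 + rnorm(length(conc), 0, cfg$noise_sigma_rel))
    pmax(c_n, 1e-6)   # keep the log argument positive
  })
  v <- nikolskiVoltage(noisy, cal) + cfg$drift_mV_per_min * t / 60
  list(times_s = t, voltage_mV = v, truth = truth,
       params_true = cfg$params_true, config = cfg)
}

#' Simulate an ISM calibration series
#'
#' Nikolski voltages on the standard five-solution grid (0.1, 0.3, 1, 3,
#' 10 mM) plus Gaussian measurement noise.
#'
#' @param cal_true generating \code{\linkS4class{IsmCalibration}}.
#' @param noise_mV sd of the additive voltage noise, mV.
#' @param seed RNG seed.
#' @param concentrations_mM calibration solutions, mM.
#' @return data.frame with columns \code{concentration_mM},
#'   \code{voltage_mV}.
#' @examples
#' ser <- simulateCalibration(IsmCalibration(10, 58, 0.08), noise_mV = 0)
#' fitCalibration(ser)
#' @export
simulateCalibration <- function(cal_true, noise_mV = 0.2, seed = 1L,
                                concentrations_mM = c(0.1, 0.3, 1, 3, 10)) {
  stopifnot(is(cal_true, "IsmCalibration"), noise_mV >= 0)
  v <- nikolskiVoltage(concentrations_mM, cal_true)
  if (noise_mV > 0)
    v <- withr::with_seed(seed, v + rnorm(length(v), 0, noise_mV))
  data.frame(concentration_mM = concentrations_mM, voltage_mV = v)
}
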