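## S4 classes for the RTI diffusion assay and the confocal morphometry assay.

#' DiffusionParams: physical unknowns of one RTI measurement
#'
#' Holds the extracellular-space (ECS) diffusion parameters of one recording
#' site together with the electrode constants calibrated in dilute agar.
#'
#' @slot alpha ECS volume fraction (ECS volume / total tissue volume),
#'   dimensionless in (0, 1]. Free medium: 1.
#' @slot lam tortuosity \eqn{\lambda} (\eqn{\lambda^2} = free / apparent
#'   diffusion coefficient), dimensionless, >= 1. Free medium: 1.
#' @slot kprime non-specific uptake rate \eqn{k'}, 1/s, >= 0.
#' @slot D free diffusion coefficient of the tracer, cm^2/s, > 0.
#' @slot n_transport electrode transport number (fraction of iontophoretic
#'   current carried by the tracer ion), dimensionless in (0, 1].
#'
#' @seealso \code{\link{freeMediumParams}}, \code{\link{concentrationOn}}
#' @export
setClass("DiffusionParams", representation(
  alpha = "numeric", lam = "numeric", kprime = "numeric",
  D = "numeric", n_transport = "numeric"
))

setValidity("DiffusionParams", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!one(object@alpha) || object@alpha <= 0 || object@alpha > 1)
    msg <- c(msg, "alpha must be a single value in (0, 1]")
  if (!one(object@lam) || object@lam < 1)
    msg <- c(msg, "lam must be a single value >= 1")
  if (!one(object@kprime) || object@kprime < 0)
    msg <- c(msg, "kprime must be a single value >= 0")
  if (!one(object@D) || object@D <= 0)
    msg <- c(msg, "D must be a single value > 0")
  if (!one(object@n_transport) || object@n_transport <= 0 ||
      object@n_transport > 1)
    msg <- c(msg, "n_transport must be a single value in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct DiffusionParams
#'
#' @param alpha ECS volume fraction in (0, 1].
#' @param lam tortuosity, >= 1.
#' @param kprime non-specific uptake rate, 1/s.
#' @param D free diffusion coefficient, cm^2/s. The default 1.2e-5 cm^2/s
#'   is a typical room-temperature value for TMA+.
#' @param n_transport electrode transport number in (0, 1].
#' @return a \code{DiffusionParams} object.
#' @examples
#' DiffusionParams(alpha = 0.19, lam = 1.6, kprime = 5e-3)
#' @export
DiffusionParams <- function(alpha, lam, kprime = 0, D = 1.2e-5,
                            n_transport = 0.3) {
  new("DiffusionParams", alpha = as.numeric(alpha), lam = as.numeric(lam),
      kprime = as.numeric(kprime), D = as.numeric(D),
      n_transport = as.numeric(n_transport))
}

#' Free-medium diffusion parameters
#'
#' In a free medium (dilute agar) there is no tortuosity, no ECS
#' restriction and no uptake: alpha = 1, lambda = 1, k' = 0 exactly.
#'
#' @param D free diffusion coefficient, cm^2/s.
#' @param n_transport electrode transport number.
#' @return a \code{DiffusionParams} object describing a free medium.
#' @export
freeMediumParams <- function(D = 1.2e-5, n_transport = 0.3) {
  DiffusionParams(alpha = 1, lam = 1, kprime = 0, D = D,
                  n_transport = n_transport)
}

#' SourceConfig: iontophoresis source and recording geometry
#'
#' Describes the current protocol of the iontophoretic micropipette and the
#' geometry of the electrode array. Stored internally in SI-like units
#' (A, s, cm, mol/cm^3); the constructor accepts nA, um and mM.
#'
#' @slot i_step step current amplitude, A.
#' @slot i_bias continuously applied bias current, A.
#' @slot duration_s duration of the current step, s.
#' @slot r source-sensor tip separation, cm.
#' @slot z_valence ion charge number (TMA+: +1).
#' @slot faraday Faraday constant, C/mol.
#' @slot c_baseline background tracer concentration, mol/cm^3.
#' @export
setClass("SourceConfig", representation(
  i_step = "numeric", i_bias = "numeric", duration_s = "numeric",
  r = "numeric", z_valence = "numeric", faraday = "numeric",
  c_baseline = "numeric"
))

setValidity("SourceConfig", function(object) {
  msg <- character()
  if (!(object@i_step > object@i_bias) || object@i_bias < 0)
    msg <- c(msg, "need i_step > i_bias >= 0")
  if (object@duration_s <= 0) msg <- c(msg, "duration_s must be > 0")
  ## tips closer than 1 um are unphysical for a 50-100 um array
  if (object@r < 1e-4)
    msg <- c(msg, "source-sensor separation below 1 um is rejected")
  if (object@z_valence < 1) msg <- c(msg, "z_valence must be >= 1")
  if (object@c_baseline < 0) msg <- c(msg, "c_baseline must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SourceConfig
#'
#' Defaults follow the standard RTI protocol: a 200 nA / 24 s current step
#' on a continuously applied 20 nA bias, 0.1 mM TMA+ background, and a
#' 100 um tip separation (protocol range 50--100 um).
#'
#' @param i_step_nA step current amplitude, nA.
#' @param i_bias_nA bias current, nA.
#' @param duration_s step duration, s.
#' @param r_um source-sensor separation, um.
#' @param z_valence ion charge number.
#' @param c_baseline_mM background tracer concentration, mM.
#' @param faraday Faraday constant, C/mol.
#' @return a \code{SourceConfig} object.
#' @examples
#' SourceConfig()                 # the standard protocol
#' SourceConfig(r_um = 50)        # closer electrode pair
#' @export
SourceConfig <- function(i_step_nA = 200, i_bias_nA = 20, duration_s = 24,
                         r_um = 100, z_valence = 1, c_baseline_mM = 0.1,
                         faraday = .FARADAY) {
  new("SourceConfig",
      i_step = nAToA(i_step_nA), i_bias = nAToA(i_bias_nA),
      duration_s = as.numeric(duration_s), r = umToCm(r_um),
      z_valence = as.numeric(z_valence), faraday = as.numeric(faraday),
      c_baseline = mMToMolPerCm3(c_baseline_mM))
}

#' DiffusionCurve: one recorded (or simulated) TMA+ transient
#'
#' A sampled concentration-versus-time record around one current step,
#' spanning pre-pulse baseline, pulse and decay. Concentrations are stored
#' in mM, the unit in which curves are fitted.
#'
#' @slot t time grid, s, strictly increasing. The pulse switches on at
#'   \code{onset_s}.
#' @slot conc_mM concentration, mM, >= 0, including the baseline.
#' @slot source the \code{\linkS4class{SourceConfig}} of the recording.
#' @slot medium \code{"agar"} or \code{"tissue"}.
#' @slot baseline_mM estimated pre-pulse baseline concentration, mM.
#' @slot onset_s pulse onset time on the \code{t} axis, s.
#' @export
setClass("DiffusionCurve", representation(
  t = "numeric", conc_mM = "numeric", source = "SourceConfig",
  medium = "character", baseline_mM = "numeric", onset_s = "numeric"
))

setValidity("DiffusionCurve", function(object) {
  msg <- character()
  if (length(object@t) != length(object@conc_mM))
    msg <- c(msg, "t and conc_mM must have equal length")
  if (length(object@t) > 1 && any(diff(object@t) <= 0))
    msg <- c(msg, "t must be strictly increasing")
  if (any(object@conc_mM < 0)) msg <- c(msg, "concentrations must be >= 0")
  if (!object@medium %in% c("agar", "tissue"))
    msg <- c(msg, "medium must be 'agar' or 'tissue'")
  if (length(msg)) msg else TRUE
})

#' Construct a DiffusionCurve
#'
#' @param t time grid, s.
#' @param conc_mM concentration, mM.
#' @param source a \code{\linkS4class{SourceConfig}}.
#' @param medium \code{"agar"} or \code{"tissue"}.
#' @param baseline_mM pre-pulse baseline, mM; defaults to the source's
#'   background concentration.
#' @param onset_s pulse onset on the \code{t} axis, s.
#' @return a \code{DiffusionCurve}.
#' @export
DiffusionCurve <- function(t, conc_mM, source = SourceConfig(),
                           medium = "tissue",
                           baseline_mM = molPerCm3ToMM(source@c_baseline),
                           onset_s = 0) {
  new("DiffusionCurve", t = as.numeric(t), conc_mM = as.numeric(conc_mM),
      source = source, medium = medium,
      baseline_mM = as.numeric(baseline_mM), onset_s = as.numeric(onset_s))
}

#' IsmCalibration: Nicolsky-Eisenman transfer function of one ISM
#'
#' The voltage of a TMA+-selective microelectrode follows
#' \eqn{V = v_0 + s \log_{10}(c + c_i)} where \eqn{s} is the slope per
#' decade and \eqn{c_i} lumps interfering ions into an equivalent background
#' concentration.
#'
#' @slot v0 voltage offset, mV (voltage at 1 mM when interference is 0).
#' @slot slope mV per decade of concentration, > 0 for a cation electrode.
#' @slot interference equivalent interfering concentration, mM, >= 0.
#' @slot rms_mV residual RMS of the calibration fit, mV (NA if constructed
#'   directly).
#' @export
setClass("IsmCalibration", representation(
  v0 = "numeric", slope = "numeric", interference = "numeric",
  rms_mV = "numeric"
))

setValidity("IsmCalibration", function(object) {
  msg <- character()
  if (object@slope <= 0) msg <- c(msg, "slope must be > 0")
  if (object@interference < 0) msg <- c(msg, "interference must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an IsmCalibration
#'
#' @param v0 voltage offset, mV.
#' @param slope mV per decade, > 0. The default 58 mV/decade is the
#'   near-Nernstian room-temperature slope of a monovalent cation electrode.
#' @param interference equivalent interfering concentration, mM.
#' @param rms_mV residual RMS of a fit, mV.
#' @return an \code{IsmCalibration}.
#' @examples
#' cal <- IsmCalibration(v0 = 10, slope = 58, interference = 0.05)
#' nikolskiVoltage(1, cal)
#' @export
IsmCalibration <- function(v0 = 0, slope = 58, interference = 0,
                           rms_mV = NA_real_) {
  new("IsmCalibration", v0 = as.numeric(v0), slope = as.numeric(slope),
      interference = as.numeric(interference), rms_mV = as.numeric(rms_mV))
}

#' FitResult: outcome of one diffusion-curve fit
#'
#' @slot params fitted \code{\linkS4class{DiffusionParams}}.
#' @slot sse sum of squared residuals, (mM)^2, over the fitted window.
#' @slot n_iter optimizer function evaluations used (summed over restarts).
#' @slot converged logical; FALSE when the optimizer failed or the curve
#'   carried no usable signal.
#' @slot fitted_window c(t_start, t_end) of the residual window, s.
#' @slot diagnostics list: per-parameter bound flags, restart SSEs, notes.
#' @export
setClass("FitResult", representation(
  params = "DiffusionParams", sse = "numeric", n_iter = "numeric",
  converged = "logical", fitted_window = "numeric", diagnostics = "list"
))

#' ImageTimeSeries: ordered fluorescence z-stacks of one cell
#'
#' @slot stacks list of 3D numeric arrays, dimension (rows y, cols x,
#'   slices z); all stacks share dimensions.
#' @slot voxel_size voxel edge lengths c(x, y, z), um.
#' @slot timepoints acquisition times, min, one per stack, non-decreasing.
#' @slot n_baseline number of pre-treatment stacks (used for the
#'   photobleaching fit), >= 2.
#' @export
setClass("ImageTimeSeries", representation(
  stacks = "list", voxel_size = "numeric", timepoints = "numeric",
  n_baseline = "integer"
))

setValidity("ImageTimeSeries", function(object) {
  msg <- character()
  if (!length(object@stacks)) msg <- c(msg, "need at least one stack")
  dims <- lapply(object@stacks, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    msg <- c(msg, "stacks must be 3D arrays")
  else if (length(unique(vapply(dims, paste, "", collapse = "x"))) > 1)
    msg <- c(msg, "all stacks must share dimensions")
  if (length(object@voxel_size) != 3 || any(object@voxel_size <= 0))
    msg <- c(msg, "voxel_size must be 3 positive values (x, y, z) in um")
  if (length(object@timepoints) != length(object@stacks))
    msg <- c(msg, "one timepoint per stack required")
  if (length(object@timepoints) > 1 && any(diff(object@timepoints) < 0))
    msg <- c(msg, "timepoints must be non-decreasing")
  if (object@n_baseline < 2L)
    msg <- c(msg, "n_baseline must be >= 2 for the bleaching fit")
  if (length(msg)) msg else TRUE
})

#' Construct an ImageTimeSeries
#'
#' @param stacks list of 3D arrays (y, x, z).
#' @param voxel_size voxel size c(x, y, z) in um; the default
#'   0.41 x 0.41 x 0.5 um matches the acquisition protocol emulated by the
#'   synthetic generator.
#' @param timepoints acquisition times, min.
#' @param n_baseline number of baseline stacks.
#' @return an \code{ImageTimeSeries}.
#' @export
ImageTimeSeries <- function(stacks, voxel_size = c(0.41, 0.41, 0.5),
                            timepoints = seq_along(stacks) - 1,
                            n_baseline = 3L) {
  new("ImageTimeSeries", stacks = stacks,
      voxel_size = as.numeric(voxel_size),
      timepoints = as.numeric(timepoints),
      n_baseline = as.integer(n_baseline))
}

#' VolumeTimecourse: normalized soma volume of one cell over time
#'
#' Soma volume is estimated from the segmented 2D soma area Ss assuming
#' isotropic volume changes, \eqn{V_s \propto S_s^{3/2}}, and expressed as
#' percent of the reference timepoint.
#'
#' @slot t acquisition times, min.
#' @slot vol_pct normalized soma volume, percent of the reference
#'   timepoint (exactly 100 there).
#' @slot fi ROI integral fluorescence intensity, a.u. (NA when not
#'   measured).
#' @slot ss segmented soma area per frame, um^2.
#' @slot reference_index index of the reference timepoint.
#' @export
setClass("VolumeTimecourse", representation(
  t = "numeric", vol_pct = "numeric", fi = "numeric", ss = "numeric",
  reference_index = "integer"
))

setValidity("VolumeTimecourse", function(object) {
  n <- length(object@t)
  msg <- character()
  if (length(object@vol_pct) != n || length(object@ss) != n ||
      length(object@fi) != n)
    msg <- c(msg, "t, vol_pct, fi, ss must share length")
  ri <- object@reference_index
  if (ri < 1L || ri > n) msg <- c(msg, "reference_index out of range")
  else if (abs(object@vol_pct[ri] - 100) > 1e-9)
    msg <- c(msg, "vol_pct must equal 100 at the reference timepoint")
  if (length(msg)) msg else TRUE
})
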