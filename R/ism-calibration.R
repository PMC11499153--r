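## Ion-selective microelectrode calibration: the Nicolsky-Eisenman
## ("Nikolski") transfer function with a lumped interference term, and the
## five-solution calibration fit that recovers its constants.

#' ISM voltage for a given tracer concentration
#'
#' Nicolsky-Eisenman form with the interfering ions lumped into one
#' equivalent concentration: \eqn{V = v_0 + s \log_{10}(c + c_i)}. The
#' function is monotonically increasing in \code{c} for a cation-selective
#' electrode (slope > 0).
#'
#' @param c_mM tracer concentration, mM, >= 0 (vectorized).
#' @param cal an \code{\linkS4class{IsmCalibration}}.
#' @return electrode voltage, mV.
#' @examples
#' cal <- IsmCalibration(v0 = 10, slope = 58, interference = 0.05)
#' nikolskiVoltage(c(0.1, 1, 10), cal)
#' @export
nikolskiVoltage <- function(c_mM, cal) {
  stopifnot(is(cal, "IsmCalibration"))
  if (any(c_mM < 0)) stop("concentrations must be >= 0")
  arg <- c_mM + cal@interference
  if (any(arg <= 0))
    stop("c + interference must be > 0 for the Nikolski log term")
  cal@v0 + cal@slope * log10(arg)
}

#' Concentration from an ISM voltage
#'
#' Inverse of \code{\link{nikolskiVoltage}}:
#' \eqn{c = 10^{(V - v_0)/s} - c_i}, clipped at 0. Voltages far below the
#' calibrated range therefore map to 0 mM rather than to negative
#' concentrations.
#'
#' @param v_mV electrode voltage, mV (vectorized).
#' @param cal an \code{\linkS4class{IsmCalibration}}.
#' @return concentration, mM, >= 0.
#' @export
voltageToConcentration <- function(v_mV, cal) {
  stopifnot(is(cal, "IsmCalibration"))
  pmax(0, 10^((v_mV - cal@v0) / cal@slope) - cal@interference)
}

#' Read a calibration series from CSV
#'
#' One file per electrode with columns \code{concentration_mM} and
#' \code{voltage_mV}, one row per calibration solution.
#'
#' @param path CSV file path.
#' @return a data.frame with columns \code{concentration_mM},
#'   \code{voltage_mV}, sorted by concentration.
#' @export
readCalibrationSeries <- function(path) {
  df <- read.csv(path)
  need <- c("concentration_mM", "voltage_mV")
  if (!all(need %in% names(df)))
    stop("calibration CSV needs columns: ", paste(need, collapse = ", "))
  df <- df[complete.cases(df[, need]), need]
  df[order(df$concentration_mM), , drop = FALSE]
}

#' Fit calibration constants from a calibration series
#'
#' Nonlinear least-squares fit of \eqn{V = v_0 + s \log_{10}(c + c_i)} to a
#' measured concentration/voltage series (the standard series spans 0.1,
#' 0.3, 1, 3, 10 mM). \code{v_0} and the slope are initialized from a
#' log-linear fit of the top three concentrations, where the interference
#' term is negligible; the interference starts at 0 and is bounded below
#' by 0.
#'
#' @param series data.frame with columns \code{concentration_mM} and
#'   \code{voltage_mV} (>= 4 points spanning >= 1.5 decades), or the two
#'   vectors given separately via \code{voltages_mV}.
#' @param voltages_mV optional voltage vector when \code{series} is a
#'   concentration vector.
#' @return an \code{\linkS4class{IsmCalibration}} with the residual RMS
#'   recorded in its \code{rms_mV} slot.
#' @examples
#' truth <- IsmCalibration(v0 = 10, slope = 58, interference = 0.08)
#' conc <- c(0.1, 0.3, 1, 3, 10)
#' fitCalibration(data.frame(concentration_mM = conc,
#'                           voltage_mV = nikolskiVoltage(conc, truth)))
#' @export
fitCalibration <- function(series, voltages_mV = NULL) {
  if (!is.null(voltages_mV))
    series <- data.frame(concentration_mM = series, voltage_mV = voltages_mV)
  conc <- series$concentration_mM
  v <- series$voltage_mV
  if (length(conc) < 4)
    stop("calibration fit needs at least 4 points")
  if (any(conc <= 0) || any(diff(sort(conc)) <= 0))
    stop("concentrations must be positive and distinct")
  if (log10(max(conc) / min(conc)) < 1.5)
    stop("calibration series must span at least 1.5 decades")
  if (length(unique(v)) == 1L)
    stop("degenerate calibration series: all voltages identical")
  ord <- order(conc)
  conc <- conc[ord]; v <- v[ord]
  if (any(diff(v) <= 0))
    warning("voltages are not monotonically increasing in concentration; ",
            "fitting anyway")
  ## initialize from the high end, where interference barely bends the line
  top <- tail(seq_along(conc), 3)
  ini <- coef(lm(v[top] ~ log10(conc[top])))
  if (!is.finite(ini[2]) || ini[2] <= 0)
    stop("calibration fit failed: could not initialize a positive slope")
  fit <- try(minpack.lm::nlsLM(
    v ~ v0 + slope * log10(conc + ci),
    start = list(v0 = unname(ini[1]), slope = unname(ini[2]), ci = 0),
    lower = c(-Inf, 1e-6, 0),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14)),
    silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("calibration fit failed: ", attr(fit, "condition")$message)
  cf <- coef(fit)
  IsmCalibration(v0 = cf[["v0"]], slope = cf[["slope"]],
                 interference = cf[["ci"]],
                 rms_mV = sqrt(mean(residuals(fit)^2)))
}
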