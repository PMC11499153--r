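## Inverse problem: Nelder-Mead simplex fitting of diffusion curves.
## Agar mode recovers the electrode constants (n, D) with alpha = lambda = 1
## and k' = 0 fixed; tissue mode holds (n, D) from the agar calibration and
## recovers (alpha, lambda, k').

## raw increment without S4 construction, for tight optimizer loops
.concIncrementOn <- function(r, t, Q, alpha, lam, kprime, D) {
  out <- numeric(length(t))
  on <- t > 0
  if (!any(on)) return(out)
  tt <- t[on]
  a <- r * lam / (2 * sqrt(D * tt))
  s <- sqrt(kprime * tt)
  b <- r * lam * sqrt(kprime / D)
  E <- exp(-(a^2 + s^2))
  term1 <- .erfcx(a + s) * E
  term2 <- ifelse(a >= s,
                  .erfcx(a - s) * E,
                  2 * exp(-b) - .erfcx(s - a) * E)
  out[on] <- Q * lam^2 / (8 * pi * D * alpha * r) * (term1 + term2)
  out
}

## pulse increment (mol/cm^3) at times since onset, raw parameters
.pulseIncrement <- function(r, t, dur, Q, alpha, lam, kprime, D) {
  up <- .concIncrementOn(r, pmax(t, 0), Q, alpha, lam, kprime, D)
  after <- t > dur
  if (any(after))
    up[after] <- up[after] -
      .concIncrementOn(r, t[after] - dur, Q, alpha, lam, kprime, D)
  up
}

## bounded <-> unconstrained transforms (logistic on (lo, hi))
.toTheta <- function(x, lo, hi) qlogis(pmin(pmax((x - lo) / (hi - lo),
                                                 1e-12), 1 - 1e-12))
.fromTheta <- function(th, lo, hi) lo + (hi - lo) * plogis(th)

## Nelder-Mead with deterministic perturbed restarts, then polish passes
## until refitting no longer improves the SSE by more than 1e-6 relative.
.simplexFit <- function(obj, theta0, n_restarts = 3, maxit = 5000,
                        reltol = 1e-10) {
  perturb <- list(0, 0.5, -0.5)
  best <- NULL
  evals <- 0
  codes <- integer(0)
  for (i in seq_len(n_restarts)) {
    th <- theta0 + perturb[[i]] * rep_len(c(1, -1), length(theta0))
    o <- optim(th, obj, method = "Nelder-Mead",
               control = list(reltol = reltol, maxit = maxit))
    evals <- evals + o$counts[["function"]]
    codes <- c(codes, o$convergence)
    if (is.null(best) || o$value < best$value) best <- o
  }
  repeat {
    o <- optim(best$par, obj, method = "Nelder-Mead",
               control = list(reltol = reltol, maxit = maxit))
    evals <- evals + o$counts[["function"]]
    codes <- c(codes, o$convergence)
    improved <- (best$value - o$value) > 1e-6 * max(best$value, 1e-300)
    if (o$value < best$value) best <- o
    if (!improved) break
  }
  list(par = best$par, value = best$value, evals = evals,
       ok = all(codes == 0L))
}

## residual window and observed increments of a curve
.fitData <- function(curve, decay_mult = 2) {
  dur <- curve@source@duration_s
  w <- curve@t >= curve@onset_s &
    curve@t <= curve@onset_s + (1 + decay_mult) * dur
  if (!any(curve@t < curve@onset_s))
    stop("curve has no pre-pulse baseline samples")
  if (max(curve@t) < curve@onset_s + dur)
    stop("curve is shorter than the current pulse")
  list(t = curve@t[w] - curve@onset_s,
       inc_mM = curve@conc_mM[w] - curve@baseline_mM,
       window = range(curve@t[w]), dur = dur)
}

#' Fit electrode constants from an agar calibration curve
#'
#' In dilute agar the medium is free (alpha = 1, lambda = 1, k' = 0 fixed),
#' so the curve determines the electrode transport number \code{n} and the
#' free diffusion coefficient \code{D}. Minimizes the sum of squared
#' residuals (mM^2) between the recorded curve and the pulse model with a
#' Nelder-Mead simplex (log/logit-transformed parameters, deterministic
#' perturbed restarts).
#'
#' @param curve a \code{\linkS4class{DiffusionCurve}} with
#'   \code{medium == "agar"}.
#' @param D_init,n_init starting values for the free diffusion coefficient
#'   (cm^2/s) and transport number.
#' @param fit_t0 also fit a small onset-time offset (nuisance parameter for
#'   recordings whose trigger and pulse are not perfectly aligned).
#' @param decay_mult length of the fitted post-pulse decay, in pulse
#'   durations.
#' @return a \code{\linkS4class{FitResult}} whose params carry the fitted
#'   \code{n_transport} and \code{D} (alpha = lambda = 1, k' = 0).
#' @examples
#' cfg <- SourceConfig(r_um = 100)
#' truth <- freeMediumParams(D = 1.2e-5, n_transport = 0.35)
#' curve <- pulseCurve(seq(-10, 72, by = 0.1), cfg, truth, medium = "agar")
#' fit <- fitAgar(curve)
#' transportNumber(fit); freeDiffusion(fit)
#' @export
fitAgar <- function(curve, D_init = 1.2e-5, n_init = 0.3, fit_t0 = FALSE,
                    decay_mult = 2) {
  stopifnot(is(curve, "DiffusionCurve"))
  if (curve@medium != "agar")
    stop("fitAgar expects a curve recorded in agar")
  fd <- .fitData(curve, decay_mult)
  cfg <- curve@source
  I <- cfg@i_step - cfg@i_bias
  no_signal <- max(fd$inc_mM) < 1e-4

  obj <- function(th) {
    n <- .fromTheta(th[1], 0, 1)
    D <- exp(th[2])
    t0 <- if (fit_t0) th[3] else 0
    Q <- I * n / (cfg@z_valence * cfg@faraday)
    mod <- molPerCm3ToMM(.pulseIncrement(cfg@r, fd$t - t0, fd$dur, Q,
                                         1, 1, 0, D))
    sum((fd$inc_mM - mod)^2)
  }
  theta0 <- c(.toTheta(n_init, 0, 1), log(D_init))
  if (fit_t0) theta0 <- c(theta0, 0)
  sf <- .simplexFit(obj, theta0)
  n_hat <- .fromTheta(sf$par[1], 0, 1)
  D_hat <- exp(sf$par[2])
  params <- freeMediumParams(D = D_hat, n_transport = n_hat)
  flags <- c(n_transport = abs(n_hat - 1) < 1e-3 || n_hat < 1e-3)
  new("FitResult", params = params, sse = sf$value, n_iter = sf$evals,
      converged = sf$ok && !no_signal, fitted_window = fd$window,
      diagnostics = list(bound_flags = flags, no_signal = no_signal,
                         t0 = if (fit_t0) sf$par[3] else 0,
                         mode = "agar"))
}

#' Fit ECS diffusion parameters from a tissue curve
#'
#' Holds the electrode constants \code{n} and \code{D} fixed at the values
#' from a prior agar calibration and fits the tissue parameters by
#' Nelder-Mead on the residual sum of squares (mM^2): volume fraction
#' alpha in (0.01, 1], tortuosity lambda in [1, 3] and uptake rate
#' k' in [0, 0.1] 1/s, enforced through logistic transforms. Residuals run
#' from pulse onset to pulse end plus \code{decay_mult} pulse durations;
#' the stored pre-pulse baseline is subtracted first. A fit that terminates
#' within 1e-3 of a bound is flagged \code{bound-constrained} in the
#' diagnostics, not failed.
#'
#' @param curve a \code{\linkS4class{DiffusionCurve}} with
#'   \code{medium == "tissue"}.
#' @param n_transport,D electrode constants from \code{\link{fitAgar}}.
#' @param start starting values \code{c(alpha, lam, kprime)}; the default
#'   (0.2, 1.5, 3e-3) sits in the physiological regime of grey matter.
#' @param fit_D also free the diffusion coefficient (by default it stays
#'   fixed at the agar value, which is how the two-step protocol is run).
#' @param fit_t0 also fit an onset-time offset.
#' @param decay_mult length of the fitted decay, in pulse durations.
#' @return a \code{\linkS4class{FitResult}}.
#' @examples
#' cfg <- SourceConfig(r_um = 100)
#' truth <- DiffusionParams(0.19, 1.6, 5e-3, n_transport = 0.3)
#' curve <- pulseCurve(seq(-10, 72, by = 0.1), cfg, truth)
#' fit <- fitTissue(curve, n_transport = 0.3, D = 1.2e-5)
#' volumeFraction(fit); tortuosity(fit); uptakeRate(fit)
#' @export
fitTissue <- function(curve, n_transport, D,
                      start = c(alpha = 0.2, lam = 1.5, kprime = 3e-3),
                      fit_D = FALSE, fit_t0 = FALSE, decay_mult = 2) {
  stopifnot(is(curve, "DiffusionCurve"))
  if (curve@medium != "tissue")
    stop("fitTissue expects a curve recorded in tissue")
  fd <- .fitData(curve, decay_mult)
  cfg <- curve@source
  I <- cfg@i_step - cfg@i_bias
  Q <- I * n_transport / (cfg@z_valence * cfg@faraday)
  no_signal <- max(fd$inc_mM) < 1e-4

  lo <- c(0.01, 1, 0)
  hi <- c(1, 3, 0.1)
  obj <- function(th) {
    x <- .fromTheta(th[1:3], lo, hi)
    Dfit <- if (fit_D) exp(th[4]) else D
    t0 <- if (fit_t0) th[length(th)] else 0
    mod <- molPerCm3ToMM(.pulseIncrement(cfg@r, fd$t - t0, fd$dur, Q,
                                         x[1], x[2], x[3], Dfit))
    sum((fd$inc_mM - mod)^2)
  }
  theta0 <- .toTheta(start, lo, hi)
  if (fit_D) theta0 <- c(theta0, log(D))
  if (fit_t0) theta0 <- c(theta0, 0)
  sf <- .simplexFit(obj, theta0)
  x <- .fromTheta(sf$par[1:3], lo, hi)
  D_hat <- if (fit_D) exp(sf$par[4]) else D
  params <- DiffusionParams(alpha = x[1], lam = x[2], kprime = x[3],
                            D = D_hat, n_transport = n_transport)
  tol <- 1e-3 * (hi - lo)
  flags <- c(alpha = min(x[1] - lo[1], hi[1] - x[1]) < tol[1],
             lam = min(x[2] - lo[2], hi[2] - x[2]) < tol[2],
             kprime = min(x[3] - lo[3], hi[3] - x[3]) < tol[3])
  new("FitResult", params = params, sse = sf$value, n_iter = sf$evals,
      converged = sf$ok && !no_signal, fitted_window = fd$window,
      diagnostics = list(bound_flags = flags, no_signal = no_signal,
                         t0 = if (fit_t0) sf$par[length(sf$par)] else 0,
                         mode = "tissue"))
}

#' Convert a raw voltage trace into a DiffusionCurve
#'
#' Applies the ISM calibration to turn voltages into concentrations,
#' estimates the baseline as the median of the pre-pulse samples (at least
#' 5 s of pre-pulse recording required) and returns an annotated
#' \code{\linkS4class{DiffusionCurve}} ready for fitting.
#'
#' @param voltages_mV recorded voltages, mV.
#' @param times_s sample times, s, strictly increasing.
#' @param cal an \code{\linkS4class{IsmCalibration}}.
#' @param cfg the \code{\linkS4class{SourceConfig}} of the recording.
#' @param onset_s pulse onset on the time axis (default 0).
#' @param medium \code{"agar"} or \code{"tissue"}.
#' @return a \code{\linkS4class{DiffusionCurve}}.
#' @export
preprocessCurve <- function(voltages_mV, times_s, cal, cfg, onset_s = 0,
                            medium = "tissue") {
  stopifnot(length(voltages_mV) == length(times_s))
  if (min(times_s) > onset_s - 5)
    stop("need at least 5 s of pre-pulse baseline before the onset")
  conc <- voltageToConcentration(voltages_mV, cal)
  baseline <- median(conc[times_s < onset_s])
  DiffusionCurve(times_s, pmax(conc, 0), source = cfg, medium = medium,
                 baseline_mM = baseline, onset_s = onset_s)
}
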