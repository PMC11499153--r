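## Forward model: TMA+ concentration around an iontophoretic point source
## in free medium and in porous tissue with first-order uptake.
##
## The tissue model is the point-source solution of the modified diffusion
## equation  dC/dt = (D/lambda^2) laplacian(C) + (Q/alpha) delta(r) - k' C:
##
##   C(r,t) = Q lambda^2 / (8 pi D alpha r) *
##            [ e^{ b} erfc( r lambda / (2 sqrt(D t)) + sqrt(k' t) )
##            + e^{-b} erfc( r lambda / (2 sqrt(D t)) - sqrt(k' t) ) ]
##   with b = r lambda sqrt(k'/D).
##
## e^{b} can overflow for admissible (r, lambda, k'); the products are
## therefore evaluated through the scaled complementary error function
## erfcx(x) = e^{x^2} erfc(x). Writing a = r lambda/(2 sqrt(D t)) and
## s = sqrt(k' t) one has b = 2 a s, so
##   e^{ b} erfc(a + s) = erfcx(a + s) e^{-(a^2 + s^2)}
##   e^{-b} erfc(a - s) = erfcx(a - s) e^{-(a^2 + s^2)}          (a >= s)
##                      = 2 e^{-b} - erfcx(s - a) e^{-(a^2 + s^2)} (a < s)
## and every exponent is <= 0.

## erfcx(x) = e^{x^2} erfc(x) for x >= 0. pracma::erfcx loses accuracy and
## eventually returns NaN past x ~ 26 (its erfc factor underflows); beyond
## that the asymptotic expansion
##   erfcx(x) ~ 1/(x sqrt(pi)) (1 - 1/(2x^2) + 3/(4x^4) - 15/(8x^6))
## is accurate to ~1e-11 already at x = 20.
.erfcx <- function(x) {
  out <- numeric(length(x))
  lo <- x <= 20
  if (any(lo)) out[lo] <- pracma::erfcx(x[lo])
  if (any(!lo)) {
    xi2 <- 1 / x[!lo]^2
    out[!lo] <- (1 + xi2 * (-0.5 + xi2 * (0.75 - 1.875 * xi2))) /
      (x[!lo] * sqrt(pi))
  }
  out
}

#' Molar release rate of the iontophoretic source
#'
#' The source releases tracer at \eqn{Q = I n / (z F)} mol/s, where
#' \eqn{n} is the electrode transport number. The continuously applied
#' bias current is treated as an equilibrated part of the measured
#' baseline, so the step response uses the step amplitude
#' \eqn{I = i_{step} - i_{bias}} (linear superposition).
#'
#' @param cfg a \code{\linkS4class{SourceConfig}}.
#' @param n_transport electrode transport number in (0, 1]; may be 0 to
#'   express a non-transporting electrode.
#' @param use_step_only if TRUE (default) the effective current is
#'   \code{i_step - i_bias}; if FALSE the full \code{i_step} is used.
#' @return molar release rate Q, mol/s.
#' @examples
#' cfg <- SourceConfig(i_step_nA = 200, i_bias_nA = 0)
#' sourceRate(cfg, n_transport = 0.5)  # ~1.036e-12 mol/s
#' @export
sourceRate <- function(cfg, n_transport, use_step_only = TRUE) {
  stopifnot(is(cfg, "SourceConfig"))
  if (n_transport < 0 || n_transport > 1)
    stop("n_transport must be in [0, 1]")
  I <- if (use_step_only) cfg@i_step - cfg@i_bias else cfg@i_step
  if (I <= 0) stop("effective iontophoretic current must be positive")
  I * n_transport / (cfg@z_valence * cfg@faraday)
}

#' Concentration increment around a source switched on at t = 0
#'
#' Closed-form solution for a point source of strength \code{Q} switched on
#' at t = 0 and still on, in a medium described by \code{p}. With
#' alpha = 1, lambda = 1, k' = 0 it reduces to the free-medium solution
#' \eqn{C = Q/(4 \pi D r) \, \mathrm{erfc}(r / (2 \sqrt{D t}))}.
#'
#' @param r source-sensor distance, cm, > 0 (>= 1 um).
#' @param t time since source on, s, >= 0 (vectorized).
#' @param Q molar release rate, mol/s (see \code{\link{sourceRate}}).
#' @param p a \code{\linkS4class{DiffusionParams}}.
#' @return concentration increment above baseline, mol/cm^3, one value per
#'   element of \code{t}; exactly 0 at t = 0.
#' @examples
#' p <- DiffusionParams(alpha = 0.19, lam = 1.6, kprime = 5e-3)
#' concentrationOn(umToCm(100), c(0, 1, 10, 24), Q = 1e-12, p)
#' @export
concentrationOn <- function(r, t, Q, p) {
  stopifnot(is(p, "DiffusionParams"))
  if (r < 1e-4) stop("r below 1 um is unphysical for an RTI array")
  if (any(t < 0)) stop("t must be >= 0")
  out <- numeric(length(t))
  on <- t > 0
  if (!any(on)) return(out)
  tt <- t[on]
  a <- r * p@lam / (2 * sqrt(p@D * tt))
  s <- sqrt(p@kprime * tt)
  b <- r * p@lam * sqrt(p@kprime / p@D)
  E <- exp(-(a^2 + s^2))
  term1 <- .erfcx(a + s) * E
  term2 <- ifelse(a >= s,
                  .erfcx(a - s) * E,
                  2 * exp(-b) - .erfcx(s - a) * E)
  pref <- Q * p@lam^2 / (8 * pi * p@D * p@alpha * r)
  out[on] <- pref * (term1 + term2)
  out
}

#' Steady-state concentration increment
#'
#' The large-time limit of \code{\link{concentrationOn}}:
#' \eqn{C_\infty = Q \lambda^2 / (4 \pi D \alpha r) \,
#' e^{-r \lambda \sqrt{k'/D}}}.
#'
#' @inheritParams concentrationOn
#' @return concentration increment, mol/cm^3.
#' @export
steadyState <- function(r, Q, p) {
  stopifnot(is(p, "DiffusionParams"))
  if (r < 1e-4) stop("r below 1 um is unphysical for an RTI array")
  b <- r * p@lam * sqrt(p@kprime / p@D)
  Q * p@lam^2 / (4 * pi * p@D * p@alpha * r) * exp(-b)
}

#' Concentration during and after a current step
#'
#' Full pulse response at the sensor: baseline plus the on-response, minus
#' (after the pulse ends) the on-response delayed by the pulse duration --
#' linear superposition of switching an equal-and-opposite source on at
#' \code{t = duration_s}. Time is measured from pulse onset.
#'
#' @param r source-sensor distance, cm; defaults to the separation stored
#'   in \code{cfg}.
#' @param t time since pulse onset, s, >= 0 (vectorized).
#' @param cfg a \code{\linkS4class{SourceConfig}}.
#' @param p a \code{\linkS4class{DiffusionParams}} (its
#'   \code{n_transport} sets the release rate).
#' @param use_step_only passed to \code{\link{sourceRate}}.
#' @return total concentration, mol/cm^3, including the baseline.
#' @examples
#' cfg <- SourceConfig()
#' p <- DiffusionParams(0.19, 1.6, 5e-3, n_transport = 0.3)
#' molPerCm3ToMM(concentrationPulse(t = c(1, 24, 48), cfg = cfg, p = p))
#' @export
concentrationPulse <- function(r = cfg@r, t, cfg, p, use_step_only = TRUE) {
  Q <- sourceRate(cfg, p@n_transport, use_step_only = use_step_only)
  up <- concentrationOn(r, t, Q, p)
  after <- t > cfg@duration_s
  if (any(after)) {
    down <- concentrationOn(r, t[after] - cfg@duration_s, Q, p)
    up[after] <- up[after] - down
  }
  cfg@c_baseline + up
}

#' Model a full pulse as a DiffusionCurve
#'
#' Convenience wrapper: evaluates \code{\link{concentrationPulse}} on a
#' time grid (which may extend before the onset) and returns a
#' \code{\linkS4class{DiffusionCurve}} in mM.
#'
#' @param t time grid, s; the pulse switches on at \code{onset_s}.
#' @param cfg a \code{\linkS4class{SourceConfig}}.
#' @param p a \code{\linkS4class{DiffusionParams}}.
#' @param medium curve label, \code{"agar"} or \code{"tissue"}.
#' @param onset_s pulse onset on the \code{t} axis.
#' @return a \code{\linkS4class{DiffusionCurve}}.
#' @export
pulseCurve <- function(t, cfg, p, medium = "tissue", onset_s = 0) {
  conc <- rep(molPerCm3ToMM(cfg@c_baseline), length(t))
  on <- t >= onset_s
  conc[on] <- molPerCm3ToMM(
    concentrationPulse(t = t[on] - onset_s, cfg = cfg, p = p))
  DiffusionCurve(t, conc, source = cfg, medium = medium,
                 baseline_mM = molPerCm3ToMM(cfg@c_baseline),
                 onset_s = onset_s)
}
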