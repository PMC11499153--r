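## Independent numerical cross-check of the closed-form forward model:
## a spherically symmetric finite-volume discretisation of the modified
## diffusion equation integrated with deSolve. Used by the validation
## suite; shares no code path with concentrationOn().

#' Radial finite-difference solution of the modified diffusion equation
#'
#' Solves \eqn{\partial C/\partial t = (D/\lambda^2) \nabla^2 C +
#' (Q/\alpha)\,\delta(r) - k' C} on a spherically symmetric, logarithmically
#' graded finite-volume grid, with the source deposited in the innermost
#' shell and a zero-concentration outer boundary. This is an independent
#' numerical route to the quantity computed in closed form by
#' \code{\link{concentrationOn}}; it exists to validate that model and is
#' not used by the fitting routines.
#'
#' @param r_eval radii at which to report the solution, cm.
#' @param t_eval times at which to report, s (> 0, increasing).
#' @param Q molar release rate, mol/s.
#' @param p a \code{\linkS4class{DiffusionParams}}.
#' @param r_max outer boundary, cm; must exceed the diffusion length at
#'   \code{max(t_eval)} (default 0.1 cm = 1000 um).
#' @param n_cells number of radial cells.
#' @param r_min radius of the innermost cell edge, cm.
#' @return matrix of concentration increments, mol/cm^3, with
#'   \code{length(t_eval)} rows and \code{length(r_eval)} columns.
#' @examples
#' p <- DiffusionParams(0.2, 1.5, 3e-3)
#' fd <- solveRadialDiffusionFD(umToCm(100), c(5, 24), Q = 1e-12, p = p)
#' cf <- concentrationOn(umToCm(100), c(5, 24), Q = 1e-12, p = p)
#' fd[, 1] / cf   # ~1
#' @export
solveRadialDiffusionFD <- function(r_eval, t_eval, Q, p,
                                   r_max = 0.1, n_cells = 400,
                                   r_min = 5e-5) {
  stopifnot(is(p, "DiffusionParams"), all(t_eval > 0),
            all(diff(t_eval) > 0), all(r_eval > 0), all(r_eval < r_max))
  Dstar <- p@D / p@lam^2
  ## log-graded cell edges, fine near the source
  edges <- c(0, exp(seq(log(r_min), log(r_max), length.out = n_cells)))
  rc <- (edges[-1] + edges[-length(edges)]) / 2   # cell centers
  vol <- 4 / 3 * pi * diff(edges^3)               # cell volumes, cm^3
  area <- 4 * pi * edges^2                        # interface areas
  dcc <- diff(rc)                                 # center-to-center gaps
  src <- numeric(n_cells)
  src[1] <- Q / (p@alpha * vol[1])
  k <- p@kprime

  rhs <- function(t, C, parms) {
    ## diffusive fluxes across interior interfaces (positive = inward, i.e.
    ## towards larger index); the r = 0 edge carries no flux and the outer
    ## boundary sees a C = 0 ghost value at r_max
    flux <- Dstar * (C[-1] - C[-n_cells]) / dcc
    dC <- numeric(n_cells)
    dC[1] <- flux[1] * area[2] / vol[1]
    if (n_cells > 2)
      dC[2:(n_cells - 1)] <-
        (flux[2:(n_cells - 1)] * area[3:n_cells] -
         flux[1:(n_cells - 2)] * area[2:(n_cells - 1)]) /
        vol[2:(n_cells - 1)]
    out_flux <- Dstar * (0 - C[n_cells]) / (r_max - rc[n_cells])
    dC[n_cells] <- (out_flux * area[n_cells + 1] -
                    flux[n_cells - 1] * area[n_cells]) / vol[n_cells]
    list(dC + src - k * C)
  }

  sol <- deSolve::ode(y = numeric(n_cells), times = c(0, t_eval),
                      func = rhs, parms = NULL, method = "lsoda",
                      jactype = "bandint", bandup = 1, banddown = 1,
                      rtol = 1e-8, atol = 1e-18)
  conc <- sol[-1, -1, drop = FALSE]
  ## report at requested radii by monotone interpolation over cell centers
  out <- matrix(NA_real_, length(t_eval), length(r_eval))
  for (i in seq_along(t_eval))
    out[i, ] <- stats::spline(rc, conc[i, ], xout = r_eval)$y
  out
}
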