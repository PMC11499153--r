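## Synthetic fluorescent-astrocyte z-stack time series with programmed
## volume changes, photobleaching, lateral drift and Poisson-Gaussian
## noise. The phantom emulates the standard acquisition protocol: three
## baseline stacks in isotonic solution, four stacks at 5-min intervals
## during the potassium challenge, and washout stacks at +20 and +40 min.

#' Configuration for a simulated astrocyte image series
#'
#' The default protocol acquires 9 stacks: 3 baseline (the last one, at
#' t = 0, is the volume reference), 4 during the challenge at 5-min
#' intervals, and 2 washout stacks at 40 and 60 min. The default volume
#' profile swells to 340\% at the end of the challenge -- the regime evoked
#' by a 50 mM potassium challenge in cortical astrocytes -- and recovers
#' during washout. Geometry uses a 0.41 x 0.41 x 0.5 um voxel.
#'
#' @param soma_axes_um ellipsoid soma semi-axes c(x, y, z), um.
#' @param n_processes number of tapering processes radiating from the soma.
#' @param volume_profile_pct target soma volume per timepoint, percent of
#'   the reference (must be exactly 100 at the reference).
#' @param timepoints_min acquisition times, min.
#' @param n_baseline number of baseline stacks; the reference timepoint is
#'   the last of them.
#' @param bleach_per_stack fractional linear intensity loss per acquired
#'   stack (stack i is scaled by 1 - bleach_per_stack*(i-1)).
#' @param drift_px_per_frame lateral stage drift c(dy, dx), px per frame.
#' @param snr photon-noise level: relative noise at unit intensity is
#'   1/snr (Poisson shot noise with gain snr^2).
#' @param read_noise_sd additive Gaussian read noise, intensity units.
#' @param voxel_size_um voxel size c(x, y, z), um.
#' @param field_px lateral field size c(rows, cols), px.
#' @param n_slices z-slices per stack.
#' @param soma_intensity,process_intensity,background rendering
#'   intensities, arbitrary units in [0, 1].
#' @param process_length_um baseline process length beyond the soma edge.
#' @param supersample lateral supersampling factor for anti-aliased
#'   rendering (block-averaged back to the voxel grid).
#' @param seed RNG seed.
#' @return a validated config (classed list \code{"CellSimConfig"}).
#' @export
cellSimConfig <- function(soma_axes_um = c(6, 5, 4),
                          n_processes = 5L,
                          volume_profile_pct = c(100, 100, 100, 160, 220,
                                                 280, 340, 150, 100),
                          timepoints_min = c(-10, -5, 0, 5, 10, 15, 20,
                                             40, 60),
                          n_baseline = 3L,
                          bleach_per_stack = 0.02,
                          drift_px_per_frame = c(0.3, -0.2),
                          snr = 20,
                          read_noise_sd = 0.01,
                          voxel_size_um = c(0.41, 0.41, 0.5),
                          field_px = c(96, 96),
                          n_slices = 28L,
                          soma_intensity = 1,
                          process_intensity = 0.25,
                          background = 0.02,
                          process_length_um = 14,
                          supersample = 4L,
                          seed = 1L) {
  stopifnot(all(soma_axes_um > 0), length(soma_axes_um) == 3,
            length(volume_profile_pct) == length(timepoints_min),
            n_baseline >= 2, n_baseline <= length(volume_profile_pct),
            snr > 0, bleach_per_stack >= 0, bleach_per_stack < 1 / 8,
            all(volume_profile_pct > 0))
  if (abs(volume_profile_pct[n_baseline] - 100) > 1e-9)
    stop("volume_profile_pct must be exactly 100 at the reference ",
         "timepoint (the last baseline stack)")
  smax <- (max(volume_profile_pct) / 100)^(1 / 3)
  need <- smax * max(soma_axes_um[1:2]) / min(voxel_size_um[1:2]) +
    length(timepoints_min) * max(abs(drift_px_per_frame)) + 2
  if (2 * need > min(field_px))
    stop("soma (at peak swelling, plus drift) is larger than the field")
  if (smax * soma_axes_um[3] * 2 > n_slices * voxel_size_um[3])
    stop("soma taller than the imaged z-range at peak swelling")
  structure(list(soma_axes_um = soma_axes_um,
                 n_processes = as.integer(n_processes),
                 volume_profile_pct = volume_profile_pct,
                 timepoints_min = timepoints_min,
                 n_baseline = as.integer(n_baseline),
                 bleach_per_stack = bleach_per_stack,
                 drift_px_per_frame = drift_px_per_frame,
                 snr = snr, read_noise_sd = read_noise_sd,
                 voxel_size_um = voxel_size_um,
                 field_px = as.integer(field_px),
                 n_slices = as.integer(n_slices),
                 soma_intensity = soma_intensity,
                 process_intensity = process_intensity,
                 background = background,
                 process_length_um = process_length_um,
                 supersample = as.integer(supersample),
                 seed = as.integer(seed)),
            class = "CellSimConfig")
}

## block-average an (n*ss) x (m*ss) matrix down to n x m
.blockMean <- function(m, ss) {
  d <- dim(m) / ss
  dim(m) <- c(ss, d[1], ss, d[2])
  colMeans(aperm(m, c(1, 3, 2, 4)), dims = 2)
}

## render one noiseless stack at linear scale factor `s`, centered at
## center_px = c(y, x); returns array (y, x, z) of intensities
.renderCellStack <- function(cfg, s, center_px) {
  ss <- cfg$supersample
  vx <- cfg$voxel_size_um[1]; vy <- cfg$voxel_size_um[2]
  vz <- cfg$voxel_size_um[3]
  ny <- cfg$field_px[1]; nx <- cfg$field_px[2]; nz <- cfg$n_slices
  ## supersampled pixel-center coordinates, um, relative to the cell center
  ycoord <- (((seq_len(ny * ss) - 0.5) / ss + 0.5) - center_px[1]) * vy
  xcoord <- (((seq_len(nx * ss) - 0.5) / ss + 0.5) - center_px[2]) * vx
  a <- cfg$soma_axes_um[1] * s
  b <- cfg$soma_axes_um[2] * s
  cz <- cfg$soma_axes_um[3] * s
  z0 <- (nz + 1) / 2
  angles <- 2 * pi * (seq_len(cfg$n_processes) - 1) / cfg$n_processes + 0.4
  proc_halfz <- 1.5   # processes rendered in a thin central z-band, um
  plen <- cfg$process_length_um * s
  Y <- matrix(ycoord, length(ycoord), length(xcoord))
  X <- matrix(xcoord, length(ycoord), length(xcoord), byrow = TRUE)
  stack <- array(cfg$background, c(ny, nx, nz))
  for (k in seq_len(nz)) {
    dz <- (k - z0) * vz
    frac <- 1 - (dz / cz)^2
    slice <- NULL
    if (frac > 0) {
      az <- a * sqrt(frac); bz <- b * sqrt(frac)
      soma <- (X / az)^2 + (Y / bz)^2 <= 1
      slice <- soma * cfg$soma_intensity
    }
    if (abs(dz) <= proc_halfz) {
      if (is.null(slice)) slice <- matrix(0, nrow(Y), ncol(X))
      r_in <- 0.9 * sqrt(a * b)   # arm root just inside the soma edge
      for (th in angles) {
        u <- cos(th) * X + sin(th) * Y
        v <- -sin(th) * X + cos(th) * Y
        along <- (u - r_in) / plen
        wid <- (1.2 - 0.8 * pmin(pmax(along, 0), 1)) / 2  # taper 1.2->0.4 um
        arm <- along >= 0 & along <= 1 & abs(v) <= wid
        slice <- pmax(slice, arm * cfg$process_intensity)
      }
    }
    if (!is.null(slice))
      stack[, , k] <- pmax(.blockMean(slice, ss), cfg$background)
  }
  stack
}

#' Simulate a fluorescent-astrocyte z-stack time series
#'
#' Renders an anti-aliased ellipsoidal soma with tapering processes at each
#' timepoint, scaled isotropically so the soma volume follows
#' \code{volume_profile_pct}; applies per-stack linear photobleaching,
#' lateral drift and Poisson-Gaussian noise. The programmed volume profile
#' is returned as ground truth, together with the analytic soma
#' cross-section area and the supra-half-maximum voxel count of the
#' noiseless rendering (a self-check of the phantom's volume scaling).
#'
#' @param cfg a \code{\link{cellSimConfig}}.
#' @return list with \code{its} (an \code{\linkS4class{ImageTimeSeries}}),
#'   \code{truth} (a \code{\linkS4class{VolumeTimecourse}} holding the
#'   programmed volumes and analytic soma areas), \code{soma_voxels}
#'   (noiseless supra-half-max voxel count per stack) and
#'   \code{center_px} (true soma center per stack).
#' @examples
#' \donttest{
#' sim <- simulateCellSeries(cellSimConfig(seed = 3))
#' vt <- analyzeCellSeries(sim$its, seed_point = round(sim$center_px[3, ]))
#' }
#' @export
simulateCellSeries <- function(cfg = cellSimConfig()) {
  stopifnot(inherits(cfg, "CellSimConfig"))
  n <- length(cfg$timepoints_min)
  scale <- (cfg$volume_profile_pct / 100)^(1 / 3)
  center0 <- (cfg$field_px + 1) / 2
  gain <- cfg$snr^2
  stacks <- vector("list", n)
  soma_vox <- numeric(n)
  centers <- matrix(0, n, 2, dimnames = list(NULL, c("y", "x")))
  noise_seeds <- withr::with_seed(cfg$seed,
                                  sample.int(.Machine$integer.max, n))
  for (i in seq_len(n)) {
    centers[i, ] <- center0 + cfg$drift_px_per_frame * (i - 1)
    clean <- .renderCellStack(cfg, scale[i], centers[i, ])
    soma_vox[i] <- sum(clean > cfg$soma_intensity / 2)
    bleach <- 1 - cfg$bleach_per_stack * (i - 1)
    img <- clean * bleach
    stacks[[i]] <- withr::with_seed(noise_seeds[i], {
      shot <- array(rpois(length(img), img * gain) / gain, dim(img))
      pmax(shot + array(rnorm(length(img), 0, cfg$read_noise_sd),
                        dim(img)), 0)
    })
  }
  its <- ImageTimeSeries(stacks, voxel_size = cfg$voxel_size_um,
                         timepoints = cfg$timepoints_min,
                         n_baseline = cfg$n_baseline)
  ss_true <- pi * cfg$soma_axes_um[1] * cfg$soma_axes_um[2] * scale^2
  truth <- new("VolumeTimecourse", t = cfg$timepoints_min,
               vol_pct = cfg$volume_profile_pct,
               fi = rep(NA_real_, n), ss = ss_true,
               reference_index = cfg$n_baseline)
  list(its = its, truth = truth, soma_voxels = soma_vox,
       center_px = centers)
}
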