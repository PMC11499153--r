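## 3D confocal morphometry: projection, registration, photobleach
## correction, Isodata segmentation, soma area / volume, ROI intensity.
## Frames are plain numeric matrices indexed [row (y), col (x)]; stacks are
## arrays [y, x, z].

#' Average-intensity projection of a z-stack
#'
#' Reduces a 3D stack to a 2D frame by the pixelwise mean along z.
#'
#' @param stack 3D numeric array (y, x, z), non-empty.
#' @return 2D numeric matrix.
#' @examples
#' averageProjection(array(1:8, c(2, 2, 2)))
#' @export
averageProjection <- function(stack) {
  if (!is.array(stack) || length(dim(stack)) != 3 || !length(stack))
    stop("stack must be a non-empty 3D array")
  rowMeans(stack, dims = 2)
}

## shift a frame by (dy, dx) pixels in the Fourier domain (periodic,
## exact for band-limited content); used during shift estimation
.fourierShift <- function(frame, dy, dx) {
  d <- dim(frame)
  ky <- c(0:(floor(d[1] / 2)), -(ceiling(d[1] / 2) - 1):-1) / d[1]
  kx <- c(0:(floor(d[2] / 2)), -(ceiling(d[2] / 2) - 1):-1) / d[2]
  ph <- exp(-2i * pi * (outer(ky * dy, kx * dx, "+")))
  Re(fft(fft(frame) * ph, inverse = TRUE)) / length(frame)
}

.hannWindow <- function(d) {
  wy <- 0.5 - 0.5 * cos(2 * pi * seq_len(d[1]) / (d[1] + 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * seq_len(d[2]) / (d[2] + 1))
  outer(wy, wx)
}

## estimate the translation of `frame` relative to `ref`: integer peak of
## the FFT cross-correlation, then Nelder-Mead refinement of the SSD
## between the windowed reference and the Fourier-shifted frame
.estimateShift <- function(ref, frame) {
  d <- dim(ref)
  w <- .hannWindow(d)
  ## normalize both frames so amplitude differences (e.g. photobleaching)
  ## cannot bias the SSD minimum away from the true shift
  ref <- (ref - mean(ref)) / sd(ref)
  frame <- (frame - mean(frame)) / sd(frame)
  rw <- ref * w
  fw <- frame * w
  cc <- Re(fft(fft(rw) * Conj(fft(fw)), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  ## lag convention: cc[i+1, j+1] is correlation at shift (i, j) of frame
  ## relative to ref, wrapped
  int_shift <- pk - 1
  int_shift <- ifelse(int_shift > d / 2, int_shift - d, int_shift)
  obj <- function(s) sum(((frame - .fourierShift(ref, s[1], s[2])) * w)^2)
  o <- optim(int_shift, obj, method = "Nelder-Mead",
             control = list(reltol = 1e-12, maxit = 500))
  o$par
}

#' Register a frame time stack by translation
#'
#' Aligns every frame to the first by translation-only registration:
#' integer shift from the FFT cross-correlation peak, refined to subpixel
#' precision by minimizing the windowed squared difference under Fourier
#' shifting. Aligned frames are produced by bilinear resampling
#' (\code{EBImage::translate}); featureless (constant) frames get a zero
#' shift and a warning.
#'
#' @param frames list of 2D matrices, or a 3D array (y, x, frame); >= 2
#'   frames of one shape.
#' @return list with \code{frames} (list of aligned matrices) and
#'   \code{shifts} (n x 2 matrix of per-frame (dy, dx) displacements of
#'   each frame relative to the first, px).
#' @export
registerTimestack <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  if (length(frames) < 2) stop("need at least 2 frames")
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), TRUE)))
    stop("frames must share one shape")
  ref <- frames[[1]]
  n <- length(frames)
  shifts <- matrix(0, n, 2, dimnames = list(NULL, c("dy", "dx")))
  aligned <- vector("list", n)
  aligned[[1]] <- ref
  for (i in 2:n) {
    f <- frames[[i]]
    if (sd(f) == 0 || sd(ref) == 0) {
      warning("featureless frame ", i, "; assuming zero shift")
      aligned[[i]] <- f
      next
    }
    s <- .estimateShift(ref, f)
    shifts[i, ] <- s
    ## EBImage::translate moves content by v = c(along dim1, along dim2)
    aligned[[i]] <- as.matrix(EBImage::translate(f, -s, bg.col = 0))
  }
  list(frames = aligned, shifts = shifts)
}

#' Photobleaching correction by a linear baseline fit
#'
#' Image acquisition bleaches the fluorophore; over the pre-treatment
#' baseline stacks the scene is static, so any trend in total frame
#' intensity is attributed to bleaching. A straight line is fitted to total
#' intensity versus acquisition index over the first \code{n_baseline}
#' frames and every frame is divided by the line's predicted decay relative
#' to the first frame (factor 1 at frame 1, extrapolated past the
#' baseline). An increasing baseline trend cannot be bleaching; the
#' correction factor is then capped at 1 with a warning.
#'
#' @param frames list of 2D matrices (typically registered projections).
#' @param n_baseline number of baseline frames, >= 2.
#' @return list with \code{frames} (corrected), \code{factors} (per-frame
#'   divisors) and \code{slope_per_stack} (fitted fractional change per
#'   acquisition).
#' @export
bleachCorrect <- function(frames, n_baseline) {
  if (n_baseline < 2) stop("bleaching fit needs >= 2 baseline frames")
  if (length(frames) < n_baseline) stop("fewer frames than n_baseline")
  tot <- vapply(frames, sum, 0)
  idx <- seq_along(frames)
  fit <- lm(tot[seq_len(n_baseline)] ~ idx[seq_len(n_baseline)])
  pred <- coef(fit)[1] + coef(fit)[2] * idx
  factors <- pred / pred[1]
  if (coef(fit)[2] / pred[1] > 1e-9) {
    warning("baseline intensity increases; capping bleach factors at 1")
    factors <- pmin(factors, 1)
  } else if (coef(fit)[2] > 0) {
    factors <- pmin(factors, 1)   # numerically flat baseline
  }
  factors <- pmax(factors, 0.05)  # guard against absurd extrapolation
  list(frames = Map(function(f, k) f / k, frames, factors),
       factors = factors,
       slope_per_stack = unname(coef(fit)[2] / pred[1]))
}

#' Isodata (iterative intermeans) threshold
#'
#' Computes the automatic threshold T satisfying
#' \eqn{T = (\mu_{\le T} + \mu_{> T}) / 2} at convergence, on a 256-bin
#' histogram spanning the data's min--max range. Iteration moves the split
#' bin to \code{floor(u + 0.5)} (round half up) of the bin-unit coordinate
#' of the intermean midpoint, and stops when the split moves by less than
#' half a bin; a two-cycle, if one occurs, is resolved towards the
#' midpoint. Pixels strictly above the returned value are foreground.
#'
#' @param frame 2D matrix or numeric vector with >= 2 distinct values.
#' @param nbins histogram resolution.
#' @return threshold value (numeric scalar), with the converged split bin
#'   index in attribute \code{"split"}.
#' @examples
#' isodataThreshold(c(rep(10, 50), rep(200, 50)))  # ~105
#' @export
isodataThreshold <- function(frame, nbins = 256L) {
  v <- as.numeric(frame)
  lo <- min(v); hi <- max(v)
  if (!(hi > lo)) stop("cannot threshold a constant image")
  w <- (hi - lo) / nbins
  bin <- pmin(nbins, floor((v - lo) / w) + 1L)
  cnt <- tabulate(bin, nbins)
  centers <- lo + (seq_len(nbins) - 0.5) * w
  csum_n <- cumsum(cnt)
  csum_x <- cumsum(cnt * centers)
  midpoint <- function(s) {
    n1 <- csum_n[s]; n2 <- csum_n[nbins] - n1
    if (n1 == 0 || n2 == 0) return(NA_real_)
    m1 <- csum_x[s] / n1
    m2 <- (csum_x[nbins] - csum_x[s]) / n2
    (m1 + m2) / 2
  }
  splitOf <- function(Tval) {
    u <- (Tval - lo) / w
    min(max(floor(u + 0.5), 1L), nbins - 1L)
  }
  ## start at the bin of the global mean
  s <- splitOf(csum_x[nbins] / csum_n[nbins])
  prev <- -1L
  for (iter in 1:256) {
    Tval <- midpoint(s)
    if (is.na(Tval)) {  # empty class: nudge inward
      s <- min(max(s + if (csum_n[s] == 0) 1L else -1L, 1L), nbins - 1L)
      next
    }
    s_new <- splitOf(Tval)
    if (s_new == s) break
    if (s_new == prev) {  # period-2 cycle: keep the split nearer its map
      if (abs(s_new - (Tval - lo) / w) > abs(s - (Tval - lo) / w)) s_new <- s
      s <- s_new
      Tval <- midpoint(s)
      break
    }
    prev <- s
    s <- s_new
  }
  structure(Tval, split = s)
}

## 8-connected component of `mask` containing `seed` (c(row, col)),
## grown by vectorised dilation restricted to the mask
.floodFill8 <- function(mask, seed) {
  d <- dim(mask)
  comp <- matrix(FALSE, d[1], d[2])
  comp[seed[1], seed[2]] <- TRUE
  repeat {
    ## one-step Moore dilation: vertical pass from comp, horizontal pass
    ## from the vertical result, then restrict to the mask
    v <- comp
    v[-1, ] <- v[-1, ] | comp[-d[1], ]
    v[-d[1], ] <- v[-d[1], ] | comp[-1, ]
    g <- v
    g[, -1] <- g[, -1] | v[, -d[2]]
    g[, -d[2]] <- g[, -d[2]] | v[, -1]
    g <- g & mask
    if (identical(g, comp)) break
    comp <- g
  }
  comp
}

#' Segment the soma around a seed point
#'
#' Thresholds the frame and keeps the 8-connected supra-threshold component
#' containing the user-supplied soma seed point. The component's pixel
#' count times the pixel area gives the 2D soma area Ss.
#'
#' @param frame 2D matrix.
#' @param threshold intensity threshold; pixels strictly above it are
#'   foreground (see \code{\link{isodataThreshold}}).
#' @param seed_point c(row, col) inside the soma.
#' @param pixel_size_um pixel edge lengths c(x, y), um.
#' @return list with \code{mask} (logical matrix) and \code{ss_um2}
#'   (soma area, um^2).
#' @export
somaMask <- function(frame, threshold, seed_point,
                     pixel_size_um = c(0.41, 0.41)) {
  d <- dim(frame)
  seed_point <- as.integer(round(seed_point))
  if (any(seed_point < 1) || seed_point[1] > d[1] || seed_point[2] > d[2])
    stop("seed point outside the frame")
  mask <- frame > threshold
  if (!mask[seed_point[1], seed_point[2]])
    stop("seed point is below the threshold; no soma component")
  comp <- .floodFill8(mask, seed_point)
  list(mask = comp, ss_um2 = sum(comp) * prod(pixel_size_um[1:2]))
}

#' Normalized soma-volume time course from soma areas
#'
#' Applies the isotropic-scaling law \eqn{V_s \propto S_s^{3/2}}: the
#' normalized volume at timepoint i is
#' \eqn{100 \cdot (S_s[i]/S_s[\mathrm{ref}])^{3/2}} percent, exactly 100 at
#' the reference.
#'
#' @param ss_series soma areas, um^2.
#' @param t_series acquisition times, min.
#' @param reference_index index of the reference timepoint (volume 100\%).
#' @param fi_series optional ROI intensity series.
#' @return a \code{\linkS4class{VolumeTimecourse}}.
#' @examples
#' vt <- volumeTimecourse(c(50, 100, 200), c(0, 5, 10), 1)
#' volPercent(vt)   # 100, 283, 800
#' @export
volumeTimecourse <- function(ss_series, t_series,
                             reference_index = 1L, fi_series = NULL) {
  if (ss_series[reference_index] <= 0)
    stop("soma area at the reference timepoint must be > 0")
  vol <- 100 * (ss_series / ss_series[reference_index])^1.5
  if (is.null(fi_series)) fi_series <- rep(NA_real_, length(ss_series))
  new("VolumeTimecourse", t = as.numeric(t_series),
      vol_pct = vol, fi = as.numeric(fi_series),
      ss = as.numeric(ss_series),
      reference_index = as.integer(reference_index))
}

## pixel mask of a circular ROI; pixel centers within the radius count
.roiMask <- function(d, center, radius_px) {
  dy <- outer(seq_len(d[1]) - center[1], rep(1, d[2]))
  dx <- outer(rep(1, d[1]), seq_len(d[2]) - center[2])
  sqrt(dy^2 + dx^2) <= radius_px
}

#' Integral fluorescence intensity in a circular ROI
#'
#' Sums pixel intensities within a circular ROI (a ~2 um disc placed
#' inside the soma in the standard protocol) in every frame. A pixel
#' belongs to the ROI when its center lies within the radius.
#'
#' @param frames list of 2D matrices (or one matrix).
#' @param center ROI center, c(row, col), px.
#' @param diameter_um ROI diameter, um.
#' @param pixel_size_um pixel edge lengths c(x, y), um.
#' @return numeric vector of per-frame integral intensities.
#' @export
roiIntensity <- function(frames, center, diameter_um = 2,
                         pixel_size_um = c(0.41, 0.41)) {
  if (is.matrix(frames)) frames <- list(frames)
  d <- dim(frames[[1]])
  r_px <- diameter_um / 2 / mean(pixel_size_um[1:2])
  if (center[1] - r_px < 1 || center[1] + r_px > d[1] ||
      center[2] - r_px < 1 || center[2] + r_px > d[2])
    stop("ROI clipped by the frame border")
  m <- .roiMask(d, center, r_px)
  vapply(frames, function(f) sum(f[m]), 0)
}

#' Fluorescence-positive area fraction and mean gray value in a region
#'
#' Segments the pixels inside \code{region_mask} with the Isodata
#' threshold computed from that region's own histogram, and reports the
#' fraction of the region that is fluorescence-positive together with the
#' mean gray value of the segmented (positive) pixels only.
#'
#' @param frame 2D matrix.
#' @param region_mask logical matrix of the same shape, non-empty.
#' @param threshold optional fixed threshold; when NULL (default) the
#'   Isodata threshold of the region's histogram is used, which requires a
#'   non-constant region.
#' @return list with \code{fraction} (in [0, 1]), \code{mean_gray}
#'   (mean intensity of positive pixels) and \code{threshold}.
#' @export
areaFraction <- function(frame, region_mask, threshold = NULL) {
  if (!any(region_mask)) stop("region mask is empty")
  vals <- frame[region_mask]
  thr <- if (is.null(threshold))
    isodataThreshold(vals)   # errors on a constant region
  else threshold
  pos <- vals > thr
  list(fraction = mean(pos), mean_gray = mean(vals[pos]),
       threshold = as.numeric(thr))
}

#' Full morphometry pipeline for one cell
#'
#' Runs the standard analysis on an \code{\linkS4class{ImageTimeSeries}}:
#' average-intensity projection per stack, translation registration to the
#' first frame, linear photobleach correction from the baseline stacks,
#' per-frame Isodata segmentation of the soma around a seed point, ROI
#' intensity measurement and conversion of soma areas to the normalized
#' volume time course. The reference timepoint (volume = 100\%) defaults
#' to the last baseline stack, i.e. t = 0 of the treatment.
#'
#' @param its an \code{\linkS4class{ImageTimeSeries}}.
#' @param seed_point soma seed c(row, col) in the reference frame.
#' @param roi_center ROI center, defaults to the seed point.
#' @param roi_diameter_um ROI diameter, um.
#' @param reference_index reference timepoint; defaults to
#'   \code{nBaseline(its)}.
#' @return a \code{\linkS4class{VolumeTimecourse}}; per-frame masks and
#'   thresholds are attached as attribute \code{"detail"}.
#' @export
analyzeCellSeries <- function(its, seed_point, roi_center = seed_point,
                              roi_diameter_um = 2,
                              reference_index = nBaseline(its)) {
  stopifnot(is(its, "ImageTimeSeries"))
  proj <- lapply(its@stacks, averageProjection)
  reg <- registerTimestack(proj)
  bc <- bleachCorrect(reg$frames, nBaseline(its))
  px <- its@voxel_size[1:2]
  seg <- lapply(bc$frames, function(f) {
    thr <- isodataThreshold(f)
    somaMask(f, thr, seed_point, pixel_size_um = px)
  })
  ss <- vapply(seg, `[[`, 0, "ss_um2")
  fi <- roiIntensity(bc$frames, roi_center, roi_diameter_um,
                     pixel_size_um = px)
  vt <- volumeTimecourse(ss, timePoints(its), reference_index, fi)
  attr(vt, "detail") <- list(shifts = reg$shifts,
                             bleach_factors = bc$factors,
                             masks = lapply(seg, `[[`, "mask"))
  vt
}
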