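# Projection, registration, bleach correction, Isodata segmentation,
# soma area / volume law, ROI intensity, area fraction.

gaussianScene <- function(d = c(128, 128)) {
  yy <- outer(seq_len(d[1]), rep(1, d[2]))
  xx <- t(outer(seq_len(d[2]), rep(1, d[1])))
  0.9 * exp(-((yy - 60)^2 + (xx - 70)^2) / 128) +
    0.6 * exp(-((yy - 40)^2 + (xx - 40)^2) / 50) +
    0.4 * exp(-((yy - 90)^2 + (xx - 55)^2) / 200)
}

test_that("average projection is the pixelwise z-mean", {
  expect_equal(averageProjection(array(5, c(4, 4, 3))), matrix(5, 4, 4))
  two <- array(c(rep(0, 9), rep(4, 9)), c(3, 3, 2))
  expect_equal(averageProjection(two), matrix(2, 3, 3))
  # projection mass equals voxel sum / n_slices (summation oracle)
  set.seed(2)
  st <- array(runif(16 * 16 * 7), c(16, 16, 7))
  expect_equal(sum(averageProjection(st)), sum(st) / 7, tolerance = 1e-12)
  expect_error(averageProjection(matrix(1, 2, 2)), "3D")
})

test_that("registration recovers known integer and subpixel shifts", {
  ref <- gaussianScene()
  r0 <- registerTimestack(list(ref, ref))
  expect_equal(unname(r0$shifts[2, ]), c(0, 0), tolerance = 1e-6)
  shifted <- ECSmorph:::.fourierShift(ref, 3, -2)
  r1 <- registerTimestack(list(ref, shifted))
  expect_lt(max(abs(r1$shifts[2, ] - c(3, -2))), 0.1)
  # aligned frame reproduces the reference up to interpolation error
  expect_lt(max(abs(r1$frames[[2]] - ref)) / max(ref), 0.01)
  sub <- ECSmorph:::.fourierShift(ref, 0.5, 0.5)
  r2 <- registerTimestack(list(ref, sub))
  expect_lt(max(abs(r2$shifts[2, ] - c(0.5, 0.5))), 0.2)
  expect_warning(registerTimestack(list(matrix(1, 8, 8), matrix(1, 8, 8))),
                 "featureless")
})

test_that("bleach correction flattens a linear decay and guards inputs", {
  scene <- gaussianScene(c(64, 64))
  # 2% per stack linear decay on a static scene
  frames <- lapply(0:8, function(i) scene * (1 - 0.02 * i))
  bc <- bleachCorrect(frames, n_baseline = 3)
  tot <- vapply(bc$frames, sum, 0)
  expect_lt(max(abs(tot / tot[1] - 1)), 0.001)
  # no decay: frames unchanged
  flat <- bleachCorrect(lapply(1:4, function(i) scene), n_baseline = 3)
  expect_equal(flat$frames[[4]], scene, tolerance = 1e-12)
  # increasing baseline cannot be bleaching
  grow <- lapply(0:3, function(i) scene * (1 + 0.05 * i))
  expect_warning(bleachCorrect(grow, 3), "capping")
  expect_error(bleachCorrect(frames, n_baseline = 1), ">= 2")
})

test_that("Isodata threshold is the intermeans fixed point", {
  # two-valued frame: the fixed point is midway between the values
  thr <- isodataThreshold(c(rep(10, 50), rep(200, 50)))
  expect_equal(as.numeric(thr), 105, tolerance = (200 - 10) / 256)
  # matches the exhaustive fixed-point search on random 8-bit frames
  set.seed(9)
  for (i in 1:20) {
    v <- sample(0:255, 48 * 48, replace = TRUE,
                prob = 0.5 * dnorm(0:255, 60, 30) +
                       0.5 * dnorm(0:255, 180, 40))
    got <- attr(isodataThreshold(v), "split")
    fixed <- isodataFixedPoints(v)
    expect_true(got %in% fixed)
  }
  # scale equivariance (up to histogram-bin resolution)
  set.seed(10)
  v <- runif(2000, 0, 1)
  expect_equal(as.numeric(isodataThreshold(v * 7)),
               7 * as.numeric(isodataThreshold(v)),
               tolerance = 7 / 256)
  expect_error(isodataThreshold(rep(3, 100)), "constant")
})

test_that("soma segmentation measures a disk and respects connectivity", {
  d <- c(64, 64)
  yy <- outer(seq_len(d[1]), rep(1, d[2]))
  xx <- t(outer(seq_len(d[2]), rep(1, d[1])))
  frame <- matrix(0, d[1], d[2])
  frame[(yy - 32)^2 + (xx - 32)^2 <= 10^2] <- 1
  sm <- somaMask(frame, 0.5, c(32, 32), pixel_size_um = c(0.41, 0.41))
  analytic <- pi * (10 * 0.41)^2
  boundary <- 2 * pi * 10 * 0.41^2     # one pixel ring of slack
  expect_lt(abs(sm$ss_um2 - analytic), boundary)
  # two disjoint blobs: only the seeded one is counted
  frame[(yy - 10)^2 + (xx - 55)^2 <= 4^2] <- 1
  sm2 <- somaMask(frame, 0.5, c(32, 32))
  expect_false(any(sm2$mask[(yy - 10)^2 + (xx - 55)^2 <= 4^2]))
  # seed on background
  expect_error(somaMask(matrix(0, 8, 8), 0.5, c(4, 4)), "below the threshold")
  expect_error(somaMask(frame, 0.5, c(200, 4)), "outside")
})

test_that("volume law: vol_pct = 100 (ss/ss_ref)^{3/2}", {
  vt <- volumeTimecourse(c(50, 50, 200), c(0, 5, 10), reference_index = 1)
  expect_equal(volPercent(vt), c(100, 100, 800))
  # isotropy: linear scale f multiplies ss by f^2 and vol by f^3
  f <- 1.3
  ss0 <- 75
  vt2 <- volumeTimecourse(c(ss0, ss0 * f^2), c(0, 5), 1)
  expect_equal(volPercent(vt2)[2], 100 * f^3, tolerance = 1e-12)
  expect_error(volumeTimecourse(c(0, 10), c(0, 5), 1), "> 0")
})

test_that("ROI intensity sums a rasterized circle", {
  frame <- matrix(2, 32, 32)
  fi <- roiIntensity(frame, center = c(16, 16), diameter_um = 2,
                     pixel_size_um = c(0.41, 0.41))
  k <- rasterCircleCount(dim(frame), c(16, 16), 1 / 0.41)
  expect_equal(fi, 2 * k)
  expect_equal(roiIntensity(frame * 2, c(16, 16)), 2 * fi)
  expect_error(roiIntensity(frame, c(1, 16)), "border")
})

test_that("area fraction and mean gray value in a region", {
  region <- matrix(TRUE, 40, 40)
  half <- cbind(matrix(10, 40, 20), matrix(200, 40, 20))
  af <- areaFraction(half, region)
  expect_equal(af$fraction, 0.5, tolerance = 0.01)
  expect_equal(af$mean_gray, 200)
  expect_gte(af$mean_gray, mean(half))
  # fully positive region under a fixed threshold
  expect_equal(areaFraction(half, half > 100, threshold = 50)$fraction, 1)
  expect_error(areaFraction(matrix(5, 4, 4), region[1:4, 1:4]), "constant")
  expect_error(areaFraction(half, region & FALSE), "empty")
})

test_that("registration and bleach correction commute on static scenes", {
  # blobs must sit well inside the border: mass drifting off the field
  # is lost by real resampling but wrapped by the Fourier phantom shift
  scene <- gaussianScene(c(128, 128))
  frames <- lapply(0:4, function(i)
    ECSmorph:::.fourierShift(scene, 0.4 * i, -0.3 * i) * (1 - 0.02 * i))
  a <- bleachCorrect(registerTimestack(frames)$frames, 3)$frames
  b_bc <- bleachCorrect(frames, 3)
  b <- registerTimestack(b_bc$frames)$frames
  fiA <- roiIntensity(a, c(60, 70), 4)
  fiB <- roiIntensity(b, c(60, 70), 4)
  expect_lt(max(abs(fiA / fiB - 1)), 0.005)
})
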