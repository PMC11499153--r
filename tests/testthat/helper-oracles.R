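# Independent oracles used across the suite. These deliberately share no
# code with the implementation paths they check.

# Exhaustive intermeans search: all split bins s (background = bins <= s)
# that are fixed points of the intermeans map on a 256-bin histogram of
# the data's min-max range, using the same bin-unit round-half-up map as
# the iterative algorithm but found by brute force over every candidate.
isodataFixedPoints <- function(v, nbins = 256L) {
  v <- as.numeric(v)
  lo <- min(v); hi <- max(v)
  w <- (hi - lo) / nbins
  bin <- pmin(nbins, floor((v - lo) / w) + 1L)
  cnt <- tabulate(bin, nbins)
  centers <- lo + (seq_len(nbins) - 0.5) * w
  fixed <- integer(0)
  for (s in 1:(nbins - 1L)) {
    n1 <- sum(cnt[1:s]); n2 <- sum(cnt) - n1
    if (n1 == 0 || n2 == 0) next
    m1 <- sum(cnt[1:s] * centers[1:s]) / n1
    m2 <- sum(cnt[(s + 1):nbins] * centers[(s + 1):nbins]) / n2
    u <- ((m1 + m2) / 2 - lo) / w
    if (min(max(floor(u + 0.5), 1L), nbins - 1L) == s)
      fixed <- c(fixed, s)
  }
  fixed
}

# Brute-force pixel-in-circle count: loop over every pixel center.
rasterCircleCount <- function(d, center, radius_px) {
  k <- 0L
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    if (sqrt((i - center[1])^2 + (j - center[2])^2) <= radius_px)
      k <- k + 1L
  k
}

# Free-medium closed form written independently of the package model.
freeMediumConc <- function(r, t, Q, D) {
  ifelse(t > 0, Q / (4 * pi * D * r) * pracma::erfc(r / (2 * sqrt(D * t))),
         0)
}
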