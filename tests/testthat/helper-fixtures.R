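# Shared fixture builders; everything is generated in code.

# solid horizontal bar mask: width px tall, len px long
bar_mask <- function(nrow = 40, ncol = 120, width = 10, len = 100) {
  m <- matrix(FALSE, nrow, ncol)
  r0 <- floor((nrow - width) / 2) + 1
  c0 <- floor((ncol - len) / 2) + 1
  m[r0:(r0 + width - 1), c0:(c0 + len - 1)] <- TRUE
  m
}

# plus sign: two crossing bars sharing their center
plus_mask <- function(size = 120, width = 10, len = 100) {
  m <- matrix(FALSE, size, size)
  c0 <- floor((size - len) / 2) + 1
  r0 <- floor((size - width) / 2) + 1
  m[r0:(r0 + width - 1), c0:(c0 + len - 1)] <- TRUE
  m[c0:(c0 + len - 1), r0:(r0 + width - 1)] <- TRUE
  m
}

# brute-force triangle threshold: explicit perpendicular point-line
# distance maximized over all bins on the tail side
triangle_oracle <- function(image, n_bins = 256) {
  x <- as.numeric(image)
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  h <- tabulate(bin, nbins = n_bins)
  peak <- which.max(h)
  nz <- which(h > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  right <- (hi - peak) >= (peak - lo)
  tail_bin <- if (right) hi + 1L else lo - 1L
  bs <- if (right) seq(peak + 1L, tail_bin - 1L) else
    seq(tail_bin + 1L, peak - 1L)
  if (length(bs) == 0) bs <- peak
  # perpendicular distance from (b, h[b]) to the line through
  # (peak, h[peak]) and (tail_bin, 0), counted only below the line
  x1 <- peak; y1 <- h[peak]; x2 <- tail_bin; y2 <- 0
  dist <- vapply(bs, function(b) {
    num <- (y2 - y1) * b - (x2 - x1) * h[b] + x2 * y1 - y2 * x1
    d <- abs(num) / sqrt((y2 - y1)^2 + (x2 - x1)^2)
    line_at <- y1 + (y2 - y1) * (b - x1) / (x2 - x1)
    if (h[b] > line_at) -d else d
  }, numeric(1))
  best <- bs[which.max(dist)]
  breaks[best + 1L]
}

# default sparse network parameters used in topology-recovery tests
sparse_net_params <- function(seed, shape = c(512, 512), n_segments = 8) {
  vessel_network_params(image_shape = shape, n_segments = n_segments,
                        target_coverage = NULL, noise_sd = 0,
                        segment_length_range = c(60, 150), seed = seed)
}
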