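# Vessel morphometry: projection, triangle threshold, mask cleanup,
# skeletonization, skeleton statistics and derived network metrics.

#' Maximum intensity projection of a z-stack
#'
#' @param zstack Numeric array `rows x cols x slices` (a matrix is treated
#'   as a single slice).
#' @return A matrix with the per-pixel maximum across slices.
#' @export
max_projection <- function(zstack) {
  if (is.matrix(zstack)) return(zstack)
  if (length(dim(zstack)) != 3L) abort("`zstack` must be a 3D array.")
  apply(zstack, c(1, 2), max)
}

#' Triangle threshold of an intensity image
#'
#' Implements the triangle algorithm on a 256-bin histogram: a line is
#' drawn from the histogram peak to the farthest empty tail bin, and the
#' threshold is placed at the bin maximizing the perpendicular distance
#' between the line and the histogram. The longer tail is used when the
#' peak is not at a histogram end.
#'
#' @param image Numeric matrix with at least two distinct values.
#' @param n_bins Number of histogram bins.
#' @return A list with `threshold` (intensity value; foreground is
#'   `image > threshold`), `tail` (`"left"` or `"right"`), and `bin`.
#' @export
triangle_threshold <- function(image, n_bins = 256) {
  x <- as.numeric(as_image_matrix(image))
  rng <- range(x)
  if (diff(rng) == 0) abort("constant image: threshold undefined.")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L),
              n_bins)
  h <- tabulate(bin, nbins = n_bins)
  peak <- which.max(h)
  nz <- which(h > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  tail_side <- if ((hi - peak) >= (peak - lo)) "right" else "left"
  tail_bin <- if (tail_side == "right") hi + 1L else lo - 1L
  # maximize distance below the line from (peak, h_peak) to (tail_bin, 0);
  # the perpendicular distance is proportional to line(b) - h(b)
  bs <- if (tail_side == "right") seq(peak + 1L, tail_bin - 1L) else
    seq(tail_bin + 1L, peak - 1L)
  if (length(bs) == 0) bs <- peak
  line_h <- h[peak] * (bs - tail_bin) / (peak - tail_bin)
  d <- line_h - h[bs]
  best <- bs[which.max(d)]
  thr <- breaks[best + 1L]  # upper edge of the selected bin
  list(threshold = thr, tail = tail_side, bin = best)
}

#' Segment vessels from a projected image
#'
#' The mask pipeline applied to CD31 maximum projections: Gaussian blur
#' (sigma 2 px), triangle threshold, binary erosion (3x3 cross) and
#' bright-outlier removal by a binary median despeckle filter. Every
#' parameter and the threshold used are recorded in the provenance.
#'
#' @param projection Numeric matrix (a maximum projection).
#' @param pixel_size um per pixel.
#' @param blur_sigma Gaussian blur sigma in px.
#' @param erode_iters Binary erosion iterations with a 3x3 cross. The
#'   default (3) is calibrated on synthetic renders so that the
#'   blur + triangle-threshold step, which admits the dim halo around
#'   vessels, is compensated and the recovered area fraction is unbiased.
#' @param outlier_radius Median despeckle radius in px (0 disables).
#' @return A `vessel_mask` object: list with `mask` (logical matrix),
#'   `pixel_size`, `provenance` and `empty` flag.
#' @export
preprocess_mask <- function(projection, pixel_size, blur_sigma = 2,
                            erode_iters = 3, outlier_radius = 2) {
  img <- as_image_matrix(projection, "projection")
  check_number(pixel_size, "pixel_size", positive = TRUE)
  blurred <- if (blur_sigma > 0)
    as.matrix(EBImage::gblur(img, sigma = blur_sigma)) else img
  tri <- triangle_threshold(blurred)
  m <- blurred > tri$threshold
  if (erode_iters > 0) {
    kern <- EBImage::makeBrush(3, shape = "diamond")
    mm <- matrix(as.numeric(m), nrow(m), ncol(m))
    for (i in seq_len(erode_iters)) mm <- as.matrix(EBImage::erode(mm, kern))
    m <- mm > 0.5
  }
  if (outlier_radius > 0) {
    mm <- matrix(as.numeric(m), nrow(m), ncol(m))
    mm <- as.matrix(EBImage::medianFilter(mm, size = outlier_radius))
    m <- mm > 0.5
  }
  res <- structure(list(
    mask = m, pixel_size = pixel_size,
    provenance = list(threshold = tri$threshold, tail = tri$tail,
                      blur_sigma = blur_sigma, erode_iters = erode_iters,
                      outlier_radius = outlier_radius),
    empty = !any(m)
  ), class = "vessel_mask")
  if (res$empty) warn("preprocess_mask produced an empty mask.")
  res
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %d x %d px, %.1f%% foreground, %g um/px%s\n",
              nrow(x$mask), ncol(x$mask), 100 * mean(x$mask), x$pixel_size,
              if (x$empty) " [EMPTY]" else ""))
  invisible(x)
}

# One Zhang-Suen subiteration; returns the updated logical matrix.
zs_subiter <- function(m, step) {
  mm <- matrix(as.numeric(m), nrow(m), ncol(m))
  # neighbours in Zhang-Suen order P2..P9 = N, NE, E, SE, S, SW, W, NW
  p <- list(
    shift_mat(mm, 1, 0),  shift_mat(mm, 1, -1), shift_mat(mm, 0, -1),
    shift_mat(mm, -1, -1), shift_mat(mm, -1, 0), shift_mat(mm, -1, 1),
    shift_mat(mm, 0, 1),  shift_mat(mm, 1, 1)
  )
  b <- Reduce(`+`, p)
  a <- matrix(0, nrow(mm), ncol(mm))
  for (i in 1:8) {
    j <- if (i == 8) 1 else i + 1
    a <- a + (p[[i]] == 0 & p[[j]] == 1)
  }
  if (step == 1) {
    c1 <- p[[1]] * p[[3]] * p[[5]] == 0
    c2 <- p[[3]] * p[[5]] * p[[7]] == 0
  } else {
    c1 <- p[[1]] * p[[3]] * p[[7]] == 0
    c2 <- p[[1]] * p[[5]] * p[[7]] == 0
  }
  del <- m & b >= 2 & b <= 6 & a == 1 & c1 & c2
  m & !del
}

# Yokoi connectivity number for 8-connectivity, vectorised over the whole
# image: the number of foreground components in the 8-neighbourhood that
# touch the pixel. A pixel with C8 == 1 is simple (deletable without
# changing connectivity).
yokoi_c8 <- function(mm) {
  # x1..x8 = E, NE, N, NW, W, SW, S, SE (x = foreground indicator)
  x <- list(
    shift_mat(mm, 0, -1), shift_mat(mm, 1, -1), shift_mat(mm, 1, 0),
    shift_mat(mm, 1, 1), shift_mat(mm, 0, 1), shift_mat(mm, -1, 1),
    shift_mat(mm, -1, 0), shift_mat(mm, -1, -1)
  )
  xb <- lapply(x, function(v) 1 - v)
  c8 <- 0
  for (k in c(1, 3, 5, 7)) {
    k1 <- if (k == 7) 8 else k + 1
    k2 <- if (k == 7) 1 else k + 2
    c8 <- c8 + xb[[k]] - xb[[k]] * xb[[k1]] * xb[[k2]]
  }
  c8
}

#' Skeletonize a binary vessel mask
#'
#' Morphological thinning (Zhang-Suen) to a 1-px-wide, 8-connected medial
#' skeleton, followed by removal of residual staircase/block redundancy:
#' simple non-endpoint pixels (Yokoi connectivity number 1) touching the
#' 4-connected background are deleted until stable, which preserves the
#' connected-component count of the mask. Runs in compiled code.
#'
#' @param mask A `vessel_mask` object or logical matrix.
#' @param prune_px When > 0, terminal skeleton branches shorter than this
#'   many pixels that hang off a junction are removed after thinning; such
#'   spurs are artifacts of thinning wide tubes at corners and joints.
#'   0 (default) keeps the raw thinning result.
#' @return A logical matrix of skeleton pixels.
#' @export
skeletonize_2d <- function(mask, prune_px = 0) {
  m <- if (inherits(mask, "vessel_mask")) mask$mask else mask > 0
  if (!any(m)) return(m)
  m <- .zs_thin_cpp(m)
  if (prune_px > 0) m <- prune_spurs(m, prune_px)
  m
}

# Pure-R reference thinning (Zhang-Suen + subfield redundancy removal);
# slow, retained as an independent check of the compiled implementation.
thin_r <- function(m) {
  repeat {
    m1 <- zs_subiter(m, 1)
    m2 <- zs_subiter(m1, 2)
    if (identical(m2, m)) break
    m <- m2
  }
  rows <- matrix(seq_len(nrow(m)), nrow(m), ncol(m))
  cols <- matrix(seq_len(ncol(m)), nrow(m), ncol(m), byrow = TRUE)
  repeat {
    changed <- FALSE
    for (sr in 0:1) for (sc in 0:1) {
      mm <- matrix(as.numeric(m), nrow(m), ncol(m))
      nb <- neighbor_count(m)
      bg4 <- (1 - shift_mat(mm, 1, 0)) + (1 - shift_mat(mm, -1, 0)) +
        (1 - shift_mat(mm, 0, 1)) + (1 - shift_mat(mm, 0, -1))
      del <- m & nb >= 2 & nb <= 6 & yokoi_c8(mm) == 1 & bg4 > 0 &
        rows %% 2 == sr & cols %% 2 == sc
      if (any(del)) {
        m <- m & !del
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

# Remove terminal skeleton branches (endpoint-bearing components of the
# skeleton minus its junction pixels) shorter than `min_px` pixels, when
# they are attached to a junction. Repeats until stable: removing a spur
# can downgrade its junction to a regular path pixel.
prune_spurs <- function(m, min_px) {
  repeat {
    nb <- neighbor_count(m)
    junc <- m & nb >= 3
    if (!any(junc)) return(m)
    lab <- label_components8(m & !junc)
    if (lab$no == 0L) return(m)
    has_end <- tapply(nb[lab$idx] == 1, lab$membership, any)
    size <- tabulate(lab$membership, nbins = lab$no)
    # components touching a junction pixel (8-neighbourhood dilation)
    near_junc <- neighbor_count(junc) > 0
    touch_px <- near_junc[lab$idx]
    touches <- logical(lab$no)
    touches[unique(lab$membership[touch_px])] <- TRUE
    kill <- which(as.logical(has_end) & touches & size < min_px)
    if (length(kill) == 0) return(m)
    m[lab$idx[lab$membership %in% kill]] <- FALSE
  }
}


#' Skeleton topology and length statistics
#'
#' Endpoints are skeleton pixels with exactly one 8-connected skeleton
#' neighbour; junction pixels have three or more, and 8-adjacent junction
#' pixels are merged into a single junction. Total length sums adjacent
#' pixel steps (1 px orthogonal, sqrt(2) px diagonal), counting a diagonal
#' step only when its two orthogonal intermediates are absent so that
#' staircase corners are not double-counted.
#'
#' @param skeleton Logical matrix from [skeletonize_2d()].
#' @param pixel_size um per pixel.
#' @return A one-row tibble of class `skeleton_stats`: `total_length` (um),
#'   `n_junctions`, `n_endpoints`, `n_branches`.
#' @export
skeleton_stats <- function(skeleton, pixel_size) {
  check_number(pixel_size, "pixel_size", positive = TRUE)
  m <- skeleton > 0
  if (!any(m)) {
    out <- tibble::tibble(total_length = 0, n_junctions = 0L,
                          n_endpoints = 0L, n_branches = 0L)
    class(out) <- c("skeleton_stats", class(out))
    return(out)
  }
  nb <- neighbor_count(m)
  endpoints <- sum(m & nb == 1)
  junc <- m & nb >= 3
  idx <- which(junc)
  nr <- nrow(m)
  n_junctions <- cluster_count8(((idx - 1L) %% nr) + 1L,
                                ((idx - 1L) %/% nr) + 1L)
  mm <- matrix(as.numeric(m), nr, ncol(m))
  east <- shift_mat(mm, 0, -1)   # value of (r, c+1) at (r, c)
  south <- shift_mat(mm, -1, 0)  # (r+1, c)
  se <- shift_mat(mm, -1, -1)    # (r+1, c+1)
  ne <- shift_mat(mm, 1, -1)     # (r-1, c+1)
  north <- shift_mat(mm, 1, 0)   # (r-1, c)
  orth <- sum(mm * east) + sum(mm * south)
  diag_se <- sum(mm * se * (1 - east) * (1 - south))
  diag_ne <- sum(mm * ne * (1 - east) * (1 - north))
  total_len <- (orth + sqrt(2) * (diag_se + diag_ne)) * pixel_size
  branches <- count_components8(m & !junc)
  out <- tibble::tibble(total_length = total_len,
                        n_junctions = as.integer(n_junctions),
                        n_endpoints = as.integer(endpoints),
                        n_branches = as.integer(branches))
  class(out) <- c("skeleton_stats", class(out))
  out
}

#' Derived vessel network metrics
#'
#' Combines a vessel mask and its skeleton statistics into the four
#' morphometric readouts: vessel area fraction of the field, total network
#' length, mean diameter (total vessel area divided by total network
#' length) and connectivity (junction count divided by endpoint count,
#' undefined when there are no endpoints).
#'
#' @param mask A `vessel_mask` object.
#' @param stats A `skeleton_stats` row computed from the same mask.
#' @return A one-row tibble of class `vessel_metrics`: `area_fraction`,
#'   `total_length` (um), `mean_diameter` (um), `connectivity`,
#'   `n_junctions`, `n_endpoints`, `degenerate` flag.
#' @export
vessel_metrics <- function(mask, stats) {
  stopifnot(inherits(mask, "vessel_mask"))
  area_px <- sum(mask$mask)
  area_um2 <- area_px * mask$pixel_size^2
  area_fraction <- area_px / length(mask$mask)
  degenerate <- stats$total_length == 0 && area_px > 0
  if (degenerate) warn("zero skeleton length with nonzero area.")
  out <- tibble::tibble(
    area_fraction = area_fraction,
    total_length = stats$total_length,
    mean_diameter = if (stats$total_length > 0)
      area_um2 / stats$total_length else NA_real_,
    connectivity = if (stats$n_endpoints > 0)
      stats$n_junctions / stats$n_endpoints else NA_real_,
    n_junctions = stats$n_junctions,
    n_endpoints = stats$n_endpoints,
    degenerate = degenerate
  )
  class(out) <- c("vessel_metrics", class(out))
  out
}

#' Full vessel morphometry pipeline on a projected image
#'
#' Chains [preprocess_mask()], [skeletonize_2d()], [skeleton_stats()] and
#' [vessel_metrics()].
#'
#' @inheritParams preprocess_mask
#' @param prune_factor Spur-pruning scale: terminal skeleton branches
#'   shorter than `prune_factor` times the provisional mean diameter
#'   (area / raw skeleton length) are treated as thinning artifacts and
#'   removed. 0 disables pruning.
#' @param ... Passed to [preprocess_mask()].
#' @return A `vessel_metrics` tibble (one row).
#' @export
analyze_vessels <- function(projection, pixel_size, prune_factor = 1.2, ...) {
  vm <- preprocess_mask(projection, pixel_size = pixel_size, ...)
  sk <- skeletonize_2d(vm)
  st <- skeleton_stats(sk, pixel_size = pixel_size)
  if (prune_factor > 0 && st$total_length > 0) {
    d_hat_px <- sum(vm$mask) * pixel_size / st$total_length
    sk <- prune_spurs(sk, prune_factor * d_hat_px)
    st <- skeleton_stats(sk, pixel_size = pixel_size)
  }
  vessel_metrics(vm, st)
}

#' Fraction of liposome signal outside the vasculature
#'
#' Thresholds the liposome channel (triangle threshold by default) and
#' reports the fraction of liposome-positive pixels falling outside the
#' vessel mask, optionally dilated to absorb registration slack at the
#' vessel wall.
#'
#' @param liposome Numeric matrix (liposome channel, projected).
#' @param vessel_mask Logical matrix or `vessel_mask` object.
#' @param positive_threshold `"triangle"` or a numeric threshold; pixels
#'   strictly above it are liposome-positive.
#' @param dilation_px Disc radius (px) by which the vessel mask is dilated
#'   before counting (default 1; 0 disables).
#' @return A one-row tibble: `extravascular_fraction`, `n_positive`,
#'   `n_outside`, `undefined` flag (no positive pixels).
#' @export
extravascular_fraction <- function(liposome, vessel_mask,
                                   positive_threshold = "triangle",
                                   dilation_px = 1) {
  img <- as_image_matrix(liposome, "liposome")
  mask <- if (inherits(vessel_mask, "vessel_mask")) vessel_mask$mask else
    vessel_mask > 0
  if (!identical(dim(img), dim(mask)))
    abort("liposome image and vessel mask must have the same shape.")
  thr <- if (identical(positive_threshold, "triangle"))
    triangle_threshold(img)$threshold else as.numeric(positive_threshold)
  pos <- img > thr
  n_pos <- sum(pos)
  if (n_pos == 0) {
    warn("no liposome-positive pixels; fraction undefined.")
    return(tibble::tibble(extravascular_fraction = NA_real_, n_positive = 0L,
                          n_outside = 0L, undefined = TRUE))
  }
  if (dilation_px > 0) {
    kern <- EBImage::makeBrush(2 * dilation_px + 1, shape = "disc")
    mm <- as.matrix(EBImage::dilate(matrix(as.numeric(mask), nrow(mask),
                                           ncol(mask)), kern))
    mask <- mm > 0.5
  }
  n_out <- sum(pos & !mask)
  tibble::tibble(extravascular_fraction = n_out / n_pos,
                 n_positive = as.integer(n_pos),
                 n_outside = as.integer(n_out), undefined = FALSE)
}

#' Mean intensity of a region of interest
#'
#' For z-stacks a maximum projection is taken first.
#'
#' @param image Matrix or `rows x cols x slices` array.
#' @param roi Either `c(xmin, xmax, ymin, ymax)` (inclusive pixel bounds,
#'   `x` = column) or a logical matrix.
#' @return Mean pixel value in the ROI.
#' @export
roi_mean_intensity <- function(image, roi) {
  img <- if (is.matrix(image)) image else max_projection(image)
  if (is.matrix(roi)) {
    if (!any(roi)) abort("empty ROI.")
    return(mean(img[roi > 0]))
  }
  stopifnot(length(roi) == 4)
  if (roi[1] > roi[2] || roi[3] > roi[4] ||
      roi[1] < 1 || roi[2] > ncol(img) || roi[3] < 1 || roi[4] > nrow(img))
    abort("empty ROI or ROI outside image bounds.")
  mean(img[roi[3]:roi[4], roi[1]:roi[2]])
}
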