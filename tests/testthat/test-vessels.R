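# Vessel morphometry: projection, triangle threshold, mask pipeline,
# skeletonization and network metrics.

test_that("max projection equals the brute-force per-pixel maximum", {
  one <- matrix(3, 5, 5)
  expect_identical(max_projection(array(one, c(5, 5, 1))), one)
  st <- array(0, c(4, 4, 2)); st[, , 2] <- 5
  expect_identical(max_projection(st), matrix(5, 4, 4))
  set.seed(2)
  rnd <- array(runif(6 * 7 * 5), c(6, 7, 5))
  expect_equal(max_projection(rnd), apply(rnd, c(1, 2), max))
})

test_that("triangle threshold separates a two-valued image", {
  img <- matrix(10, 50, 50)
  img[1:5, ] <- 200  # 10% bright
  tt <- triangle_threshold(img)
  expect_gt(tt$threshold, 10)
  expect_lt(tt$threshold, 200)
  expect_error(triangle_threshold(matrix(1, 4, 4)), "constant")
})

test_that("triangle threshold lands in the valley of a bimodal histogram", {
  set.seed(5)
  img <- matrix(c(rnorm(7000, 30, 10), rnorm(3000, 180, 10)), 100, 100)
  tt <- triangle_threshold(img)
  expect_equal(tt$threshold, triangle_oracle(img))
  expect_gt(tt$threshold, 55)
  expect_lt(tt$threshold, 150)
})

test_that("triangle threshold equals the brute-force geometric oracle", {
  set.seed(11)
  for (i in 1:20) {
    img <- switch(1 + i %% 4,
      matrix(rnorm(2500, 50, 20), 50, 50),
      matrix(c(rnorm(2000, 20, 5), rnorm(500, 150, 30)), 50, 50),
      matrix(c(rexp(2200, 1 / 30), rnorm(300, 200, 10)), 50, 50),
      # peak at the bright end: tail-selection flips to the left
      matrix(c(rnorm(2200, 220, 6), runif(300, 0, 180)), 50, 50))
    expect_equal(triangle_threshold(img)$threshold, triangle_oracle(img),
                 info = paste("case", i))
  }
})

test_that("mask preprocessing recovers a clean render and its provenance", {
  p <- vessel_network_params(image_shape = c(512, 512),
                             target_coverage = 0.645, noise_sd = 0, seed = 6)
  net <- gen_vessel_network(p)
  vm <- preprocess_mask(net$image, pixel_size = 1)
  iou <- sum(vm$mask & net$mask) / sum(vm$mask | net$mask)
  expect_gt(iou, 0.85)
  expect_named(vm$provenance,
               c("threshold", "tail", "blur_sigma", "erode_iters",
                 "outlier_radius"))
  expect_false(vm$empty)
})

test_that("despeckle removes isolated bright pixels", {
  img <- matrix(10, 64, 64)
  img[40:52, 10:60] <- 200  # one real structure
  img[5, 5] <- 255          # isolated speck
  vm <- preprocess_mask(img, pixel_size = 1, blur_sigma = 0,
                        erode_iters = 0, outlier_radius = 2)
  expect_false(vm$mask[5, 5])
  expect_true(any(vm$mask[45, 20:50]))
})

test_that("one erosion iteration narrows a bar by one pixel per side", {
  img <- matrix(10, 64, 128)
  img[28:37, 15:114] <- 200  # 10 px wide bar
  vm <- preprocess_mask(img, pixel_size = 1, blur_sigma = 0,
                        erode_iters = 1, outlier_radius = 0)
  widths <- colSums(vm$mask[, 40:90])
  expect_true(all(widths == 8))
})

test_that("thinning canonical shapes gives known skeletons", {
  sk <- skeletonize_2d(bar_mask())
  st <- skeleton_stats(sk, 1)
  expect_equal(st$n_endpoints, 2L)
  expect_equal(st$n_junctions, 0L)
  expect_true(st$total_length >= 89 && st$total_length <= 99)
  expect_identical(skeletonize_2d(matrix(FALSE, 10, 10)),
                   matrix(FALSE, 10, 10))
  single <- matrix(FALSE, 9, 9); single[5, 5] <- TRUE
  expect_identical(skeletonize_2d(single), single)
})

test_that("compiled thinning matches the pure-R reference", {
  # canonical shapes: pixel-identical
  for (m in list(bar_mask(), plus_mask())) {
    expect_identical(skeletonize_2d(m), cardiochip:::thin_r(m))
  }
  # random networks: the redundancy-removal pass visits pixels in a
  # different order, so skeletons may differ by single staircase pixels;
  # topology and length must nevertheless agree
  for (i in 1:4) {
    net <- gen_vessel_network(sparse_net_params(seed = i, shape = c(160, 160),
                                                n_segments = 3))
    a <- skeleton_stats(skeletonize_2d(net$mask), 1)
    b <- skeleton_stats(cardiochip:::thin_r(net$mask), 1)
    expect_equal(a$n_endpoints, b$n_endpoints)
    expect_equal(a$n_junctions, b$n_junctions)
    expect_lt(abs(a$total_length / b$total_length - 1), 0.01)
  }
})

test_that("skeleton statistics follow the stated length conventions", {
  line <- matrix(FALSE, 20, 120); line[10, 11:110] <- TRUE
  st <- skeleton_stats(line, pixel_size = 2)
  expect_equal(st$total_length, 99 * 2)
  expect_equal(st$n_endpoints, 2L)
  expect_equal(st$n_junctions, 0L)
  # exact plus sign drawn as 1-px lines: 4 endpoints, 1 junction
  pl <- matrix(FALSE, 61, 61)
  pl[31, 6:56] <- TRUE; pl[6:56, 31] <- TRUE
  stp <- skeleton_stats(pl, 1)
  expect_equal(stp$n_endpoints, 4L)
  expect_equal(stp$n_junctions, 1L)
  # two disjoint lines
  two <- matrix(FALSE, 20, 60)
  two[5, 6:25] <- TRUE; two[15, 30:55] <- TRUE
  st2 <- skeleton_stats(two, 1)
  expect_equal(st2$n_endpoints, 4L)
  expect_equal(st2$n_junctions, 0L)
  # diagonal adjacency counts sqrt(2)
  dg <- matrix(FALSE, 30, 30)
  for (i in 5:25) dg[i, i] <- TRUE
  expect_equal(skeleton_stats(dg, 1)$total_length, 20 * sqrt(2))
})

test_that("vessel metrics combine area, length and topology", {
  m <- bar_mask()
  vm <- structure(list(mask = m, pixel_size = 1, provenance = list(),
                       empty = FALSE), class = "vessel_mask")
  st <- skeleton_stats(skeletonize_2d(m), 1)
  met <- vessel_metrics(vm, st)
  expect_equal(met$area_fraction, sum(m) / length(m))
  expect_equal(met$mean_diameter, sum(m) / st$total_length)
  expect_true(met$mean_diameter > 10 && met$mean_diameter < 11.5)
  # plus sign: connectivity 1/4
  stp <- skeleton_stats(skeletonize_2d(plus_mask()), 1)
  vp <- structure(list(mask = plus_mask(), pixel_size = 1,
                       provenance = list(), empty = FALSE),
                  class = "vessel_mask")
  expect_equal(vessel_metrics(vp, stp)$connectivity, 0.25)
})

test_that("skeleton preserves the component count of the mask", {
  for (s in 1:5) {
    net <- gen_vessel_network(sparse_net_params(seed = s, shape = c(256, 256),
                                                n_segments = 4))
    sk <- skeletonize_2d(net$mask)
    expect_equal(cardiochip:::count_components8(sk),
                 cardiochip:::count_components8(net$mask))
  }
})

test_that("metrics scale correctly with pixel size and rotation", {
  net <- gen_vessel_network(sparse_net_params(seed = 3, shape = c(256, 256),
                                              n_segments = 5))
  sk <- skeletonize_2d(net$mask)
  st1 <- skeleton_stats(sk, 1)
  st2 <- skeleton_stats(sk, 2)
  expect_equal(st2$total_length, 2 * st1$total_length)
  vm1 <- structure(list(mask = net$mask, pixel_size = 1, provenance = list(),
                        empty = FALSE), class = "vessel_mask")
  vm2 <- structure(list(mask = net$mask, pixel_size = 2, provenance = list(),
                        empty = FALSE), class = "vessel_mask")
  m1 <- vessel_metrics(vm1, st1); m2 <- vessel_metrics(vm2, st2)
  expect_equal(m2$mean_diameter, 2 * m1$mean_diameter)
  expect_equal(m2$area_fraction, m1$area_fraction)
  expect_equal(m2$connectivity, m1$connectivity)
  # 90 degree rotation: counts exact, length within 1%
  rot <- t(net$mask)[, nrow(net$mask):1]
  str <- skeleton_stats(skeletonize_2d(rot), 1)
  expect_equal(str$n_junctions, st1$n_junctions)
  expect_equal(str$n_endpoints, st1$n_endpoints)
  expect_lt(abs(str$total_length / st1$total_length - 1), 0.01)
})

test_that("junctions and endpoints are recovered from sparse renders", {
  res <- t(sapply(1:40, function(s) {
    p <- sparse_net_params(seed = s)
    net <- gen_vessel_network(p)
    sk <- skeletonize_2d(net$mask,
                         prune_px = 1.3 * p$tube_diameter_mean / p$pixel_size)
    st <- skeleton_stats(sk, 1)
    c(tj = net$truth$derived$n_junctions, j = st$n_junctions,
      te = net$truth$derived$n_endpoints, e = st$n_endpoints)
  }))
  exact <- res[, "tj"] == res[, "j"] & res[, "te"] == res[, "e"]
  off1 <- abs(res[, "tj"] - res[, "j"]) <= 1 &
    abs(res[, "te"] - res[, "e"]) <= 1
  expect_gte(mean(exact), 0.9)
  expect_true(all(off1))
})

test_that("extravascular fraction counts positive pixels outside the mask", {
  mask <- bar_mask(64, 64, width = 20, len = 40)
  img <- matrix(10, 64, 64)
  img[mask] <- 200  # all signal inside
  expect_equal(extravascular_fraction(img, mask,
                                      dilation_px = 0)$extravascular_fraction,
               0)
  img2 <- matrix(10, 64, 64)
  img2[1, 1:30] <- 200  # all outside
  expect_equal(extravascular_fraction(img2, mask,
                                      dilation_px = 0)$extravascular_fraction,
               1)
  pr <- gen_extravasation_pair(0.618, mask, n_positive = 1000, seed = 7)
  ef <- extravascular_fraction(pr$liposome, pr$vessel_mask, dilation_px = 0)
  expect_equal(ef$extravascular_fraction, 0.618)
  # dilation absorbs wall-adjacent pixels: fraction can only decrease
  ef1 <- extravascular_fraction(pr$liposome, pr$vessel_mask, dilation_px = 2)
  expect_lte(ef1$extravascular_fraction, ef$extravascular_fraction)
  blank <- matrix(10, 64, 64)
  expect_warning(out <- extravascular_fraction(blank, mask,
                                               positive_threshold = 100),
                 "undefined")
  expect_true(out$undefined)
})

test_that("ROI mean intensity matches the brute-force mean", {
  img <- matrix(7, 12, 12)
  expect_equal(roi_mean_intensity(img, c(2, 5, 3, 8)), 7)
  img2 <- matrix(0, 10, 10); img2[1:5, ] <- 10
  expect_equal(roi_mean_intensity(img2, c(1, 10, 1, 10)), 5)
  set.seed(3)
  st <- array(runif(8 * 8 * 3), c(8, 8, 3))
  mp <- apply(st, c(1, 2), max)
  expect_equal(roi_mean_intensity(st, c(2, 6, 2, 6)),
               mean(mp[2:6, 2:6]))
  expect_error(roi_mean_intensity(img, c(5, 2, 1, 1)), "ROI")
})
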