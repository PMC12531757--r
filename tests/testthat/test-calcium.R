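# Calcium-transient analysis: trace extraction, dF/F0, beat detection and
# summary statistics, plus the recovery invariants against the generator.

test_that("ROI traces are per-frame means over the ROI", {
  movie <- array(7, dim = c(16, 16, 4))
  rois <- data.frame(roi_id = "a", xmin = 3, xmax = 6, ymin = 3, ymax = 6)
  tr <- extract_roi_traces(movie, rois, frame_interval = 0.01)
  expect_equal(tr$intensity, rep(7, 4))
  expect_equal(tr$time, (0:3) * 0.01)
  # half 0 / half 2 -> mean 1
  movie2 <- array(0, dim = c(4, 4, 2))
  movie2[1:2, , ] <- 2
  tr2 <- extract_roi_traces(movie2, data.frame(roi_id = "a", xmin = 1,
                                               xmax = 4, ymin = 1, ymax = 4),
                            frame_interval = 0.5)
  expect_equal(tr2$intensity, c(1, 1))
  # painted-trace round trip
  known <- 100 + 10 * sin(seq(0, 2 * pi, length.out = 20))
  movie3 <- array(1, dim = c(10, 10, 20))
  for (k in 1:20) movie3[3:5, 3:5, k] <- known[k]
  tr3 <- extract_roi_traces(movie3, data.frame(roi_id = "r", xmin = 3,
                                               xmax = 5, ymin = 3, ymax = 5),
                            frame_interval = 0.01)
  expect_equal(tr3$intensity, known)
  expect_error(extract_roi_traces(movie, data.frame(roi_id = "bad",
                                                    xmin = 20, xmax = 25,
                                                    ymin = 1, ymax = 2),
                                  0.01),
               "bounds")
})

test_that("dF/F0 normalization uses the requested baseline", {
  tr <- tibble::tibble(time = (0:99) / 100, intensity = rep(50, 100))
  d <- compute_dff(tr)
  expect_equal(d$dff, rep(0, 100))
  tr2 <- tibble::tibble(time = (0:9) / 10, intensity = c(rep(10, 9), 20))
  d2 <- compute_dff(tr2, f0_method = "min")
  expect_equal(d2$dff[10], 1.0)  # F = 2 F0
  # generator baseline is recovered exactly on clean traces
  p <- beat_train_params(mean_frequency = 0.5, time_to_peak = 0.1,
                         decay80 = 0.15, ibi_cv = 0, amplitude_cv = 0,
                         noise_sd = 0, baseline_f0 = 100, seed = 1)
  tr3 <- gen_calcium_trace(p)
  d3 <- compute_dff(tr3)
  expect_equal(unname(attr(d3, "f0")), 100)
  bad <- tibble::tibble(time = 0:3, intensity = c(-5, -5, -5, 1))
  expect_error(compute_dff(bad), "F0")
})

test_that("beat detection parameterizes an isolated analytic transient", {
  w <- gen_beat_waveform(time_to_peak = 0.1, decay80 = 0.4, amplitude = 1,
                         dt = 0.01)
  x <- c(rep(0, 20), w$value, rep(0, 100))
  b <- detect_beats(x, dt = 0.01, min_prominence = 0.2)
  expect_equal(nrow(b), 1)
  # onset at the 10% crossing of a linear rise starting at t = 0
  expect_equal(b$time_to_peak, 0.09, tolerance = 1e-9)
  expect_equal(b$decay80_time, 0.4, tolerance = 0.01 + 1e-9)
  expect_equal(b$amplitude, 1.0, tolerance = 1e-9)
  expect_equal(nrow(detect_beats(rep(0, 500), dt = 0.01,
                                 min_prominence = 0.1)), 0)
})

test_that("a periodic noise-free train is recovered beat for beat", {
  p <- beat_train_params(mean_frequency = 1, ibi_cv = 0, amplitude_cv = 0,
                         noise_sd = 0, time_to_peak = 0.15, decay80 = 0.35,
                         seed = 1)
  tr <- gen_calcium_trace(p)
  b <- detect_beats(compute_dff(tr))
  gt <- attr(tr, "ground_truth")
  expect_equal(nrow(b), gt$derived$n_beats)
  expect_equal(unique(round(diff(b$peak_time), 9)), 1.0)
})

test_that("noise-free recovery is exact when beats fully separate", {
  # tau small enough that the truncated tail is exactly zero at next onset
  p <- beat_train_params(mean_frequency = 0.5, time_to_peak = 0.1,
                         decay80 = 0.15, ibi_cv = 0, amplitude_cv = 0,
                         noise_sd = 0, mean_amplitude = 1.3, seed = 1)
  tr <- gen_calcium_trace(p)
  gt <- attr(tr, "ground_truth")
  b <- detect_beats(compute_dff(tr))
  expect_equal(nrow(b), gt$derived$n_beats)
  expect_equal(b$peak_time, gt$derived$peak_times, tolerance = 1e-9)
  expect_equal(b$amplitude, gt$derived$amplitudes, tolerance = 1e-9)
  expect_equal(b$time_to_peak,
               rep(0.9 * p$time_to_peak, nrow(b)), tolerance = 1e-9)
  ok <- !is.na(b$decay80_time)
  expect_true(all(abs(b$decay80_time[ok] - p$decay80) <= p$dt))
})

test_that("transient summaries implement the stated statistics", {
  beats <- tibble::tibble(
    onset_time = c(0.9, 1.7, 2.7, 3.9),
    peak_time = c(1, 1.8, 2.8, 4),  # IBIs 0.8, 1.0, 1.2
    peak_dff = c(1, 1, 1, 1), amplitude = c(1, 1, 1, 1),
    time_to_peak = rep(0.1, 4), decay80_time = rep(0.3, 4))
  s <- summarize_transients(beats, duration = 5)
  expect_equal(s$frequency, 1.0)
  fi <- 1 / c(0.8, 1.0, 1.2)
  expect_equal(s$cv_frequency, sd(fi) / mean(fi))
  expect_equal(round(s$cv_frequency, 5), 0.20405)
  expect_equal(s$cv_amplitude, 0)
  # n = 1 beat: frequency missing, not zero
  s1 <- summarize_transients(beats[1, ], duration = 5)
  expect_true(is.na(s1$frequency))
  s2 <- summarize_transients(beats[1:2, ], duration = 5)
  expect_true(is.na(s2$cv_frequency))
  expect_false(is.na(s2$frequency))
})

test_that("frequency and its CV are recovered under realistic noise", {
  rec <- t(sapply(1:10, function(s) {
    p <- beat_train_params(mean_frequency = 1.48, ibi_cv = 0.05,
                           noise_sd = 2, seed = s)
    s <- analyze_calcium_trace(gen_calcium_trace(p))
    c(f = s$frequency, cv = s$cv_frequency)
  }))
  expect_lt(abs(mean(rec[, "f"]) / 1.48 - 1), 0.02)
  expect_lt(abs(mean(rec[, "cv"]) - 0.05), 0.02)
})

test_that("recovered frequency CV increases with generator IBI CV", {
  mean_cv <- function(ibi_cv) {
    mean(sapply(1:100, function(s) {
      p <- beat_train_params(mean_frequency = 1.04, ibi_cv = ibi_cv,
                             noise_sd = 2, seed = s)
      analyze_calcium_trace(gen_calcium_trace(p))$cv_frequency
    }))
  }
  cvs <- vapply(c(0.02, 0.1, 0.25), mean_cv, numeric(1))
  expect_true(all(diff(cvs) > 0))
})

test_that("amplitude CV is invariant to trace rescaling", {
  p <- beat_train_params(mean_frequency = 1.04, amplitude_cv = 0.2,
                         noise_sd = 0, seed = 4)
  tr <- gen_calcium_trace(p)
  d <- compute_dff(tr)
  s1 <- summarize_transients(detect_beats(d), 30)
  d2 <- d
  d2$dff <- d2$dff * 7.3
  s2 <- summarize_transients(detect_beats(d2), 30)
  expect_equal(s1$cv_amplitude, s2$cv_amplitude, tolerance = 1e-9)
})

test_that("decay80 of a pure exponential tail equals tau ln 5", {
  dt <- 0.005
  tau <- 0.21
  t <- seq(0, 3, by = dt)
  x <- c(rep(0, 50), seq(0, 1, length.out = 21)[-21], exp(-t / tau))
  b <- detect_beats(x, dt = dt, min_prominence = 0.5)
  expect_equal(nrow(b), 1)
  expect_lt(abs(b$decay80_time - tau * log(5)), dt)
})

test_that("day-0 normalization divides by the matching chip baseline", {
  tb <- tibble::tibble(chip_id = c("a", "a", "b", "b"),
                       day = c(0, 7, 0, 7),
                       frequency = c(1.0, 0.53, 2.0, 1.0),
                       mean_amplitude = c(0.8, 0.992, 1.0, 1.24))
  f <- normalize_to_day0(tb)
  expect_equal(f$frequency, c(1, 0.53, 1, 0.5))
  expect_equal(f$mean_amplitude, c(1, 1.24, 1, 1.24))
  # randomized table equals brute-force elementwise division
  set.seed(1)
  tb2 <- tibble::tibble(chip_id = rep(letters[1:3], each = 3),
                        day = rep(c(0, 3, 7), 3),
                        m1 = runif(9, 0.5, 2), m2 = runif(9, 0.5, 2))
  f2 <- normalize_to_day0(tb2)
  for (ch in letters[1:3]) {
    base <- tb2[tb2$chip_id == ch & tb2$day == 0, ]
    rows <- tb2$chip_id == ch
    expect_equal(f2$m1[rows], tb2$m1[rows] / base$m1)
    expect_equal(f2$m2[rows], tb2$m2[rows] / base$m2)
  }
  expect_error(normalize_to_day0(tb[tb$day != 0 | tb$chip_id != "b", ]),
               "chip.*b|b.*chip")
})
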