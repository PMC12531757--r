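# Generators: analytic waveform, beat trains, vessel renders, tracer
# stacks, extravasation pairs, and their ground-truth contracts.

test_that("beat waveform kinetics are analytically exact", {
  w <- gen_beat_waveform(time_to_peak = 0.1, decay80 = 0.4, amplitude = 1,
                         dt = 0.01)
  expect_equal(w$value[w$time == 0.1], 1.0)
  expect_equal(w$value[w$time == 0.5], 0.2)  # 80% decayed at peak + decay80
  expect_equal(attr(w, "params")$tau, 0.4 / log(5))
  w2 <- gen_beat_waveform(0.05, 0.2, 2.0, dt = 0.005)
  expect_equal(w2$value[w2$time == 0.025], 1.0)  # linear rise midpoint
  expect_error(gen_beat_waveform(0.1, 0.4, 1, dt = 0.06), "unresolvable")
  expect_error(gen_beat_waveform(-0.1, 0.4, 1), "time_to_peak")
})

test_that("degenerate beat train is perfectly periodic and reproducible", {
  p <- beat_train_params(mean_frequency = 1, ibi_cv = 0, amplitude_cv = 0,
                         noise_sd = 0, bleach_rate = 0, seed = 1)
  tr <- gen_calcium_trace(p)
  gt <- attr(tr, "ground_truth")
  expect_equal(gt$derived$ibis, rep(1, gt$derived$n_beats - 1))
  expect_equal(gt$derived$n_beats, 30L)
  tr2 <- gen_calcium_trace(p)
  expect_identical(tr$intensity, tr2$intensity)
})

test_that("beat-train parameter validation rejects overlapping beats", {
  expect_error(beat_train_params(mean_frequency = 2, time_to_peak = 0.2,
                                 decay80 = 0.4), "overlap")
  expect_error(beat_train_params(dt = 0.2), "dt")
})

test_that("realized beat count over seeds matches the gamma IBI model", {
  # independent oracle: Monte-Carlo count of gamma renewals in 30 s
  count_oracle <- function(seed, mf = 1.48, cv = 0.05, dur = 30, ttp = 0.15) {
    set.seed(seed)
    mean_ibi <- 1 / mf
    t <- 0.2 * mean_ibi
    n <- 1L
    repeat {
      t <- t + rgamma(1, shape = 1 / cv^2, scale = mean_ibi * cv^2)
      if (t + ttp > dur) break
      n <- n + 1L
    }
    n
  }
  counts <- vapply(1:100, function(s) {
    p <- beat_train_params(mean_frequency = 1.48, ibi_cv = 0.05, seed = s)
    attr(gen_calcium_trace(p), "ground_truth")$derived$n_beats
  }, integer(1))
  oracle <- vapply(1:100, count_oracle, integer(1))
  expect_identical(counts, oracle)
  expect_true(all(counts >= 35 & counts <= 53))
})

test_that("realized IBI moments match the requested gamma mean and CV", {
  ibis <- unlist(lapply(1:300, function(s) {
    p <- beat_train_params(mean_frequency = 1.2, ibi_cv = 0.15, seed = s)
    attr(gen_calcium_trace(p), "ground_truth")$derived$ibis
  }))
  n <- length(ibis)
  m <- mean(ibis); cv <- sd(ibis) / m
  se_mean <- sd(ibis) / sqrt(n)
  se_cv <- cv / sqrt(2 * n)  # large-sample SE of a CV estimate
  expect_lt(abs(m - 1 / 1.2), 3 * se_mean)
  expect_lt(abs(cv - 0.15), 3 * se_cv)
})

test_that("explicit segment renders carry exact topology ground truth", {
  seg <- data.frame(x0 = 14, y0 = 32, x1 = 113, y1 = 32, diameter = 10)
  v <- gen_vessel_image(seg, image_shape = c(64, 128))
  expect_equal(v$truth$derived$n_junctions, 0)
  expect_equal(v$truth$derived$n_endpoints, 2)
  expect_equal(v$truth$derived$coverage, mean(v$mask))
  plus <- data.frame(x0 = c(14, 64), y0 = c(64, 14), x1 = c(113, 64),
                     y1 = c(64, 113), diameter = 10)
  vp <- gen_vessel_image(plus, image_shape = c(128, 128))
  expect_equal(vp$truth$derived$n_junctions, 1)
  expect_equal(vp$truth$derived$n_endpoints, 4)
})

test_that("coverage-driven renders hit the target and record it exactly", {
  p <- vessel_network_params(image_shape = c(512, 512),
                             target_coverage = 0.645, seed = 3)
  net <- gen_vessel_network(p)
  expect_equal(net$truth$derived$coverage, mean(net$mask))  # conservation
  expect_lt(abs(net$truth$derived$coverage - 0.645), 0.02)
  # determinism
  net2 <- gen_vessel_network(p)
  expect_identical(net$image, net2$image)
  expect_identical(net$mask, net2$mask)
})

test_that("unreachable coverage fails explicitly instead of clipping", {
  expect_error(
    gen_vessel_network(vessel_network_params(image_shape = c(256, 256),
                                             target_coverage = 0.97,
                                             seed = 1)),
    "unreachable")
})

test_that("tracer stacks follow the linear influx model exactly", {
  # hand evaluation of the forward model (verified independently):
  # 3.3e-6 * 1000 * (4 / 22.9e-4) * 720 = 4150.2...
  p <- permeability_sim_params(permeability_true = 3.3e-6,
                               vessel_diameter = 22.9,
                               intensity_vessel = 1010,
                               intensity_background = 10)
  sim <- gen_permeability_stack(p)
  rise <- sim$truth$derived$tissue_intensity[5] - 10
  expect_equal(rise, 3.3e-6 * 1000 * (4 / 22.9e-4) * 720, tolerance = 1e-12)
  expect_true(sim$truth$derived$linear_regime_violated)
  # zero flux: all tissue frames identical to frame 0
  sim0 <- gen_permeability_stack(permeability_sim_params(permeability_true = 0))
  expect_identical(sim0$stack[, , 1], sim0$stack[, , 5])
  expect_false(sim0$truth$derived$linear_regime_violated)
  # determinism
  simA <- gen_permeability_stack(p)
  expect_identical(sim$stack, simA$stack)
})

test_that("extravasation pairs place the exact requested pixel split", {
  mask <- bar_mask(64, 64, width = 20, len = 40)
  pr <- gen_extravasation_pair(0.618, mask, n_positive = 1000, seed = 2)
  pos <- pr$liposome > 100
  expect_equal(sum(pos & !mask), 618)
  expect_equal(sum(pos & mask), 382)
  expect_equal(pr$truth$derived$realized_fraction, 0.618)
  pr0 <- gen_extravasation_pair(0, mask, n_positive = 200, seed = 1)
  expect_equal(sum((pr0$liposome > 100) & !mask), 0)
  pr1 <- gen_extravasation_pair(1, mask, n_positive = 200, seed = 1)
  expect_equal(sum((pr1$liposome > 100) & mask), 0)
  expect_error(gen_extravasation_pair(0.5, matrix(TRUE, 8, 8)),
               "all-foreground")
})

test_that("ground-truth records round-trip losslessly through JSON", {
  p <- beat_train_params(seed = 9)
  tr <- gen_calcium_trace(p)
  gt <- attr(tr, "ground_truth")
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(gt, path)
  back <- read_ground_truth(path)
  expect_equal(back$generator, gt$generator)
  expect_equal(back$seed, gt$seed)
  expect_equal(back$derived$onsets, gt$derived$onsets)
  expect_equal(back$derived$amplitudes, gt$derived$amplitudes)
  expect_equal(back$params$mean_frequency, gt$params$mean_frequency)
})
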