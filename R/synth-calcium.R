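# Synthetic GCaMP calcium-transient traces with ground truth.

#' Parameters for a synthetic beat train
#'
#' Bundles and validates the parameters of the synthetic calcium-transient
#' generator. Defaults reproduce a healthy spontaneously beating
#' cardiomyocyte recording: 1.04 Hz mean rate, low inter-beat-interval
#' variability, unit `\eqn{\Delta F/F_0}` amplitude, 30 s acquisition at a
#' 10 ms frame interval.
#'
#' @param mean_frequency Mean beat frequency (Hz).
#' @param ibi_cv Coefficient of variation of inter-beat intervals
#'   (dimensionless). 0 gives a perfectly periodic train.
#' @param mean_amplitude Mean transient amplitude in `\eqn{\Delta F/F_0}` units.
#' @param amplitude_cv CV of per-beat amplitudes.
#' @param time_to_peak Linear rise time of each transient (s).
#' @param decay80 Time from peak to 80 % amplitude decay (s); the decay is
#'   exponential with `tau = decay80 / ln 5`.
#' @param duration Recording length (s).
#' @param dt Sampling interval (s).
#' @param baseline_f0 Baseline fluorescence intensity (arbitrary units).
#' @param noise_sd Additive Gaussian noise standard deviation, in the same
#'   intensity units as `baseline_f0`.
#' @param bleach_rate Photobleaching rate (fraction per second) applied as a
#'   multiplicative exponential decay of the whole trace.
#' @param seed Integer seed; all randomness in the generator flows from it.
#'
#' @return A `beat_train_params` list.
#' @export
#' @examples
#' p <- beat_train_params(mean_frequency = 1.48, ibi_cv = 0.1)
beat_train_params <- function(mean_frequency = 1.04, ibi_cv = 0.05,
                              mean_amplitude = 1, amplitude_cv = 0.05,
                              time_to_peak = 0.15, decay80 = 0.35,
                              duration = 30, dt = 0.01,
                              baseline_f0 = 100, noise_sd = 2,
                              bleach_rate = 0, seed = 1) {
  check_number(mean_frequency, "mean_frequency", positive = TRUE)
  check_number(ibi_cv, "ibi_cv", nonneg = TRUE)
  check_number(mean_amplitude, "mean_amplitude", positive = TRUE)
  check_number(amplitude_cv, "amplitude_cv", nonneg = TRUE)
  check_number(time_to_peak, "time_to_peak", positive = TRUE)
  check_number(decay80, "decay80", positive = TRUE)
  check_number(duration, "duration", positive = TRUE)
  check_number(dt, "dt", positive = TRUE)
  check_number(baseline_f0, "baseline_f0", positive = TRUE)
  check_number(noise_sd, "noise_sd", nonneg = TRUE)
  check_number(bleach_rate, "bleach_rate", nonneg = TRUE)
  if (time_to_peak + decay80 >= 1 / mean_frequency)
    abort(paste0("Beats would overlap: time_to_peak + decay80 must be < ",
                 "1/mean_frequency (", signif(1 / mean_frequency, 4), " s)."))
  if (dt > time_to_peak / 2)
    abort("`dt` must be <= time_to_peak/2 so the rise is resolvable.")
  structure(list(
    mean_frequency = mean_frequency, ibi_cv = ibi_cv,
    mean_amplitude = mean_amplitude, amplitude_cv = amplitude_cv,
    time_to_peak = time_to_peak, decay80 = decay80,
    duration = duration, dt = dt, baseline_f0 = baseline_f0,
    noise_sd = noise_sd, bleach_rate = bleach_rate,
    seed = as.integer(seed)
  ), class = "beat_train_params")
}

# Analytic single-transient template evaluated at relative times t (t = 0 at
# beat onset): linear rise to `amplitude` over `time_to_peak`, then
# exponential decay with tau = decay80/ln(5), so the value at
# time_to_peak + decay80 is exactly 0.2 * amplitude.
beat_value <- function(t, time_to_peak, decay80, amplitude) {
  tau <- decay80 / log(5)
  v <- numeric(length(t))
  rise <- t >= 0 & t <= time_to_peak
  fall <- t > time_to_peak
  v[rise] <- amplitude * t[rise] / time_to_peak
  v[fall] <- amplitude * exp(-(t[fall] - time_to_peak) / tau)
  v
}

#' Sampled single calcium-transient waveform
#'
#' Returns a sampled template transient: linear rise from 0 to `amplitude`
#' over exactly `time_to_peak`, then exponential decay with
#' `tau = decay80 / ln 5`, which makes the value at
#' `time_to_peak + decay80` exactly `0.2 * amplitude`. All kinetic
#' parameters of the waveform are therefore analytically exact, so beat
#' detection can be validated against them.
#'
#' @inheritParams beat_train_params
#' @param amplitude Peak `\eqn{\Delta F/F_0}` of the transient.
#' @param n_decay_tau How many decay time constants to sample past the peak.
#'
#' @return A tibble with columns `time` and `value`; attribute `params`
#'   carries the analytic parameter record (including `tau`).
#' @export
#' @examples
#' w <- gen_beat_waveform(time_to_peak = 0.1, decay80 = 0.4, amplitude = 1)
#' w$value[w$time == 0.1]  # exactly 1
gen_beat_waveform <- function(time_to_peak, decay80, amplitude, dt = 0.01,
                              n_decay_tau = 8) {
  check_number(time_to_peak, "time_to_peak", positive = TRUE)
  check_number(decay80, "decay80", positive = TRUE)
  check_number(amplitude, "amplitude", positive = TRUE)
  check_number(dt, "dt", positive = TRUE)
  if (dt >= time_to_peak / 2)
    abort("`dt` must be < time_to_peak/2 (unresolvable rise).")
  tau <- decay80 / log(5)
  t <- seq(0, time_to_peak + n_decay_tau * tau, by = dt)
  out <- tibble::tibble(time = t,
                        value = beat_value(t, time_to_peak, decay80, amplitude))
  attr(out, "params") <- list(time_to_peak = time_to_peak, decay80 = decay80,
                              amplitude = amplitude, tau = tau, dt = dt)
  out
}

#' Simulate a calcium-transient fluorescence trace
#'
#' Generates a raw fluorescence trace
#' `F(t) = F0 * exp(-bleach_rate * t) * (1 + sum of beats) + noise`.
#' Inter-beat intervals are gamma distributed with the requested mean
#' (`1/mean_frequency`) and CV (shape `1/cv^2`, scale `mean * cv^2`);
#' per-beat amplitudes are lognormal with the requested mean and CV. Both
#' reduce to constants when the CV is 0. The attached ground truth records
#' every drawn onset, amplitude and the realized inter-beat-interval list.
#'
#' @param params A [beat_train_params()] object.
#'
#' @return A tibble of class `calcium_trace` with columns `time` and
#'   `intensity`; attributes `dt` and `ground_truth`.
#' @export
#' @examples
#' tr <- gen_calcium_trace(beat_train_params(seed = 7))
#' head(tr)
#' attr(tr, "ground_truth")$n_beats
gen_calcium_trace <- function(params) {
  stopifnot(inherits(params, "beat_train_params"))
  p <- params
  set.seed(p$seed)
  mean_ibi <- 1 / p$mean_frequency

  # draw onsets until the next peak would fall past the trace end
  onsets <- 0.2 * mean_ibi
  repeat {
    ibi <- if (p$ibi_cv == 0) mean_ibi else
      rgamma(1, shape = 1 / p$ibi_cv^2, scale = mean_ibi * p$ibi_cv^2)
    nxt <- onsets[length(onsets)] + ibi
    if (nxt + p$time_to_peak > p$duration) break
    onsets <- c(onsets, nxt)
  }
  n_beats <- length(onsets)
  amps <- if (p$amplitude_cv == 0) rep(p$mean_amplitude, n_beats) else {
    sdlog <- sqrt(log(1 + p$amplitude_cv^2))
    rlnorm(n_beats, meanlog = log(p$mean_amplitude) - sdlog^2 / 2,
           sdlog = sdlog)
  }

  t <- seq(0, p$duration - p$dt, by = p$dt)
  dff <- numeric(length(t))
  tau <- p$decay80 / log(5)
  support <- p$time_to_peak + 12 * tau
  for (i in seq_len(n_beats)) {
    j <- which(t >= onsets[i] & t <= onsets[i] + support)
    dff[j] <- dff[j] +
      beat_value(t[j] - onsets[i], p$time_to_peak, p$decay80, amps[i])
  }
  f <- p$baseline_f0 * exp(-p$bleach_rate * t) * (1 + dff)
  if (p$noise_sd > 0) f <- f + rnorm(length(t), 0, p$noise_sd)

  truth <- ground_truth(
    generator = "gen_calcium_trace",
    params = unclass(p),
    derived = list(
      onsets = onsets,
      amplitudes = amps,
      ibis = diff(onsets),
      peak_times = onsets + p$time_to_peak,
      n_beats = n_beats
    ),
    seed = p$seed
  )
  out <- tibble::tibble(time = t, intensity = f)
  class(out) <- c("calcium_trace", class(out))
  attr(out, "dt") <- p$dt
  attr(out, "ground_truth") <- truth
  out
}

#' Ground-truth record attached to every synthetic dataset
#'
#' A light container pairing generator name, the full parameter record, the
#' derived true quantities (beat tables, skeleton counts, coverage, true
#' permeability, ...) and the seed. Serializes losslessly to JSON via
#' [write_ground_truth()].
#'
#' @param generator Name of the generator that produced the artifact.
#' @param params Full parameter record (list).
#' @param derived List of derived true values.
#' @param seed Integer seed used.
#' @return A `ground_truth` list.
#' @export
ground_truth <- function(generator, params, derived, seed) {
  structure(list(generator = generator, params = params,
                 derived = derived, seed = seed),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", x$generator, " (seed ", x$seed, ")\n", sep = "")
  cat("  derived: ", paste(names(x$derived), collapse = ", "), "\n", sep = "")
  invisible(x)
}
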