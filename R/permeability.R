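# Apparent vascular permeability from tracer time-lapse imaging.

#' Per-compartment tracer intensities over time
#'
#' Partitions each frame into vessel lumen (the mask), a perivascular
#' tissue band (pixels whose distance outside the mask lies in
#' `(gap_px, gap_px + band_px]`) and background (an explicit ROI, or the
#' first-frame tissue intensity when omitted), and reports the mean
#' intensity of each compartment per frame.
#'
#' @param stack Numeric array `rows x cols x frames`, >= 2 frames.
#' @param vessel_mask Logical matrix or `vessel_mask` object.
#' @param times Frame acquisition times (s), one per frame.
#' @param gap_px Dead zone outside the vessel wall excluded from the band.
#' @param band_px Width of the tissue band (px).
#' @param background_roi Optional `c(xmin, xmax, ymin, ymax)` or logical
#'   matrix defining the background compartment.
#' @return A tibble with columns `frame, time, i_vessel, i_tissue,
#'   i_background`.
#' @export
measure_tracer_intensities <- function(stack, vessel_mask, times,
                                       gap_px = 0, band_px = 20,
                                       background_roi = NULL) {
  if (length(dim(stack)) != 3L || dim(stack)[3] < 2L)
    abort("`stack` must be a rows x cols x frames array with >= 2 frames.")
  mask <- if (inherits(vessel_mask, "vessel_mask")) vessel_mask$mask else
    vessel_mask > 0
  if (length(times) != dim(stack)[3])
    abort("`times` must have one entry per frame.")
  if (!any(mask)) abort("vessel compartment is empty.")
  outside <- !mask
  dm <- as.matrix(EBImage::distmap(matrix(as.numeric(outside), nrow(mask),
                                          ncol(mask))))
  band <- outside & dm > gap_px & dm <= gap_px + band_px
  if (!any(band)) abort("tissue band is empty; widen `band_px`.")
  bg_mask <- if (is.null(background_roi)) NULL else if (is.matrix(background_roi))
    background_roi > 0 else {
      m <- matrix(FALSE, nrow(mask), ncol(mask))
      m[background_roi[3]:background_roi[4],
        background_roi[1]:background_roi[2]] <- TRUE
      m
    }
  if (!is.null(bg_mask) && !any(bg_mask)) abort("background ROI is empty.")
  res <- purrr::map_dfr(seq_len(dim(stack)[3]), function(k) {
    fr <- stack[, , k]
    tibble::tibble(
      frame = k, time = times[k],
      i_vessel = mean(fr[mask]),
      i_tissue = mean(fr[band]),
      i_background = if (is.null(bg_mask)) NA_real_ else mean(fr[bg_mask])
    )
  })
  if (is.null(bg_mask)) res$i_background <- res$i_tissue[1]
  res
}

#' Estimate apparent permeability from tracer influx
#'
#' Fits the least-squares slope of the perivascular tissue intensity
#' against time and converts it to an apparent permeability
#' `P = slope / (I_v - I_b) * geometric_factor` (cm/s), with the
#' geometric factor `V/S = d/4` of a cylinder of diameter `d` by default.
#' Frames whose tissue intensity reaches `saturation_frac * I_v` are
#' excluded with a warning; a negative slope is reported with a warning
#' flag rather than clipped.
#'
#' @param times Frame times (s), increasing.
#' @param i_tissue Per-frame tissue intensities.
#' @param i_vessel Intravascular intensity (scalar or per-frame; averaged).
#' @param i_background Background intensity (scalar or per-frame; the
#'   first value is used).
#' @param diameter Mean vessel diameter in um (used as `d/4`, converted to
#'   cm) unless `geometric_factor` is given directly.
#' @param geometric_factor `V/S` in cm; overrides `diameter`.
#' @param saturation_frac Tissue/vessel intensity ratio above which a
#'   frame is considered saturated.
#' @return A one-row tibble of class `permeability_result`:
#'   `permeability` (cm/s), `flux_slope` (intensity/s), `delta_i`,
#'   `geometric_factor` (cm), `fit_r2`, `frames_used`, `negative_slope`,
#'   `saturated_excluded`. The fitted points are kept in attribute `fit`.
#' @export
#' @examples
#' sim <- gen_permeability_stack(permeability_sim_params())
#' m <- measure_tracer_intensities(sim$stack, sim$vessel_mask, sim$times)
#' estimate_permeability(m$time, m$i_tissue, m$i_vessel, m$i_background,
#'                       diameter = 22.9)
estimate_permeability <- function(times, i_tissue, i_vessel, i_background,
                                  diameter = NULL, geometric_factor = NULL,
                                  saturation_frac = 0.95) {
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing.")
  iv <- mean(i_vessel)
  ib <- i_background[1]
  if (iv <= ib) abort("I_vessel must exceed I_background.")
  if (is.null(geometric_factor)) {
    if (is.null(diameter)) abort("supply `diameter` (um) or `geometric_factor` (cm).")
    check_number(diameter, "diameter", positive = TRUE)
    geometric_factor <- (diameter * 1e-4) / 4
  }
  check_number(geometric_factor, "geometric_factor", positive = TRUE)
  keep <- i_tissue < saturation_frac * iv
  excluded <- sum(!keep)
  if (excluded > 0)
    warn(sprintf("%d saturated frame(s) excluded from the flux fit.", excluded))
  if (sum(keep) < 2) abort("fewer than 2 usable frames for the flux fit.")
  fit <- lm(i_tissue[keep] ~ times[keep])
  slope <- unname(coef(fit)[2])
  # snap numerically-zero slopes (constant tissue intensity) to exactly 0
  if (abs(slope) < 1e-12 * max(abs(i_tissue), 1) / max(times[-1]))
    slope <- 0
  ss_tot <- sum((i_tissue[keep] - mean(i_tissue[keep]))^2)
  r2 <- if (sum(keep) == 2 || ss_tot == 0) 1 else
    1 - sum(stats::residuals(fit)^2) / ss_tot
  if (slope < 0)
    warn("negative flux slope (photobleaching or washout?).")
  out <- tibble::tibble(
    permeability = slope / (iv - ib) * geometric_factor,
    flux_slope = slope,
    delta_i = iv - ib,
    geometric_factor = geometric_factor,
    fit_r2 = r2,
    frames_used = as.integer(sum(keep)),
    negative_slope = slope < 0,
    saturated_excluded = as.integer(excluded)
  )
  class(out) <- c("permeability_result", class(out))
  attr(out, "fit") <- tibble::tibble(time = times[keep],
                                     i_tissue = i_tissue[keep],
                                     fitted = unname(stats::fitted(fit)))
  out
}

#' Permeability pipeline from a stack
#'
#' Chains [measure_tracer_intensities()] and [estimate_permeability()].
#'
#' @inheritParams measure_tracer_intensities
#' @inheritParams estimate_permeability
#' @param ... Passed to [measure_tracer_intensities()].
#' @return A `permeability_result` tibble.
#' @export
analyze_permeability <- function(stack, vessel_mask, times, diameter = NULL,
                                 geometric_factor = NULL,
                                 saturation_frac = 0.95, ...) {
  m <- measure_tracer_intensities(stack, vessel_mask, times, ...)
  estimate_permeability(m$time, m$i_tissue, m$i_vessel, m$i_background,
                        diameter = diameter,
                        geometric_factor = geometric_factor,
                        saturation_frac = saturation_frac)
}
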