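# Calcium-transient analysis: ROI trace extraction, dF/F0, beat detection,
# per-recording summary statistics and longitudinal day-0 normalization.

#' Extract per-ROI mean-intensity traces from a movie
#'
#' Computes the mean intensity of every region of interest in every frame
#' of a time-lapse movie, producing one uniformly sampled fluorescence
#' trace per ROI.
#'
#' @param movie Numeric array `rows x cols x frames` with at least 2 frames.
#' @param rois Data frame with columns `roi_id, xmin, xmax, ymin, ymax`
#'   (inclusive pixel bounds, `x` = column, `y` = row), or a named list of
#'   logical masks.
#' @param frame_interval Frame interval in seconds.
#' @return A tibble of class `calcium_trace` with columns
#'   `roi_id, time, intensity`; attribute `dt` holds the frame interval.
#' @export
extract_roi_traces <- function(movie, rois, frame_interval) {
  if (length(dim(movie)) != 3L || dim(movie)[3] < 2L)
    abort("`movie` must be a rows x cols x frames array with >= 2 frames.")
  check_number(frame_interval, "frame_interval", positive = TRUE)
  nfr <- dim(movie)[3]
  t <- (seq_len(nfr) - 1) * frame_interval

  if (is.data.frame(rois)) {
    need <- c("roi_id", "xmin", "xmax", "ymin", "ymax")
    if (!all(need %in% names(rois)))
      abort("`rois` needs columns roi_id, xmin, xmax, ymin, ymax.")
    masks <- lapply(seq_len(nrow(rois)), function(i) {
      if (rois$xmin[i] < 1 || rois$xmax[i] > dim(movie)[2] ||
          rois$ymin[i] < 1 || rois$ymax[i] > dim(movie)[1] ||
          rois$xmin[i] > rois$xmax[i] || rois$ymin[i] > rois$ymax[i])
        abort(sprintf("ROI '%s' is empty or outside image bounds.",
                      rois$roi_id[i]))
      m <- matrix(FALSE, dim(movie)[1], dim(movie)[2])
      m[rois$ymin[i]:rois$ymax[i], rois$xmin[i]:rois$xmax[i]] <- TRUE
      m
    })
    names(masks) <- as.character(rois$roi_id)
  } else {
    masks <- rois
    if (is.null(names(masks))) names(masks) <- paste0("roi", seq_along(masks))
  }
  out <- purrr::map2_dfr(masks, names(masks), function(m, id) {
    if (!any(m)) abort(sprintf("ROI '%s' selects no pixels.", id))
    idx <- which(m)
    vals <- vapply(seq_len(nfr), function(k) mean(movie[, , k][idx]),
                   numeric(1))
    tibble::tibble(roi_id = id, time = t, intensity = vals)
  })
  class(out) <- c("calcium_trace", class(out))
  attr(out, "dt") <- frame_interval
  out
}

#' Baseline-normalize a fluorescence trace to dF/F0
#'
#' Computes `dff = (F - F0)/F0` per ROI. The default baseline `F0` is the
#' 10th percentile of the full trace, which tolerates slow drift without
#' requiring a quiet pre-beat window; alternatives are the trace minimum
#' and the mean of a pre-window.
#'
#' @param trace A `calcium_trace` tibble (columns `time`, `intensity`,
#'   optionally `roi_id`).
#' @param f0_method One of `"percentile"`, `"min"`, `"prewindow"`.
#' @param f0_param Percentile in \[0, 1\] for `"percentile"` (default 0.1),
#'   or the pre-window length in seconds for `"prewindow"`.
#' @return The input tibble with a `dff` column added; attribute `f0` maps
#'   ROI to the baseline used.
#' @export
compute_dff <- function(trace, f0_method = c("percentile", "min", "prewindow"),
                        f0_param = 0.1) {
  f0_method <- match.arg(f0_method)
  stopifnot(all(c("time", "intensity") %in% names(trace)))
  if (!"roi_id" %in% names(trace)) trace$roi_id <- "roi1"
  f0_of <- function(time, f) {
    f0 <- switch(f0_method,
      percentile = as.numeric(quantile(f, f0_param, names = FALSE)),
      min = min(f),
      prewindow = mean(f[time <= time[1] + f0_param])
    )
    if (!is.finite(f0) || f0 <= 0)
      abort("estimated F0 <= 0: corrupted or non-positive baseline.")
    f0
  }
  dt <- attr(trace, "dt")
  out <- trace |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::mutate(dff = (.data$intensity - f0_of(.data$time, .data$intensity)) /
                    f0_of(.data$time, .data$intensity)) |>
    dplyr::ungroup()
  f0s <- trace |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::summarise(f0 = f0_of(.data$time, .data$intensity)) |>
    tibble::deframe()
  class(out) <- c("calcium_trace", class(tibble::tibble()))
  attr(out, "dt") <- dt
  attr(out, "f0") <- f0s
  out
}

# Local maxima of x with prominence >= min_prom, at least min_sep samples
# apart. Prominence of a peak: height above the higher of the two minima
# separating it from the nearest higher points (or the trace edges).
find_peaks <- function(x, min_prom, min_sep) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  # cheap pruning: a peak can't have prominence >= min_prom unless it rises
  # that far above the global minimum
  cand <- cand[x[cand] >= min(x) + min_prom]
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(i) {
    v <- x[i]
    li <- i - 1L
    lmin <- v
    while (li >= 1L && x[li] <= v) {
      if (x[li] < lmin) lmin <- x[li]
      li <- li - 1L
    }
    if (li < 1L) lmin <- min(x[1:i])
    ri <- i + 1L
    rmin <- v
    while (ri <= n && x[ri] <= v) {
      if (x[ri] < rmin) rmin <- x[ri]
      ri <- ri + 1L
    }
    if (ri > n) rmin <- min(x[i:n])
    v - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prom]
  if (length(keep) <= 1) return(keep)
  # enforce separation, keeping the higher peak
  ord <- keep[order(x[keep], decreasing = TRUE)]
  sel <- integer(0)
  for (i in ord) if (all(abs(sel - i) >= min_sep)) sel <- c(sel, i)
  sort(sel)
}

#' Detect individual beats in a dF/F0 trace
#'
#' Finds transient peaks (local maxima with a minimum prominence and a
#' refractory separation) and parameterizes each beat: the local baseline
#' is the signal minimum between the previous peak (or trace start) and
#' the current peak; amplitude is peak minus local baseline; onset is the
#' last upward crossing of `baseline + onset_fraction * amplitude` before
#' the peak (linearly interpolated); `time_to_peak = peak - onset`;
#' `decay80_time` is the first post-peak time, linearly interpolated, at
#' which the signal falls to `peak - 0.8 * amplitude`, minus the peak time
#' (`NA` when the trace ends first).
#'
#' @param dff A tibble with columns `time` and `dff` (per `roi_id` if
#'   present), as returned by [compute_dff()], or a numeric vector with
#'   `dt` supplied.
#' @param min_prominence Minimum peak prominence in dF/F0 units; default
#'   `0.2 * (95th - 5th percentile)` of the trace.
#' @param min_ibi Minimum peak separation (s); default 0.2 s, above the
#'   physiological maximum beating rate.
#' @param onset_fraction Fraction of the amplitude defining beat onset.
#' @param dt Sampling interval, required when `dff` is a bare vector.
#' @return A tibble of class `beat_table` with one row per beat:
#'   `roi_id, onset_time, peak_time, peak_dff, amplitude, time_to_peak,
#'   decay80_time`.
#' @export
detect_beats <- function(dff, min_prominence = NULL, min_ibi = 0.2,
                         onset_fraction = 0.1, dt = NULL) {
  if (is.numeric(dff) && is.null(dim(dff))) {
    if (is.null(dt)) abort("supply `dt` when `dff` is a numeric vector.")
    dff <- tibble::tibble(roi_id = "roi1",
                          time = (seq_along(dff) - 1) * dt, dff = dff)
  }
  stopifnot(all(c("time", "dff") %in% names(dff)))
  if (!"roi_id" %in% names(dff)) dff$roi_id <- "roi1"

  one_roi <- function(d) {
    x <- d$dff; t <- d$time
    if (any(!is.finite(x))) abort("dF/F0 trace contains non-finite values.")
    step <- t[2] - t[1]
    prom <- min_prominence %||%
      (0.2 * diff(quantile(x, c(0.05, 0.95), names = FALSE)))
    if (prom <= 0) return(empty_beats())
    sep <- max(1L, round(min_ibi / step))
    pk <- find_peaks(x, prom, sep)
    if (length(pk) == 0) return(empty_beats())
    prev <- c(1L, pk[-length(pk)])
    rows <- lapply(seq_along(pk), function(i) {
      p <- pk[i]
      lo <- prev[i]
      base <- min(x[lo:p])
      amp <- x[p] - base
      level <- base + onset_fraction * amp
      # last upward crossing of `level` before the peak
      seg <- x[lo:p]
      below <- which(seg[-length(seg)] < level & seg[-1] >= level)
      onset <- if (length(below) == 0) t[lo] else {
        j <- lo + max(below) - 1L
        t[j] + step * (level - x[j]) / (x[j + 1L] - x[j])
      }
      # first post-peak crossing of peak - 0.8 * amplitude
      target <- x[p] - 0.8 * amp
      after <- x[p:length(x)]
      cross <- which(after[-length(after)] > target & after[-1] <= target)
      dec <- if (length(cross) == 0) NA_real_ else {
        j <- p + min(cross) - 1L
        t[j] + step * (x[j] - target) / (x[j] - x[j + 1L]) - t[p]
      }
      tibble::tibble(onset_time = onset, peak_time = t[p], peak_dff = x[p],
                     amplitude = amp, time_to_peak = t[p] - onset,
                     decay80_time = dec)
    })
    dplyr::bind_rows(rows)
  }
  out <- dff |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::group_modify(~ one_roi(.x)) |>
    dplyr::ungroup()
  class(out) <- c("beat_table", class(out))
  out
}

empty_beats <- function() {
  tibble::tibble(onset_time = numeric(0), peak_time = numeric(0),
                 peak_dff = numeric(0), amplitude = numeric(0),
                 time_to_peak = numeric(0), decay80_time = numeric(0))
}

#' Summarize detected beats into contractility statistics
#'
#' Aggregates a beat table into the per-recording parameter set: beat
#' frequency (`1 / mean(IBI)` over consecutive peak times), the CV of the
#' instantaneous per-beat frequencies `1/IBI_i`, mean and CV of amplitude,
#' and mean time-to-peak and 80 %-decay time. CVs use the sample (n-1)
#' standard deviation and are the arrhythmia indices of the analysis.
#' Fewer than 2 beats yields a missing frequency (not zero); fewer than 3
#' yields missing CVs. Beats truncated before their 80 % decay contribute
#' to frequency but not to decay statistics.
#'
#' @param beats A `beat_table` from [detect_beats()] (per `roi_id` if
#'   present).
#' @param duration Recording duration in seconds.
#' @return A tibble of class `transient_summary`, one row per ROI:
#'   `roi_id, n_beats, frequency, cv_frequency, mean_amplitude,
#'   cv_amplitude, mean_time_to_peak, mean_decay80, duration`.
#' @export
summarize_transients <- function(beats, duration) {
  check_number(duration, "duration", positive = TRUE)
  if (!"roi_id" %in% names(beats)) beats$roi_id <- "roi1"
  cv <- function(x) if (length(x) < 3) NA_real_ else sd(x) / mean(x)
  out <- beats |>
    dplyr::group_by(.data$roi_id) |>
    dplyr::summarise(
      n_beats = dplyr::n(),
      frequency = if (dplyr::n() < 2) NA_real_ else
        1 / mean(diff(.data$peak_time)),
      cv_frequency = if (dplyr::n() < 3) NA_real_ else {
        fi <- 1 / diff(.data$peak_time)
        sd(fi) / mean(fi)
      },
      mean_amplitude = mean(.data$amplitude),
      cv_amplitude = cv(.data$amplitude),
      mean_time_to_peak = mean(.data$time_to_peak),
      mean_decay80 = mean(.data$decay80_time, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(duration = duration)
  class(out) <- c("transient_summary", class(out))
  out
}

#' Analyze one dF/F0 trace end to end
#'
#' Convenience wrapper chaining [compute_dff()], [detect_beats()] and
#' [summarize_transients()] on a raw `calcium_trace`.
#'
#' @param trace A `calcium_trace` tibble (raw intensities).
#' @param ... Passed to [detect_beats()].
#' @inheritParams compute_dff
#' @return A `transient_summary` tibble.
#' @export
analyze_calcium_trace <- function(trace, f0_method = "percentile",
                                  f0_param = 0.1, ...) {
  d <- compute_dff(trace, f0_method = f0_method, f0_param = f0_param)
  b <- detect_beats(d, ...)
  summarize_transients(b, duration = max(trace$time) - min(trace$time) +
                         (attr(trace, "dt") %||% diff(trace$time[1:2])))
}

#' Normalize longitudinal metrics to each chip's day-0 value
#'
#' Divides every metric by the same chip's day-0 value, turning a
#' longitudinal summary table into fold changes relative to the
#' pre-treatment baseline. Day-0 rows become exactly 1.
#'
#' @param summaries Data frame with chip and day identifier columns plus
#'   numeric metric columns.
#' @param chip_col,day_col Names of the chip and day columns.
#' @param metrics Character vector of metric columns to normalize; default
#'   all numeric columns except the identifiers.
#' @return A tibble with the same shape, metrics replaced by fold changes.
#' @export
#' @examples
#' tb <- tibble::tibble(chip_id = c("a", "a"), day = c(0, 7),
#'                      frequency = c(1, 0.53))
#' normalize_to_day0(tb)
normalize_to_day0 <- function(summaries, chip_col = "chip_id",
                              day_col = "day", metrics = NULL) {
  stopifnot(chip_col %in% names(summaries), day_col %in% names(summaries))
  if (is.null(metrics)) {
    metrics <- setdiff(names(summaries)[vapply(summaries, is.numeric,
                                               logical(1))], c(day_col))
  }
  chips <- unique(summaries[[chip_col]])
  day0 <- summaries[summaries[[day_col]] == 0, , drop = FALSE]
  missing <- setdiff(chips, day0[[chip_col]])
  if (length(missing) > 0)
    abort(paste0("no day-0 record for chip(s): ",
                 paste(missing, collapse = ", ")))
  bad <- day0[[chip_col]][rowSums(day0[, metrics, drop = FALSE] == 0 |
                                    !is.finite(as.matrix(day0[, metrics,
                                                              drop = FALSE]))) > 0]
  if (length(bad) > 0)
    abort(paste0("day-0 value is zero or non-finite for chip(s): ",
                 paste(unique(bad), collapse = ", ")))
  long <- summaries |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = ".metric",
                        values_to = ".value")
  base <- long |>
    dplyr::filter(.data[[day_col]] == 0) |>
    dplyr::select(dplyr::all_of(chip_col), ".metric", .day0 = ".value")
  long |>
    dplyr::left_join(base, by = c(chip_col, ".metric")) |>
    dplyr::mutate(.value = .data$.value / .data$.day0) |>
    dplyr::select(-".day0") |>
    tidyr::pivot_wider(names_from = ".metric", values_from = ".value")
}
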