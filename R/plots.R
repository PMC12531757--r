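# ggplot2 visualisations for the main result types.

#' Plot a calcium trace
#'
#' Line plot of dF/F0 (when present) or raw intensity against time, one
#' facet per ROI.
#'
#' @param object A `calcium_trace` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot calcium_trace
autoplot.calcium_trace <- function(object, ...) {
  ycol <- if ("dff" %in% names(object)) "dff" else "intensity"
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time,
                                            y = .data[[ycol]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)",
                  y = if (ycol == "dff") expression(Delta * F / F[0]) else
                    "intensity (a.u.)") +
    ggplot2::theme_minimal()
  if ("roi_id" %in% names(object) && length(unique(object$roi_id)) > 1)
    p <- p + ggplot2::facet_wrap(~roi_id, ncol = 1)
  p
}

#' Overlay detected beats on a dF/F0 trace
#'
#' @param dff A dF/F0 trace tibble from [compute_dff()].
#' @param beats A `beat_table` from [detect_beats()].
#' @return A ggplot object with peak and onset markers.
#' @export
plot_beats <- function(dff, beats) {
  p <- autoplot.calcium_trace(dff)
  if (nrow(beats) > 0) {
    p <- p +
      ggplot2::geom_point(data = beats,
                          ggplot2::aes(x = .data$peak_time, y = .data$peak_dff),
                          color = "red", size = 1) +
      ggplot2::geom_vline(xintercept = beats$onset_time,
                          color = "steelblue", linetype = 3,
                          linewidth = 0.2)
  }
  p
}

#' Plot a vessel mask with optional skeleton overlay
#'
#' @param mask A `vessel_mask` object or logical matrix.
#' @param skeleton Optional logical matrix from [skeletonize_2d()].
#' @return A ggplot raster plot.
#' @export
plot_vessel_mask <- function(mask, skeleton = NULL) {
  m <- if (inherits(mask, "vessel_mask")) mask$mask else mask > 0
  df <- tidyr::expand_grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$value <- as.vector(m)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "black",
                                          `TRUE` = "grey60"),
                               guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(skeleton)) {
    idx <- which(skeleton > 0)
    sk <- tibble::tibble(row = ((idx - 1) %% nrow(m)) + 1,
                         col = ((idx - 1) %/% nrow(m)) + 1)
    p <- p + ggplot2::geom_point(data = sk,
                                 ggplot2::aes(x = .data$col, y = .data$row),
                                 inherit.aes = FALSE, color = "red",
                                 size = 0.1)
  }
  p
}

#' Plot a permeability flux fit
#'
#' Tissue intensity against time with the fitted linear influx.
#'
#' @param object A `permeability_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot permeability_result
autoplot.permeability_result <- function(object, ...) {
  fit <- attr(object, "fit")
  ggplot2::ggplot(fit, ggplot2::aes(x = .data$time, y = .data$i_tissue)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), color = "red") +
    ggplot2::labs(x = "time (s)", y = "tissue intensity (a.u.)",
                  subtitle = sprintf("P = %.3g cm/s (R² = %.3f)",
                                     object$permeability, object$fit_r2)) +
    ggplot2::theme_minimal()
}
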