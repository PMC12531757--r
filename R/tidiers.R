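# broom-style tidiers for fitted result objects.

#' Tidy a group-comparison result
#'
#' One row per group-vs-control comparison, with the adjusted p-value of
#' the post hoc test that was actually run.
#'
#' @param x A `comparison_result` from [compare_to_control()] or
#'   [two_group_test()].
#' @param ... Unused.
#' @return A tibble with columns `group, estimate, statistic, p_adj,
#'   significant`.
#' @export
#' @method tidy comparison_result
tidy.comparison_result <- function(x, ...) {
  x$comparisons
}

#' Glance at a group-comparison result
#'
#' @inheritParams tidy.comparison_result
#' @return A one-row tibble: `test_name, branch, global_p, alpha,
#'   n_comparisons`.
#' @export
#' @method glance comparison_result
glance.comparison_result <- function(x, ...) {
  tibble::tibble(test_name = x$test_name, branch = x$branch,
                 global_p = x$global_p, alpha = x$alpha,
                 n_comparisons = nrow(x$comparisons))
}

#' Tidy a permeability estimate
#'
#' Long name/value view of the fitted quantities.
#'
#' @param x A `permeability_result` from [estimate_permeability()].
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
#' @method tidy permeability_result
tidy.permeability_result <- function(x, ...) {
  tibble::tibble(
    term = c("permeability", "flux_slope", "delta_i", "geometric_factor"),
    estimate = c(x$permeability, x$flux_slope, x$delta_i, x$geometric_factor)
  )
}

#' Glance at a permeability estimate
#'
#' @inheritParams tidy.permeability_result
#' @return The one-row result tibble (fit quality and flags included).
#' @export
#' @method glance permeability_result
glance.permeability_result <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  attr(out, "fit") <- NULL
  out
}
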