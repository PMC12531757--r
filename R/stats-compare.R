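# Normality-gated group comparison workflow: Shapiro-Wilk per group, then
# one-way ANOVA + Dunnett against the control, or Kruskal-Wallis + Dunn's
# test with Holm adjustment when any group departs from normality.

#' Compare each group against a control
#'
#' Assesses normality per group with Shapiro-Wilk at `alpha`. When every
#' group passes, runs one-way ANOVA with Dunnett post hoc comparisons of
#' each group against the control; otherwise runs Kruskal-Wallis with
#' Dunn's control-vs-group z tests, Holm-adjusted. The branch actually
#' taken is recorded in the result.
#'
#' @param data Data frame with a numeric `value` column and a `group`
#'   column (names configurable).
#' @param control_label Label of the control group.
#' @param value_col,group_col Column names.
#' @param alpha Significance level used both for the normality gate and
#'   for flagging comparisons.
#' @return A `comparison_result` list: `test_name`, `branch`
#'   (`"parametric"`/`"nonparametric"`), `global_p`, `comparisons` (tibble
#'   of group vs control with statistic, adjusted p-value, significance),
#'   `normality` (tibble of per-group Shapiro p-values), `alpha`.
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(value = c(rnorm(10), rnorm(10, 2)),
#'                 group = rep(c("H", "T"), each = 10))
#' compare_to_control(d, "H")
compare_to_control <- function(data, control_label, value_col = "value",
                               group_col = "group", alpha = 0.05) {
  stopifnot(value_col %in% names(data), group_col %in% names(data))
  v <- data[[value_col]]
  g <- as.character(data[[group_col]])
  ok <- is.finite(v) & !is.na(g)
  v <- v[ok]; g <- g[ok]
  groups <- unique(g)
  if (!control_label %in% groups)
    abort(sprintf("control label '%s' not present in `%s`.",
                  control_label, group_col))
  if (length(groups) < 2) abort("need at least 2 groups.")
  ns <- table(g)
  if (any(ns < 3)) abort("every group needs n >= 3.")

  normality <- purrr::map_dfr(groups, function(gr) {
    x <- v[g == gr]
    p <- if (length(unique(x)) < 3) 0 else shapiro.test(x)$p.value
    tibble::tibble(group = gr, shapiro_p = p, normal = p >= alpha)
  })
  others <- setdiff(groups, control_label)
  fg <- factor(g, levels = c(control_label, others))

  if (all(normality$normal)) {
    fit <- aov(v ~ fg)
    global_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(fg = "Dunnett"))
    sm <- summary(gl)
    comparisons <- tibble::tibble(
      group = others,
      estimate = unname(sm$test$coefficients),
      statistic = unname(sm$test$tstat),
      p_adj = unname(as.numeric(sm$test$pvalues))
    )
    test_name <- "One-way ANOVA + Dunnett"
    branch <- "parametric"
  } else {
    kw <- kruskal.test(v, fg)
    global_p <- kw$p.value
    dn <- dunn_vs_control(v, fg, control_label)
    comparisons <- dn
    test_name <- "Kruskal-Wallis + Dunn (Holm)"
    branch <- "nonparametric"
  }
  comparisons$significant <- comparisons$p_adj < alpha
  structure(list(test_name = test_name, branch = branch,
                 global_p = global_p, comparisons = comparisons,
                 normality = normality, alpha = alpha,
                 control = control_label),
            class = "comparison_result")
}

# Dunn's z tests of each group against the control on the joint ranks,
# with tie correction; Holm adjustment over the control-vs-group family.
dunn_vs_control <- function(v, fg, control_label) {
  rk <- rank(v)
  n <- length(v)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lv <- levels(fg)
  rbar <- tapply(rk, fg, mean)
  ni <- tapply(rk, fg, length)
  others <- setdiff(lv, control_label)
  z <- vapply(others, function(gr) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) *
                 (1 / ni[[control_label]] + 1 / ni[[gr]]))
    (rbar[[gr]] - rbar[[control_label]]) / se
  }, numeric(1))
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(group = others, estimate = NA_real_, statistic = unname(z),
                 p_adj = p.adjust(unname(p), method = "holm"))
}

#' Two-tailed unpaired Student's t test
#'
#' Pooled-variance two-sample t test. When both groups have zero variance
#' and equal means the p-value is reported as 1 with a flag instead of
#' failing.
#'
#' @param a,b Numeric vectors (n >= 2 each).
#' @return A `comparison_result` with a single comparison row.
#' @export
two_group_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("each group needs n >= 2.")
  degenerate <- sd(a) == 0 && sd(b) == 0
  if (degenerate && mean(a) == mean(b)) {
    warn("zero variance in both groups with equal means; p = 1 by convention.")
    comparisons <- tibble::tibble(group = "b", estimate = 0,
                                  statistic = 0, p_adj = 1,
                                  significant = FALSE)
    return(structure(list(test_name = "Student's t (degenerate)",
                          branch = "parametric", global_p = 1,
                          comparisons = comparisons,
                          normality = NULL, alpha = 0.05, control = "a"),
                     class = "comparison_result"))
  }
  tt <- t.test(b, a, var.equal = TRUE)
  comparisons <- tibble::tibble(group = "b",
                                estimate = mean(b) - mean(a),
                                statistic = unname(tt$statistic),
                                p_adj = tt$p.value,
                                significant = tt$p.value < 0.05)
  structure(list(test_name = "Two-tailed unpaired Student's t",
                 branch = "parametric", global_p = tt$p.value,
                 comparisons = comparisons, normality = NULL,
                 alpha = 0.05, control = "a"),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> ", x$test_name, "\n", sep = "")
  cat("  global p = ", format.pval(x$global_p), "; control = ", x$control,
      "\n", sep = "")
  print(x$comparisons)
  invisible(x)
}
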