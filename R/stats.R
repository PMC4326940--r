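#' Assemble a long-format group table
#'
#' Pivots per-cell (or per-field) metric tibbles from several groups into
#' the long format consumed by [compare_two()] and [compare_many()]:
#' one row per group x id x metric.
#'
#' @param ... Named tibbles, one per group (names become group labels),
#'   each with an id column and numeric metric columns.
#' @param id_col Name of the id column (default `"cell_id"`).
#' @param metrics Metric columns to keep; default: all numeric columns.
#' @return Tibble with columns `group`, `id`, `metric`, `value`.
#' @export
group_table <- function(..., id_col = "cell_id", metrics = NULL) {
  groups <- list(...)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("every group must be named", call. = FALSE)
  out <- purrr::imap(groups, function(df, g) {
    num <- names(df)[vapply(df, is.numeric, TRUE)]
    num <- setdiff(num, id_col)
    if (!is.null(metrics)) num <- intersect(num, metrics)
    df |>
      dplyr::select(dplyr::all_of(c(id_col, num))) |>
      tidyr::pivot_longer(dplyr::all_of(num), names_to = "metric",
                          values_to = "value") |>
      dplyr::mutate(group = g, .before = 1) |>
      dplyr::rename(id = dplyr::all_of(id_col))
  })
  dplyr::bind_rows(out)
}

check_groups <- function(table, metric, min_n = 2) {
  tb <- dplyr::filter(table, .data$metric == !!metric)
  if (nrow(tb) == 0) stop("no rows for metric '", metric, "'",
                          call. = FALSE)
  if (any(!is.finite(tb$value)))
    stop("non-finite values for metric '", metric, "'", call. = FALSE)
  ns <- table(tb$group)
  if (any(ns < min_n))
    stop("group '", names(ns)[ns < min_n][1], "' has fewer than ", min_n,
         " observations", call. = FALSE)
  tb
}

#' Two-group comparison (t-test with means and SEM)
#'
#' Student's two-sample t-test on one metric of a long group table, with
#' per-group mean and standard error of the mean. Equal variances are
#' assumed by default; set `var_equal = FALSE` for Welch's test.
#'
#' @param table Long table from [group_table()] (columns `group`, `id`,
#'   `metric`, `value`).
#' @param metric Which metric to compare.
#' @param var_equal Assume equal variances (default `TRUE`).
#' @return One-row tibble: `metric`, `group1`, `group2`, `mean1`, `sem1`,
#'   `n1`, `mean2`, `sem2`, `n2`, `estimate` (mean1 - mean2), `statistic`
#'   (t), `df`, `p_value`, `method`.
#' @export
compare_two <- function(table, metric, var_equal = TRUE) {
  tb <- check_groups(table, metric)
  gs <- sort(unique(tb$group))
  if (length(gs) != 2)
    stop("compare_two needs exactly 2 groups, found ", length(gs),
         call. = FALSE)
  v1 <- tb$value[tb$group == gs[1]]
  v2 <- tb$value[tb$group == gs[2]]
  if (stats::sd(v1) == 0 && stats::sd(v2) == 0) {
    # degenerate but well-defined limits: identical constant groups, or
    # perfectly separated constant groups
    sep <- mean(v1) != mean(v2)
    tt <- list(statistic = c(t = if (sep) Inf else 0),
               parameter = c(df = length(v1) + length(v2) - 2),
               p.value = if (sep) 0 else 1,
               method = "Two Sample t-test")
  } else {
    tt <- stats::t.test(v1, v2, var.equal = var_equal)
  }
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  tibble::tibble(
    metric = metric, group1 = gs[1], group2 = gs[2],
    mean1 = mean(v1), sem1 = sem(v1), n1 = length(v1),
    mean2 = mean(v2), sem2 = sem(v2), n2 = length(v2),
    estimate = mean(v1) - mean(v2),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, method = tt$method)
}

#' Multi-group comparison (one-way ANOVA with Tukey HSD)
#'
#' One-way analysis of variance over three or more groups on one metric,
#' followed by Tukey's honest-significant-difference post hoc pairwise
#' comparisons with adjusted p-values.
#'
#' @param table Long table from [group_table()].
#' @param metric Which metric to compare.
#' @return A `group_anova` object; use [tidy()] for the Tukey pairwise
#'   table and [glance()] for the one-row ANOVA summary.
#' @export
compare_many <- function(table, metric) {
  tb <- check_groups(table, metric)
  gs <- sort(unique(tb$group))
  if (length(gs) < 3)
    stop("fewer than 3 groups; use compare_two() for a two-group ",
         "comparison", call. = FALSE)
  tb$group <- factor(tb$group)
  fit <- stats::aov(value ~ group, data = tb)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  groups <- tb |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sem = sem(.data$value), .groups = "drop")
  structure(list(
    metric = metric, fit = fit, groups = groups,
    anova = tibble::tibble(
      statistic = an[["F value"]][1], df1 = an[["Df"]][1],
      df2 = an[["Df"]][2], p_value = an[["Pr(>F)"]][1]),
    tukey = tibble::tibble(
      contrast = rownames(tk), estimate = tk[, "diff"],
      conf_low = tk[, "lwr"], conf_high = tk[, "upr"],
      adj_p_value = tk[, "p adj"])),
    class = "group_anova")
}

#' @export
print.group_anova <- function(x, ...) {
  cat("<group_anova> metric '", x$metric, "': F(", x$anova$df1, ", ",
      x$anova$df2, ") = ", signif(x$anova$statistic, 4), ", p = ",
      signif(x$anova$p_value, 3), "\n", sep = "")
  print(x$tukey)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted group comparison
#'
#' @param x A `group_anova` from [compare_many()].
#' @param ... Unused.
#' @return For `tidy()`, the Tukey pairwise table (one row per contrast);
#'   for `glance()`, a one-row tibble with the ANOVA F statistic, degrees
#'   of freedom and p-value.
#' @export
tidy.group_anova <- function(x, ...) x$tukey

#' @rdname tidy.group_anova
#' @export
glance.group_anova <- function(x, ...) x$anova

#' Tidy a CD39 classification
#'
#' @param x A `cd39_classification` from [classify_reference()].
#' @param ... Unused.
#' @return For `tidy()`, the per-cell table with classes; for `glance()`,
#'   a one-row tibble of class percentages.
#' @export
tidy.cd39_classification <- function(x, ...) x$cells

#' @rdname tidy.cd39_classification
#' @export
glance.cd39_classification <- function(x, ...) {
  tidyr::pivot_wider(x$summary[, c("cd39_class", "percent")],
                     names_from = "cd39_class", values_from = "percent",
                     names_prefix = "pct_")
}
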