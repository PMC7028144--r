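# Group-comparison statistics used for phenotype contrasts: Welch two-sample
# t-tests and one-way ANOVA with Tukey HSD adjusted pairwise p-values.

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test with Satterthwaite degrees of freedom,
#' returned broom-style as a one-row tibble. When both groups are constant
#' the conventional limits are used: p = 1 for equal means, p = 0 (infinite
#' t) otherwise.
#'
#' @param a,b Numeric vectors (>= 2 finite values each).
#' @return One-row tibble: group sizes, means, SDs, `statistic`, `df`,
#'   `p_value`.
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop_rootkin("each group needs at least two values", "rootkin_error_parameter")
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop_rootkin("inputs must be finite", "rootkin_error_domain")
  }
  base <- tibble::tibble(
    method = "welch_t",
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), mean_b = mean(b),
    sd_a = sd(a), sd_b = sd(b)
  )
  if (sd(a) == 0 && sd(b) == 0) {
    # degenerate: t.test refuses constant data
    if (mean(a) == mean(b)) {
      return(dplyr::mutate(base, statistic = 0, df = NA_real_, p_value = 1))
    }
    return(dplyr::mutate(base,
                         statistic = sign(mean(a) - mean(b)) * Inf,
                         df = NA_real_, p_value = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  dplyr::mutate(base,
                statistic = unname(ht$statistic),
                df = unname(ht$parameter),
                p_value = ht$p.value)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Fits `value ~ group` by one-way ANOVA and adjusts all pairwise contrasts
#' with Tukey's honestly-significant-difference procedure (studentized-range
#' distribution).
#'
#' @param data A data frame with a numeric `value` column and a `group`
#'   column (>= 3 groups, >= 2 values each), or a named list of numeric
#'   vectors.
#' @return An object of class `anova_tukey`: `glance()` gives the ANOVA `F`,
#'   degrees of freedom and p-value; `tidy()` the pairwise Tukey table
#'   (`contrast`, `estimate`, `conf_low`, `conf_high`, `p_adj`).
#' @export
anova_tukey <- function(data) {
  if (is.list(data) && !is.data.frame(data)) {
    data <- tibble::tibble(
      group = rep(names(data), lengths(data)),
      value = unlist(data, use.names = FALSE)
    )
  }
  if (!all(c("value", "group") %in% names(data))) {
    stop_rootkin("`data` must have `value` and `group` columns", "rootkin_error_schema")
  }
  data$group <- factor(data$group)
  sizes <- table(data$group)
  if (length(sizes) < 3L) {
    stop_rootkin("at least 3 groups are required", "rootkin_error_parameter")
  }
  if (any(sizes < 2L)) {
    stop_rootkin("every group needs at least two values", "rootkin_error_parameter")
  }
  if (any(!is.finite(data$value))) {
    stop_rootkin("values must be finite", "rootkin_error_domain")
  }
  fit <- stats::aov(value ~ group, data = data)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  pairwise <- tibble::tibble(
    contrast = rownames(tk),
    estimate = tk[, "diff"],
    conf_low = tk[, "lwr"],
    conf_high = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  structure(
    list(
      groups = data %>%
        dplyr::group_by(.data$group) %>%
        dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                         sd = sd(.data$value), .groups = "drop"),
      statistic = tab[1, "F value"],
      df1 = tab[1, "Df"],
      df2 = tab[2, "Df"],
      p_value = tab[1, "Pr(>F)"],
      pairwise = pairwise
    ),
    class = "anova_tukey"
  )
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("<anova_tukey> F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$statistic, x$p_value))
  print(x$pairwise)
  invisible(x)
}

#' @rdname anova_tukey
#' @param x An `anova_tukey` object.
#' @param ... Unused.
#' @export
glance.anova_tukey <- function(x, ...) {
  tibble::tibble(method = "anova_tukey", statistic = x$statistic,
                 df1 = x$df1, df2 = x$df2, p_value = x$p_value)
}

#' @rdname anova_tukey
#' @export
tidy.anova_tukey <- function(x, ...) x$pairwise

#' Compare one metric between two groups of roots
#'
#' Convenience wrapper running [welch_t()] on a metric column of a per-root
#' summary table split by a grouping column.
#'
#' @param data A data frame (e.g. from [analyze_kinematics()] joined with a
#'   genotype column).
#' @param metric Name of the numeric column to compare.
#' @param group Name of the two-level grouping column.
#' @return One-row tibble as from [welch_t()], with `metric` and the group
#'   labels prepended.
#' @export
compare_groups <- function(data, metric, group = "genotype") {
  if (!metric %in% names(data) || !group %in% names(data)) {
    stop_rootkin("`metric` and `group` must name columns of `data`",
                 "rootkin_error_schema")
  }
  levels <- unique(data[[group]])
  if (length(levels) != 2L) {
    stop_rootkin("`group` must have exactly two levels", "rootkin_error_parameter")
  }
  vals <- split(data[[metric]], data[[group]])
  vals <- lapply(vals, function(v) v[is.finite(v)])
  out <- welch_t(vals[[as.character(levels[1])]], vals[[as.character(levels[2])]])
  dplyr::bind_cols(
    tibble::tibble(metric = metric,
                   group_a = as.character(levels[1]),
                   group_b = as.character(levels[2])),
    out
  )
}
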