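new_test_result <- function(test_name, labels, statistic, df1, df2, p_value,
                            ns, degenerate = FALSE) {
  out <- tibble::tibble(
    test_name = test_name,
    group_a = labels[1],
    group_b = if (length(labels) > 1) labels[2] else NA_character_,
    statistic = statistic,
    df1 = df1,
    df2 = df2,
    p_value = p_value,
    n_a = ns[1],
    n_b = if (length(ns) > 1) ns[2] else NA_integer_,
    degenerate = degenerate
  )
  class(out) <- c("assay_test", class(out))
  out
}

#' Unpaired two-tailed t-test
#'
#' Classical two-sample t-test with pooled variance (Student), the form
#' consistent with an accompanying F-test of equal variances; set
#' `welch = TRUE` for the unequal-variance form. When both groups are
#' constant with equal means the statistic is 0 and p is 1 by convention
#' (flagged `degenerate`).
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param welch Use Welch's t.
#' @param labels Group labels for the output row.
#' @return One-row tibble of class `assay_test`: `test_name`, `statistic`
#'   (t), `df1` (degrees of freedom), `p_value`, group sizes.
#' @export
t_test_unpaired <- function(group_a, group_b, welch = FALSE,
                            labels = c("a", "b")) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  if (any(!is.finite(c(group_a, group_b)))) {
    stop("values must be finite", call. = FALSE)
  }
  nm <- if (welch) "t_welch_two_tailed" else "t_unpaired_two_tailed"
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    equal <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(new_test_result(nm, labels,
                           statistic = if (equal) 0 else Inf,
                           df1 = length(group_a) + length(group_b) - 2,
                           df2 = NA_real_,
                           p_value = if (equal) 1 else 0,
                           ns = c(length(group_a), length(group_b)),
                           degenerate = TRUE))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = !welch)
  new_test_result(nm, labels, statistic = unname(ht$statistic),
                  df1 = unname(ht$parameter), df2 = NA_real_,
                  p_value = ht$p.value,
                  ns = c(length(group_a), length(group_b)))
}

#' One-way ANOVA across all groups
#'
#' Fixed-effects one-way analysis of variance: F with (k-1, N-k) degrees of
#' freedom. All-constant identical groups are degenerate (0/0): reported as
#' statistic 0, p 1, flagged.
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2), or a
#'   data frame with `value` and `group` columns.
#' @return One-row tibble of class `assay_test` (`df1` = k-1,
#'   `df2` = N-k).
#' @export
one_way_anova <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    stop(">= 2 groups with n >= 2 each required", call. = FALSE)
  }
  labels <- names(groups)
  if (is.null(labels)) labels <- as.character(seq_along(groups))
  k <- length(groups)
  n_tot <- sum(lengths(groups))
  if (all(vapply(groups, stats::sd, numeric(1)) == 0) &&
      stats::sd(vapply(groups, mean, numeric(1))) == 0) {
    return(new_test_result("one_way_anova",
                           c(paste(labels, collapse = "|"), NA),
                           statistic = 0, df1 = k - 1, df2 = n_tot - k,
                           p_value = 1, ns = c(n_tot, NA), degenerate = TRUE))
  }
  df <- data.frame(value = unlist(groups),
                   group = factor(rep(labels, lengths(groups))))
  ht <- stats::oneway.test(value ~ group, data = df, var.equal = TRUE)
  new_test_result("one_way_anova", c(paste(labels, collapse = "|"), NA),
                  statistic = unname(ht$statistic),
                  df1 = unname(ht$parameter[1]),
                  df2 = unname(ht$parameter[2]),
                  p_value = ht$p.value, ns = c(n_tot, NA))
}

#' F-test of equal variances
#'
#' F is the larger sample variance over the smaller; the two-tailed p comes
#' from the F distribution with the matching degrees of freedom. Two
#' zero-variance groups are degenerate: F = 1, p = 1, flagged.
#'
#' @param group_a,group_b Numeric vectors, each n >= 2.
#' @param labels Group labels for the output row.
#' @return One-row tibble of class `assay_test` (`statistic` = F, `df1`
#'   numerator df, `df2` denominator df).
#' @export
f_variance_test <- function(group_a, group_b, labels = c("a", "b")) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs n >= 2", call. = FALSE)
  }
  va <- stats::var(group_a)
  vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    return(new_test_result("f_variance", labels, statistic = 1,
                           df1 = length(group_a) - 1,
                           df2 = length(group_b) - 1, p_value = 1,
                           ns = c(length(group_a), length(group_b)),
                           degenerate = TRUE))
  }
  if (va >= vb) {
    f <- va / vb; d1 <- length(group_a) - 1; d2 <- length(group_b) - 1
  } else {
    f <- vb / va; d1 <- length(group_b) - 1; d2 <- length(group_a) - 1
  }
  p <- min(2 * stats::pf(f, d1, d2, lower.tail = FALSE), 1)
  new_test_result("f_variance", labels, statistic = f, df1 = d1, df2 = d2,
                  p_value = p, ns = c(length(group_a), length(group_b)))
}

#' t-based 95% confidence limits of a mean
#'
#' @param x Numeric vector, n >= 2.
#' @param level Confidence level.
#' @return Tibble with `mean`, `lower`, `upper`, `n`.
#' @export
ci_mean <- function(x, level = 0.95) {
  n <- length(x)
  stopifnot(n >= 2)
  se <- stats::sd(x) / sqrt(n)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * se
  tibble::tibble(mean = mean(x), lower = mean(x) - half,
                 upper = mean(x) + half, n = n)
}

# broom-style methods --------------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.assay_test <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.assay_test <- function(x, ...) {
  tibble::tibble(test_name = x$test_name, statistic = x$statistic,
                 p_value = x$p_value, degenerate = x$degenerate)
}

#' @export
tidy.plate_threshold <- function(x, ...) {
  tibble::tibble(value = x$value, bin_width = x$bin_width, mode = x$mode,
                 run_length = x$run_length,
                 stressed_well = x$derived_from[1],
                 unstressed_well = x$derived_from[2])
}

#' @export
glance.plate_threshold <- function(x, ...) {
  tibble::tibble(value = x$value, bin_width = x$bin_width)
}

#' @export
tidy.translocation_summary <- function(x, ...) x$summary

#' @export
glance.translocation_summary <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x$summary), n_cells = sum(x$summary$n),
                 min_p = if (nrow(x$tests)) min(x$tests$p_value) else NA_real_)
}

#' @export
tidy.cell_segmentation <- function(x, ...) x$cells_tbl

#' @export
glance.cell_segmentation <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$cells_tbl),
                 n_border = sum(x$cells_tbl$touches_border),
                 n_dropped_no_er = x$n_dropped_no_er)
}

#' @export
tidy.eres_detection <- function(x, ...) x$objects

#' @export
glance.eres_detection <- function(x, ...) {
  tibble::tibble(n_objects = nrow(x$objects),
                 n_assigned = sum(x$objects$cell_id > 0),
                 median_diameter_um =
                   stats::median(x$objects$equivalent_diameter_um))
}

# figures --------------------------------------------------------------------

#' Box plot of per-cell ratios by treatment (whiskers = min/max)
#'
#' @param object A `translocation_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.translocation_summary <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(x = .data$treatment)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$whisker_low, ymax = .data$whisker_high),
      width = 0.25) +
    ggplot2::geom_crossbar(
      ggplot2::aes(y = .data$median, ymin = .data$q1, ymax = .data$q3),
      width = 0.6, fill = "grey90") +
    ggplot2::labs(x = NULL, y = "nuclear:ER ratio") +
    ggplot2::theme_classic()
}

#' Bar plot of percent activation per well with roles
#'
#' @param object Tibble from [percent_activation()] joined to a layout
#'   (needs `well_id`, `percent_activation`; `role` optional).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_percent_activation <- function(object, ...) {
  aes <- if ("role" %in% names(object)) {
    ggplot2::aes(x = .data$well_id, y = .data$percent_activation,
                 fill = .data$role)
  } else {
    ggplot2::aes(x = .data$well_id, y = .data$percent_activation)
  }
  ggplot2::ggplot(object, aes) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% activation") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Per-treatment mean with 95% confidence limits
#'
#' @param values Tibble with `value` and `group` columns.
#' @return A ggplot (bars = group means, error bars = t-based 95% CI).
#' @export
plot_group_means <- function(values) {
  s <- values |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(ci_mean(.data$value), .groups = "drop")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey80") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper), width = 0.25) +
    ggplot2::labs(x = NULL, y = "mean ± 95% CI") +
    ggplot2::theme_classic()
}

#' Render a report bundle to disk
#'
#' Writes the figures and tables a run produces: the treatment box plot
#' (whiskers min/max), per-well percent-activation bars, the statistics
#' table, and a run-metadata YAML (seed, config hash, package versions).
#' Sections whose inputs are absent are skipped. Re-rendering identical
#' inputs rewrites identical tables (figure files are raster/vector output;
#' the tables and metadata are the stable record).
#'
#' @param results Named list, any of: `translocation` (a
#'   `translocation_summary`), `wells` (percent-activation tibble),
#'   `tests` (rows of `assay_test`), `config` (list), `seed` (integer).
#' @param out_dir Output directory, created if needed.
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(results, out_dir) {
  if (length(results) == 0) stop("at least one result table required",
                                 call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  if (!is.null(results$translocation)) {
    f <- file.path(out_dir, "ratio_boxplot.png")
    ggplot2::ggsave(f, autoplot.translocation_summary(results$translocation),
                    width = 5, height = 4, dpi = 150)
    write_table(results$translocation$summary,
                file.path(out_dir, "ratio_summary.csv"))
    written <- c(written, f, file.path(out_dir, "ratio_summary.csv"))
  }
  if (!is.null(results$wells)) {
    f <- file.path(out_dir, "percent_activation.png")
    ggplot2::ggsave(f, plot_percent_activation(results$wells),
                    width = 6, height = 4, dpi = 150)
    write_table(results$wells, file.path(out_dir, "well_table.csv"))
    written <- c(written, f, file.path(out_dir, "well_table.csv"))
  }
  if (!is.null(results$tests)) {
    write_table(results$tests, file.path(out_dir, "stats.csv"))
    written <- c(written, file.path(out_dir, "stats.csv"))
  }
  meta <- list(
    seed = results$seed,
    config_hash = if (!is.null(results$config)) rlang::hash(results$config)
                  else NULL,
    package_version = as.character(utils::packageVersion("translocatr")),
    r_version = R.version.string,
    note = "raw p-values; no multiple-testing correction applied"
  )
  yaml::write_yaml(meta[!vapply(meta, is.null, logical(1))],
                   file.path(out_dir, "run_metadata.yaml"))
  written <- c(written, file.path(out_dir, "run_metadata.yaml"))
  invisible(written)
}
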