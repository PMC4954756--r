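#' Per-cell nuclear:ER intensity ratios
#'
#' For every segmented cell, the mean ATF6-channel intensity over its
#' nucleus pixels and over its ER pixels, and their ratio — the per-cell
#' translocation statistic. Cells with non-positive ER mean are dropped and
#' counted; border-touching cells are excluded by default.
#'
#' @param atf6 A [channel_image()] of the ATF6/GFP channel.
#' @param seg A `cell_segmentation` from [segment_cells()] on the same
#'   field.
#' @param include_border Keep border-touching cells? Default `FALSE`.
#' @return Tibble with `cell_id`, `well_id`, `nuclear_mean`, `er_mean`,
#'   `ratio`, `touches_border`; attribute `n_dropped_zero_er` counts cells
#'   removed for `er_mean <= 0`.
#' @export
score_cells <- function(atf6, seg, include_border = FALSE) {
  stopifnot(inherits(seg, "cell_segmentation"))
  if (!identical(dim(atf6$pixels), dim(seg$nuclei$labels))) {
    stop("ATF6 image and masks have different dimensions", call. = FALSE)
  }
  n <- nrow(seg$cells_tbl)
  out <- tibble::tibble(cell_id = integer(), well_id = character(),
                        nuclear_mean = numeric(), er_mean = numeric(),
                        ratio = numeric(), touches_border = logical())
  attr(out, "n_dropped_zero_er") <- 0L
  if (n == 0) return(out)
  nuc <- seg$nuclei$labels
  erl <- seg$er$labels
  px <- atf6$pixels
  mean_by <- function(lab) {
    s <- rowsum(px[lab > 0], lab[lab > 0])
    cnt <- tabulate(lab[lab > 0], nbins = n)
    v <- rep(NA_real_, n)
    v[as.integer(rownames(s))] <- s[, 1] / cnt[as.integer(rownames(s))]
    v
  }
  nuclear_mean <- mean_by(nuc)
  er_mean <- mean_by(erl)
  out <- tibble::tibble(
    cell_id = seg$cells_tbl$cell_id,
    well_id = atf6$well_id,
    nuclear_mean = nuclear_mean,
    er_mean = er_mean,
    ratio = nuclear_mean / er_mean,
    touches_border = seg$cells_tbl$touches_border
  )
  if (!include_border) out <- dplyr::filter(out, !.data$touches_border)
  bad <- is.na(out$er_mean) | out$er_mean <= 0
  if (any(bad)) {
    message(sum(bad), " cell(s) with non-positive ER mean dropped")
    out <- out[!bad, ]
  }
  attr(out, "n_dropped_zero_er") <- sum(bad)
  out
}

#' Derive the plate-adaptive activation threshold
#'
#' The activation threshold is the minimum nuclear:ER ratio greater than 1
#' at which the stressed-control well's histogram rises above the
#' unstressed control's. Both ratio sets are histogrammed on common
#' right-closed bins of width `bin_width` starting at 0; per-bin counts are
#' normalized to each population's size (set `mode = "count"` for raw
#' counts). The threshold is the lower edge of the lowest bin whose left
#' edge exceeds 1 where the stressed frequency strictly exceeds the
#' unstressed frequency and the next `run_length - 1` bins do not fall back
#' below it — a guard against single-bin sampling noise (disable with
#' `run_length = 1`).
#'
#' @param stressed,unstressed Numeric ratio vectors, or tibbles from
#'   [score_cells()] (their `ratio` column is used).
#' @param bin_width Histogram bin width in ratio units.
#' @param mode `"frequency"` (population-normalized, default) or
#'   `"count"`.
#' @param run_length Number of consecutive qualifying bins required.
#' @return Object of class `plate_threshold`: list with `value` (the
#'   threshold, always > 1), `bin_width`, `mode`, `run_length`,
#'   `derived_from`.
#' @export
derive_threshold <- function(stressed, unstressed, bin_width = 0.05,
                             mode = c("frequency", "count"),
                             run_length = 3) {
  mode <- match.arg(mode)
  wells <- c(stressed = "stressed", unstressed = "unstressed")
  if (is.data.frame(stressed)) {
    if (length(unique(stressed$well_id))) wells["stressed"] <-
        paste(unique(stressed$well_id), collapse = "+")
    stressed <- stressed$ratio
  }
  if (is.data.frame(unstressed)) {
    if (length(unique(unstressed$well_id))) wells["unstressed"] <-
        paste(unique(unstressed$well_id), collapse = "+")
    unstressed <- unstressed$ratio
  }
  if (length(stressed) == 0 || length(unstressed) == 0) {
    stop("both ratio sets must be non-empty", call. = FALSE)
  }
  n_bins <- ceiling(max(stressed, unstressed) / bin_width) + run_length + 1
  # right-closed bins (lo, hi]: value v falls in bin ceiling(v / bin_width)
  bin_of <- function(v) pmax(ceiling(v / bin_width - 1e-9), 1)
  cs <- tabulate(bin_of(stressed), nbins = n_bins)
  cu <- tabulate(bin_of(unstressed), nbins = n_bins)
  if (mode == "frequency") {
    cs <- cs / length(stressed)
    cu <- cu / length(unstressed)
  }
  left_edge <- (seq_len(n_bins) - 1) * bin_width
  candidate <- left_edge > 1 + 1e-9 & cs > cu
  ge <- cs >= cu
  for (k in which(candidate)) {
    succ <- k + seq_len(run_length - 1)
    succ <- succ[succ <= n_bins]
    if (all(ge[succ])) {
      return(structure(list(value = left_edge[k], bin_width = bin_width,
                            mode = mode, run_length = run_length,
                            derived_from = unname(wells)),
                       class = "plate_threshold"))
    }
  }
  stop(sprintf(
    paste0("threshold derivation failed: no ratio bin > 1 where the ",
           "stressed control (%s) exceeds the unstressed control (%s) -- ",
           "failed stressed control?"),
    wells["stressed"], wells["unstressed"]), call. = FALSE)
}

#' @export
print.plate_threshold <- function(x, ...) {
  cat(sprintf(
    "<plate_threshold> %.4g (bin width %.3g, %s mode, run %d; %s vs %s)\n",
    x$value, x$bin_width, x$mode, x$run_length,
    x$derived_from[1], x$derived_from[2]))
  invisible(x)
}

#' Percent activation per well
#'
#' The percentage of cells whose nuclear:ER ratio strictly exceeds the
#' plate threshold, computed per well. Wells below `min_cells` are kept but
#' flagged with a message (sampling noise on percent activation grows fast
#' below ~50 cells).
#'
#' @param ratios Tibble with `ratio` and `well_id` columns (one or several
#'   wells), e.g. from [score_cells()] or [simulate_well_ratios()].
#' @param threshold A [derive_threshold()] result, or a bare number.
#' @param min_cells Minimum cells per well before a warning is logged.
#' @return Tibble with `well_id`, `n_cells`, `percent_activation`.
#' @export
percent_activation <- function(ratios, threshold, min_cells = 50) {
  if (is.numeric(ratios)) {
    ratios <- tibble::tibble(well_id = "well", ratio = ratios)
  }
  if (nrow(ratios) == 0) stop("empty well: no cells to score", call. = FALSE)
  thr <- if (inherits(threshold, "plate_threshold")) threshold$value
         else as.numeric(threshold)
  out <- ratios |>
    dplyr::group_by(.data$well_id) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      percent_activation = 100 * mean(.data$ratio > thr),
      .groups = "drop"
    )
  low <- out$n_cells < min_cells
  if (any(low)) {
    message(sum(low), " well(s) below ", min_cells, " cells: ",
            paste(out$well_id[low], collapse = ", "))
  }
  out
}

#' Call screening hits by the 3-SD rule
#'
#' A test well is a hit when its percent activation lies more than
#' `sd_multiplier` (default 3) sample standard deviations below the mean of
#' the stressed-control wells. Control statistics use the n-1 denominator,
#' so at least two stressed-control wells are required.
#'
#' @param wells Tibble with `well_id` and `percent_activation` (e.g. from
#'   [percent_activation()]); a `role` column is taken from here if
#'   `layout` is `NULL`.
#' @param layout A [plate_layout()] supplying `role` per well (optional if
#'   `wells` already has one).
#' @param sd_multiplier The hit cut in control SD units.
#' @return Tibble with `well_id`, `role`, `percent_activation`,
#'   `control_mean`, `control_sd`, `z_like`
#'   (`(control_mean - percent_activation) / control_sd`), `is_hit`
#'   (test wells only; controls get `NA`).
#' @export
call_hits <- function(wells, layout = NULL, sd_multiplier = 3) {
  wells <- tibble::as_tibble(wells)
  if (!is.null(layout)) {
    wells <- dplyr::left_join(
      dplyr::select(wells, -dplyr::any_of(c("role", "control_mean",
                                            "control_sd", "z_like",
                                            "is_hit"))),
      dplyr::select(layout, "well_id", "role"), by = "well_id")
  }
  if (!"role" %in% names(wells) || anyNA(wells$role)) {
    stop("every well needs a role (supply a layout)", call. = FALSE)
  }
  ctrl <- wells$percent_activation[wells$role == "stressed_control"]
  if (length(ctrl) < 2) {
    stop("need >= 2 stressed-control wells for a sample SD", call. = FALSE)
  }
  m <- mean(ctrl)
  s <- stats::sd(ctrl)
  wells |>
    dplyr::mutate(
      control_mean = m,
      control_sd = s,
      z_like = (m - .data$percent_activation) / s,
      is_hit = dplyr::if_else(
        .data$role == "test",
        .data$percent_activation < m - sd_multiplier * s,
        NA)
    )
}

#' Box-plot summary and pairwise tests of per-cell ratios by treatment
#'
#' Per-treatment quartiles with min/max whiskers and group sizes, plus
#' pairwise unpaired two-tailed t-tests between all treatment pairs.
#' Groups with fewer than `min_n` cells are excluded with a warning.
#'
#' @param ratios Tibble with `ratio` and `treatment` columns.
#' @param min_n Minimum cells per group (default 3).
#' @param welch Use Welch's t instead of pooled-variance Student's t.
#' @return Object of class `translocation_summary`: list with `summary`
#'   (per-group `n`, `whisker_low`, `q1`, `median`, `q3`, `whisker_high`,
#'   `mean`) and `tests` (pairwise [t_test_unpaired()] rows).
#' @export
summarize_nuclear_translocation <- function(ratios, min_n = 3,
                                            welch = FALSE) {
  ratios <- tibble::as_tibble(ratios)
  stopifnot(all(c("ratio", "treatment") %in% names(ratios)))
  sizes <- table(ratios$treatment)
  small <- names(sizes)[sizes < min_n]
  if (length(small)) {
    warning("excluding group(s) with n < ", min_n, ": ",
            paste(small, collapse = ", "), call. = FALSE)
    ratios <- ratios[!(ratios$treatment %in% small), ]
  }
  if (length(unique(ratios$treatment)) < 1) {
    stop("no group with enough cells", call. = FALSE)
  }
  summary <- ratios |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(
      n = dplyr::n(),
      whisker_low = min(.data$ratio),
      q1 = stats::quantile(.data$ratio, 0.25, names = FALSE),
      median = stats::median(.data$ratio),
      q3 = stats::quantile(.data$ratio, 0.75, names = FALSE),
      whisker_high = max(.data$ratio),
      mean = mean(.data$ratio),
      .groups = "drop"
    )
  grp <- split(ratios$ratio, ratios$treatment)
  pairs <- utils::combn(names(grp), 2, simplify = FALSE)
  tests <- purrr::map_dfr(pairs, function(p) {
    t_test_unpaired(grp[[p[1]]], grp[[p[2]]], welch = welch,
                    labels = p)
  })
  structure(list(summary = summary, tests = tests),
            class = "translocation_summary")
}

#' @export
print.translocation_summary <- function(x, ...) {
  cat("<translocation_summary>\n")
  print(x$summary)
  if (nrow(x$tests)) {
    cat("pairwise unpaired two-tailed t-tests:\n")
    print(x$tests)
  }
  invisible(x)
}
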