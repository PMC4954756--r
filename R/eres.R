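#' Sec31A x Sec16 product image
#'
#' Pixelwise product of the two ERES-marker channels after per-channel
#' median background subtraction (negatives clamped to 0), so that only
#' pixels carrying both Sec31A and Sec16 fluorescence are non-zero.
#'
#' @param sec31a,sec16 [channel_image()]s of the same field and slice.
#' @return A [channel_image()] with channel `"product"`.
#' @export
product_image <- function(sec31a, sec16) {
  if (!identical(dim(sec31a$pixels), dim(sec16$pixels))) {
    stop("channel dimensions differ", call. = FALSE)
  }
  p <- subtract_background(sec31a$pixels) * subtract_background(sec16$pixels)
  channel_image(p, sec31a$pixel_size_um, "product",
                slice_index = sec31a$slice_index,
                well_id = sec31a$well_id, field_id = sec31a$field_id)
}

#' Detect ER exit sites on a product image
#'
#' Automatic global Otsu threshold on the (lightly smoothed) product image,
#' connected components, intensity-based declumping (watershed seeded at
#' intensity maxima of the product), and a size gate on the equivalent
#' diameter — the diameter of the circle with the object's area. Object
#' pixel sets and areas are the raw (unsmoothed) above-threshold pixels of
#' each component, so smoothing cannot inflate sub-resolution specks past
#' the lower bound. Defaults gate to 0.167–1.67 um.
#'
#' @param product A [channel_image()] from [product_image()].
#' @param d_min_um,d_max_um Admissible equivalent-diameter window in
#'   micrometres.
#' @param declump_tolerance Watershed tolerance as a fraction of the
#'   product image's intensity range (minimum peak prominence for a split).
#' @param smooth_sigma Gaussian pre-smoothing of the product image in
#'   pixels, applied before thresholding to suppress single-pixel shot
#'   noise; 0 disables.
#' @return Object of class `eres_detection`: list with `objects` (tibble:
#'   `object_id`, `slice_index`, `cell_id` (0 until assigned), `area_px`,
#'   `equivalent_diameter_um`, `centroid_row`, `centroid_col`) and `labels`
#'   (a [label_map()] of retained objects, relabelled 1..n).
#' @export
detect_eres <- function(product, d_min_um = 0.167, d_max_um = 1.67,
                        declump_tolerance = 0.2, smooth_sigma = 0.7) {
  px <- product$pixel_size_um
  if (d_min_um / px < 1) {
    stop("d_min_um spans less than one pixel at this pixel size",
         call. = FALSE)
  }
  m <- product$pixels
  if (smooth_sigma > 0 && max(m) > 0) {
    m <- pmax(as.matrix(EBImage::gblur(EBImage::Image(m),
                                       sigma = smooth_sigma)), 0)
  }
  empty <- function() {
    structure(list(
      objects = tibble::tibble(object_id = integer(), slice_index = integer(),
                               cell_id = integer(), area_px = integer(),
                               equivalent_diameter_um = numeric(),
                               centroid_row = numeric(),
                               centroid_col = numeric()),
      labels = label_map(matrix(0L, nrow(m), ncol(m)), px)),
      class = "eres_detection")
  }
  th <- otsu_threshold(m)
  if (!is.finite(th)) return(empty())
  mask <- m > th
  if (!any(mask)) return(empty())
  # intensity declumping per clump: watershed on each connected component,
  # normalized to the component's own peak, so the split criterion does not
  # depend on how bright other spots in the field are
  cc <- matrix(as.integer(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(mask * 1)))), nrow(m))
  lab <- matrix(0L, nrow(m), ncol(m))
  next_id <- 0L
  for (comp in seq_len(max(cc))) {
    idx_c <- which(cc == comp)
    rows_c <- range((idx_c - 1) %% nrow(m) + 1)
    cols_c <- range((idx_c - 1) %/% nrow(m) + 1)
    rb <- rows_c[1]:rows_c[2]
    cb <- cols_c[1]:cols_c[2]
    submask <- cc[rb, cb, drop = FALSE] == comp
    sub <- m[rb, cb, drop = FALSE]
    sub[!submask] <- 0
    sub <- sub / max(sub)
    ws <- EBImage::watershed(EBImage::Image(sub),
                             tolerance = declump_tolerance, ext = 1)
    wl <- matrix(as.integer(EBImage::imageData(ws)), nrow = length(rb))
    wl[!submask] <- 0L
    if (max(wl) == 0) {
      wl[submask] <- 1L  # flat component: keep as one object
    }
    block <- lab[rb, cb, drop = FALSE]
    block[wl > 0] <- wl[wl > 0] + next_id
    lab[rb, cb] <- block
    next_id <- next_id + max(wl)
  }
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (length(ids) == 0) return(empty())
  # object pixel sets are the raw (unsmoothed) above-threshold pixels,
  # assigned to the declumped seeds by propagation; smoothing therefore
  # cannot inflate sub-resolution specks past the lower diameter bound,
  # nor can it clip dim spots whose smoothed support is narrower than
  # their raw support
  raw_mask <- product$pixels > th
  grown <- EBImage::propagate(EBImage::Image(product$pixels /
                                               max(product$pixels)),
                              seeds = EBImage::Image(lab),
                              mask = EBImage::Image((raw_mask | lab > 0) * 1))
  lab <- matrix(as.integer(EBImage::imageData(grown)), nrow(m))
  lab[!raw_mask] <- 0L
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (length(ids) == 0) return(empty())
  areas <- tabulate(lab[lab > 0], nbins = max(ids))
  eq_d <- 2 * sqrt(areas / pi) * px
  keep <- which(areas > 0 & eq_d >= d_min_um & eq_d <= d_max_um)
  lab[!(lab %in% keep)] <- 0L
  lab <- relabel_sequential(lab)
  n <- max(lab)
  if (n == 0) return(empty())
  idx <- which(lab > 0)
  rows <- (idx - 1) %% nrow(lab) + 1
  cols <- (idx - 1) %/% nrow(lab) + 1
  l <- lab[idx]
  area <- tabulate(l, nbins = n)
  objects <- tibble::tibble(
    object_id = seq_len(n),
    slice_index = product$slice_index,
    cell_id = 0L,
    area_px = area,
    equivalent_diameter_um = 2 * sqrt(area / pi) * px,
    centroid_row = as.numeric(rowsum(rows, l) / area),
    centroid_col = as.numeric(rowsum(cols, l) / area)
  )
  structure(list(objects = objects, labels = label_map(lab, px)),
            class = "eres_detection")
}

#' @export
print.eres_detection <- function(x, ...) {
  cat(sprintf("<eres_detection> %d objects, slice %s\n", nrow(x$objects),
              paste(unique(x$objects$slice_index), collapse = ",")))
  invisible(x)
}

#' Build an `eres_detection` from ground-truth punctum masks
#'
#' Wraps the generator's true punctum disks (double-positive puncta only)
#' in the same container [detect_eres()] returns, so measurement and
#' correlation operations can be exercised on known masks independently of
#' the detector.
#'
#' @param truth The `truth` element of [generate_eres_field()]'s result.
#' @param slice_index Slice index to stamp on the objects.
#' @return An `eres_detection`.
#' @export
eres_objects_from_truth <- function(truth, slice_index = 0L) {
  keep <- truth$puncta$punctum_id[truth$puncta$in_both_channels]
  lab <- truth$puncta_mask$labels
  lab[!(lab %in% keep)] <- 0L
  lab <- relabel_sequential(lab)
  px <- truth$puncta_mask$pixel_size_um
  n <- max(lab)
  idx <- which(lab > 0)
  l <- lab[idx]
  area <- tabulate(l, nbins = n)
  objects <- tibble::tibble(
    object_id = seq_len(n),
    slice_index = as.integer(slice_index),
    cell_id = 0L,
    area_px = area,
    equivalent_diameter_um = 2 * sqrt(area / pi) * px,
    centroid_row = as.numeric(rowsum((idx - 1) %% nrow(lab) + 1, l) / area),
    centroid_col = as.numeric(rowsum((idx - 1) %/% nrow(lab) + 1, l) / area)
  )
  structure(list(objects = objects, labels = label_map(lab, px)),
            class = "eres_detection")
}

#' Assign detected ERES to cells
#'
#' Each object gets the label of the cell containing its centroid; objects
#' whose centroid falls on background get `cell_id` 0 and are excluded from
#' per-cell statistics downstream.
#'
#' @param det An `eres_detection`.
#' @param cells A [label_map()] of whole cells (e.g. from
#'   [segment_cells()]).
#' @return The `eres_detection` with `objects$cell_id` filled.
#' @export
assign_to_cells <- function(det, cells) {
  stopifnot(inherits(det, "eres_detection"))
  lab <- cells$labels
  ob <- det$objects
  if (nrow(ob)) {
    r <- pmin(pmax(round(ob$centroid_row), 1), nrow(lab))
    c_ <- pmin(pmax(round(ob$centroid_col), 1), ncol(lab))
    det$objects$cell_id <- lab[cbind(r, c_)]
  }
  det
}

#' Measure per-object channel intensities
#'
#' Mean of each original (unprocessed) channel over every object's pixels,
#' added as `mean_<channel>` columns.
#'
#' @param det An `eres_detection`.
#' @param channels Named list of [channel_image()]s, e.g.
#'   `list(sec31a = ..., sec16 = ..., atf6 = ..., er = ...)`.
#' @return The `eres_detection` with intensity columns filled.
#' @export
measure_eres <- function(det, channels) {
  stopifnot(inherits(det, "eres_detection"))
  if (is.null(names(channels)) || any(names(channels) == "")) {
    stop("`channels` must be a named list", call. = FALSE)
  }
  lab <- det$labels$labels
  n <- max(lab)
  idx <- which(lab > 0)
  l <- lab[idx]
  area <- tabulate(l, nbins = n)
  for (nm in names(channels)) {
    ci <- channels[[nm]]
    if (!identical(dim(ci$pixels), dim(lab))) {
      stop("channel '", nm, "' has mismatched dimensions", call. = FALSE)
    }
    v <- if (n > 0) as.numeric(rowsum(ci$pixels[idx], l) / area) else numeric()
    det$objects[[paste0("mean_", nm)]] <- v
  }
  det
}

# Pearson r over two pixel vectors; NA when undefined (< 3 px or constant)
pearson_pixels <- function(a, b) {
  if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Pairwise fluorophore correlation within ERES
#'
#' Pearson correlation of two channels over the pixels of each cell's
#' retained ERES in one slice. By default all of a cell's ERES pixels are
#' pooled into one correlation per cell per slice; `by = "object"` instead
#' computes one r per object and averages (small spots make per-object r
#' noisy). Cells with fewer than 3 pooled pixels or a constant channel are
#' skipped with `r = NA` and counted in `n_undefined`.
#'
#' @param det An `eres_detection` with `cell_id` assigned (use
#'   [assign_to_cells()]); objects with `cell_id` 0 are ignored.
#' @param channel_a,channel_b [channel_image()]s of the two fluorophores
#'   (original, unprocessed intensities).
#' @param by `"pooled"` (default) or `"object"`.
#' @return Tibble with `cell_id`, `slice_index`, `r`, `n_pixels_used`,
#'   `n_eres`; attribute `n_undefined`.
#' @export
correlate_within_eres <- function(det, channel_a, channel_b,
                                  by = c("pooled", "object")) {
  by <- match.arg(by)
  stopifnot(inherits(det, "eres_detection"))
  lab <- det$labels$labels
  ob <- det$objects
  out <- tibble::tibble(cell_id = integer(), slice_index = integer(),
                        r = numeric(), n_pixels_used = integer(),
                        n_eres = integer())
  if (nrow(ob) == 0 || all(ob$cell_id == 0)) {
    attr(out, "n_undefined") <- 0L
    return(out)
  }
  idx <- which(lab > 0)
  l <- lab[idx]
  a <- channel_a$pixels[idx]
  b <- channel_b$pixels[idx]
  cell_of <- ob$cell_id[l]           # object labels are 1..n row-aligned
  res <- lapply(split(seq_along(idx), cell_of), function(ii) {
    cid <- cell_of[ii[1]]
    if (cid == 0) return(NULL)
    r <- if (by == "pooled") {
      pearson_pixels(a[ii], b[ii])
    } else {
      rs <- vapply(split(ii, l[ii]), function(jj) pearson_pixels(a[jj], b[jj]),
                   numeric(1))
      if (all(is.na(rs))) NA_real_ else mean(rs, na.rm = TRUE)
    }
    tibble::tibble(cell_id = cid,
                   slice_index = ob$slice_index[match(cid, ob$cell_id)],
                   r = r, n_pixels_used = length(ii),
                   n_eres = length(unique(l[ii])))
  })
  out <- dplyr::bind_rows(res)
  n_undef <- sum(is.na(out$r))
  if (n_undef > 0) {
    message(n_undef, " cell-slice correlation(s) undefined (too few pixels ",
            "or constant channel)")
  }
  attr(out, "n_undefined") <- n_undef
  out
}

#' Aggregate per-slice correlations per cell, then per treatment
#'
#' Mean and SD of a cell's per-slice correlations; optionally a
#' treatment-level table of per-cell means and an experiment-level mean of
#' per-cell means (the hierarchy of the reported summaries).
#'
#' @param per_slice Tibble from [correlate_within_eres()] rows of one cell
#'   stack or many (`cell_id`, `slice_index`, `r`); extra grouping columns
#'   `treatment` and `experiment` are carried through if present.
#' @return Tibble with one row per cell: `cell_id`, `mean_r`, `sd_r`,
#'   `n_slices` (plus any grouping columns); cells with zero valid slices
#'   are excluded and counted in attribute `n_excluded`.
#' @export
aggregate_correlations <- function(per_slice) {
  per_slice <- tibble::as_tibble(per_slice)
  grp <- intersect(c("experiment", "treatment", "cell_id"),
                   names(per_slice))
  out <- per_slice |>
    dplyr::filter(!is.na(.data$r)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(mean_r = mean(.data$r),
                     sd_r = stats::sd(.data$r),
                     n_slices = dplyr::n(), .groups = "drop")
  n_excl <- length(unique(per_slice$cell_id)) - nrow(out)
  if (n_excl > 0) message(n_excl, " cell(s) with no valid slice excluded")
  attr(out, "n_excluded") <- max(n_excl, 0L)
  out
}

#' Treatment- and experiment-level correlation summaries
#'
#' @param per_cell Tibble from [aggregate_correlations()] with a
#'   `treatment` column (and optionally `experiment`).
#' @return List with `per_treatment` (mean and SD over cells of the
#'   per-cell mean r, with n) and, when an `experiment` column is present,
#'   `per_experiment` (mean of per-cell means within each
#'   experiment x treatment).
#' @export
summarize_correlations <- function(per_cell) {
  stopifnot("treatment" %in% names(per_cell))
  per_treatment <- per_cell |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(mean_r = mean(.data$mean_r),
                     sd_r = stats::sd(.data$mean_r),
                     n_cells = dplyr::n(), .groups = "drop")
  out <- list(per_treatment = per_treatment)
  if ("experiment" %in% names(per_cell)) {
    out$per_experiment <- per_cell |>
      dplyr::group_by(.data$experiment, .data$treatment) |>
      dplyr::summarise(mean_r = mean(.data$mean_r),
                       n_cells = dplyr::n(), .groups = "drop")
  }
  out
}

#' ERES counts per cell and per treatment
#'
#' Integer object counts per cell per slice, summed over slices; when a
#' `treatment` column is present, treatment means with SD.
#'
#' @param objects Objects tibble of an `eres_detection` (after
#'   [assign_to_cells()]); `cell_id` 0 rows are excluded. An optional
#'   `treatment` column groups the summary.
#' @return List with `per_cell` (`cell_id`, `n_eres`) and, if treatments
#'   are present, `per_treatment` (`mean_n`, `sd_n`, `n_cells`).
#' @export
count_eres_per_cell <- function(objects) {
  if (inherits(objects, "eres_detection")) objects <- objects$objects
  objects <- tibble::as_tibble(objects)
  assigned <- dplyr::filter(objects, .data$cell_id > 0)
  grp <- intersect(c("treatment", "cell_id"), names(assigned))
  per_cell <- assigned |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(n_eres = dplyr::n(), .groups = "drop")
  out <- list(per_cell = per_cell)
  if ("treatment" %in% names(per_cell)) {
    out$per_treatment <- per_cell |>
      dplyr::group_by(.data$treatment) |>
      dplyr::summarise(mean_n = mean(.data$n_eres),
                       sd_n = stats::sd(.data$n_eres),
                       n_cells = dplyr::n(), .groups = "drop")
  }
  out
}
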