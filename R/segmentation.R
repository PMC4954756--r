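# shared image primitives ---------------------------------------------------

# median background subtraction, clamped at zero
subtract_background <- function(m) {
  pmax(m - stats::median(m), 0)
}

# Otsu threshold on an arbitrary-scale non-negative matrix
otsu_threshold <- function(m, levels = 256) {
  mx <- max(m)
  if (mx <= 0) return(Inf)
  EBImage::otsu(EBImage::Image(m / mx), range = c(0, 1), levels = levels) * mx
}

relabel_sequential <- function(lab) {
  ids <- sort(setdiff(unique(as.vector(lab)), 0L))
  if (length(ids) == 0) return(lab)
  map <- integer(max(ids))
  map[ids] <- seq_along(ids)
  out <- lab
  out[lab > 0] <- map[lab[lab > 0]]
  out
}

label_areas <- function(lab) {
  tab <- tabulate(lab[lab > 0])
  tab[tab > 0]
}

#' Segment nuclei from the DAPI channel
#'
#' Median background subtraction, global Otsu threshold, hole filling, and
#' distance-transform watershed declumping, followed by an area gate.
#' A blank image yields an empty label map, not an error.
#'
#' @param dapi A [channel_image()] of the DAPI channel.
#' @param min_area_um2,max_area_um2 Area gate in square micrometres
#'   (defaults bracket plausible U2-OS nuclei).
#' @param watershed_tolerance Minimum distance-map depth (pixels) between
#'   objects split by declumping.
#' @return A [label_map()] of nuclei.
#' @export
segment_nuclei <- function(dapi, min_area_um2 = 40, max_area_um2 = 400,
                           watershed_tolerance = 1) {
  m <- subtract_background(dapi$pixels)
  th <- otsu_threshold(m)
  mask <- m > th
  if (!any(mask)) return(label_map(matrix(0L, nrow(m), ncol(m)),
                                   dapi$pixel_size_um))
  mask_img <- EBImage::fillHull(EBImage::Image(mask * 1))
  dm <- EBImage::distmap(mask_img)
  ws <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(m))
  px2 <- dapi$pixel_size_um^2
  ids <- setdiff(unique(as.vector(lab)), 0L)
  if (length(ids)) {
    areas <- tabulate(lab[lab > 0], nbins = max(ids)) * px2
    drop <- which(areas < min_area_um2 | areas > max_area_um2)
    lab[lab %in% drop] <- 0L
  }
  label_map(relabel_sequential(lab), dapi$pixel_size_um)
}

#' Partition the ER region among cells seeded by their nuclei
#'
#' The ER-positive region is found by Otsu on the background-subtracted
#' ER-marker (GRP94) channel; the union of that region and the nuclei is
#' partitioned among cells by seeded propagation from the nucleus labels
#' (the CellProfiler propagate metric). Each cell's ER pixels are its
#' assigned ER-positive pixels minus its nucleus, so nucleus and ER masks
#' are disjoint by construction. Nuclei with no ER pixels are dropped (and
#' counted); cells touching the image border are flagged so downstream
#' scoring can exclude them.
#'
#' @param er A [channel_image()] of the ER-marker channel.
#' @param nuclei [label_map()] from [segment_nuclei()] on the same field.
#' @param lambda Regularization of the propagate metric.
#' @return An object of class `cell_segmentation`: list with label maps
#'   `nuclei`, `cells` (whole cell), `er` (ER-only pixels), the per-cell
#'   tibble `cells_tbl` (`cell_id`, `touches_border`, `nucleus_area_um2`,
#'   `er_area_um2`), and `n_dropped_no_er`.
#' @export
segment_cells <- function(er, nuclei, lambda = 1e-4) {
  if (!identical(dim(er$pixels), dim(nuclei$labels))) {
    stop("nuclei and ER image dimensions differ", call. = FALSE)
  }
  m <- subtract_background(er$pixels)
  th <- otsu_threshold(m)
  er_pos <- m > th
  nuc <- nuclei$labels
  region <- er_pos | nuc > 0
  if (max(nuc) == 0) {
    empty <- label_map(matrix(0L, nrow(m), ncol(m)), er$pixel_size_um)
    return(structure(list(nuclei = empty, cells = empty, er = empty,
                          cells_tbl = tibble::tibble(
                            cell_id = integer(), touches_border = logical(),
                            nucleus_area_um2 = numeric(),
                            er_area_um2 = numeric()),
                          pixel_size_um = er$pixel_size_um,
                          n_dropped_no_er = 0L),
                     class = "cell_segmentation"))
  }
  prop <- EBImage::propagate(EBImage::Image(m / max(max(m), 1)),
                             seeds = EBImage::Image(nuc),
                             mask = EBImage::Image(region * 1),
                             lambda = lambda)
  cell_lab <- matrix(as.integer(EBImage::imageData(prop)), nrow(m))
  er_lab <- cell_lab
  er_lab[!er_pos | nuc > 0] <- 0L

  ids <- sort(setdiff(unique(as.vector(nuc)), 0L))
  er_area_px <- tabulate(er_lab[er_lab > 0], nbins = max(ids))
  keep <- ids[er_area_px[ids] > 0]
  n_dropped <- length(ids) - length(keep)
  if (n_dropped > 0) {
    message(n_dropped, " nucleus(ei) with no ER pixels dropped")
    nuc[!(nuc %in% keep)] <- 0L
    cell_lab[!(cell_lab %in% keep)] <- 0L
    er_lab[!(er_lab %in% keep)] <- 0L
  }
  # consistent sequential relabelling across the three maps
  if (length(keep)) {
    map <- integer(max(keep))
    map[keep] <- seq_along(keep)
    for (nm in c("nuc", "cell_lab", "er_lab")) {
      lab <- get(nm)
      lab[lab > 0] <- map[lab[lab > 0]]
      assign(nm, lab)
    }
  }
  nr <- nrow(cell_lab); ncn <- ncol(cell_lab)
  border <- cell_lab[c(seq_len(nr), seq_len(nr) + (ncn - 1) * nr,
                       1 + (seq_len(ncn) - 1) * nr,
                       nr + (seq_len(ncn) - 1) * nr)]
  border_ids <- setdiff(unique(border), 0L)
  px2 <- er$pixel_size_um^2
  n_cells <- length(keep)
  cells_tbl <- tibble::tibble(
    cell_id = seq_len(n_cells),
    touches_border = seq_len(n_cells) %in% border_ids,
    nucleus_area_um2 = tabulate(nuc[nuc > 0], nbins = n_cells) * px2,
    er_area_um2 = tabulate(er_lab[er_lab > 0], nbins = n_cells) * px2
  )
  structure(list(nuclei = label_map(nuc, er$pixel_size_um),
                 cells = label_map(cell_lab, er$pixel_size_um),
                 er = label_map(er_lab, er$pixel_size_um),
                 cells_tbl = cells_tbl,
                 pixel_size_um = er$pixel_size_um,
                 n_dropped_no_er = n_dropped),
            class = "cell_segmentation")
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat(sprintf("<cell_segmentation> %d cells (%d border, %d dropped no-ER)\n",
              nrow(x$cells_tbl), sum(x$cells_tbl$touches_border),
              x$n_dropped_no_er))
  invisible(x)
}

#' Match predicted to true objects one-to-one by IoU
#'
#' Greedy best-first matching on intersection-over-union between the pixel
#' sets of two label maps; used to score segmentation and the synthetic
#' ground truth against each other.
#'
#' @param truth,pred [label_map()]s over the same field.
#' @param iou_min Minimum IoU for a pair to count as matched.
#' @return Tibble with `truth_id`, `pred_id`, `iou`, one row per match.
#' @export
match_labels <- function(truth, pred, iou_min = 0.7) {
  tl <- truth$labels; pl <- pred$labels
  stopifnot(identical(dim(tl), dim(pl)))
  both <- tl > 0 & pl > 0
  if (!any(both)) {
    return(tibble::tibble(truth_id = integer(), pred_id = integer(),
                          iou = numeric()))
  }
  ov <- as.data.frame(table(truth_id = tl[both], pred_id = pl[both]),
                      stringsAsFactors = FALSE)
  ov <- ov[ov$Freq > 0, ]
  ov$truth_id <- as.integer(ov$truth_id)
  ov$pred_id <- as.integer(ov$pred_id)
  t_area <- tabulate(tl[tl > 0])
  p_area <- tabulate(pl[pl > 0])
  ov$iou <- ov$Freq / (t_area[ov$truth_id] + p_area[ov$pred_id] - ov$Freq)
  ov <- ov[order(-ov$iou), ]
  used_t <- integer(); used_p <- integer()
  keep <- logical(nrow(ov))
  for (i in seq_len(nrow(ov))) {
    if (!(ov$truth_id[i] %in% used_t) && !(ov$pred_id[i] %in% used_p) &&
        ov$iou[i] >= iou_min) {
      keep[i] <- TRUE
      used_t <- c(used_t, ov$truth_id[i])
      used_p <- c(used_p, ov$pred_id[i])
    }
  }
  tibble::as_tibble(ov[keep, c("truth_id", "pred_id", "iou")])
}
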