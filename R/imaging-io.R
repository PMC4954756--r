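#' Plate layout: wells, roles and treatments
#'
#' Builds and validates the well-role table every plate-level operation
#' consumes. Roles are `unstressed_control` (vehicle), `stressed_control`
#' (e.g. 100 nM thapsigargin) and `test` (compound wells).
#'
#' @param wells Data frame with columns `well_id`, `role`, and optionally
#'   `treatment` and `replicate_group`.
#' @param require_controls If `TRUE` (needed whenever a plate threshold will
#'   be derived), require at least one unstressed and one stressed control.
#' @return A tibble of class `plate_layout`.
#' @examples
#' plate_layout(data.frame(
#'   well_id = c("A01", "A02", "B01"),
#'   role = c("unstressed_control", "stressed_control", "test")
#' ))
#' @export
plate_layout <- function(wells, require_controls = TRUE) {
  wells <- tibble::as_tibble(wells)
  if (!all(c("well_id", "role") %in% names(wells))) {
    stop("layout needs `well_id` and `role` columns", call. = FALSE)
  }
  if (anyDuplicated(wells$well_id)) {
    stop("well_ids must be unique", call. = FALSE)
  }
  ok <- c("unstressed_control", "stressed_control", "test")
  if (!all(wells$role %in% ok)) {
    stop("roles must be one of: ", paste(ok, collapse = ", "), call. = FALSE)
  }
  if (require_controls &&
      (!any(wells$role == "unstressed_control") ||
       !any(wells$role == "stressed_control"))) {
    stop("layout must contain at least one unstressed_control and one ",
         "stressed_control well", call. = FALSE)
  }
  if (!"treatment" %in% names(wells)) wells$treatment <- wells$role
  if (!"replicate_group" %in% names(wells)) wells$replicate_group <- wells$role
  class(wells) <- c("plate_layout", class(wells))
  wells
}

#' Read an analysis configuration from YAML
#'
#' The configuration carries everything the pipeline cannot learn from a bare
#' TIFF: the channel map (page order), the physical pixel size, and tunables
#' with their defaults. `pixel_size_um` has no default: microscope metadata
#' is not parsed, so it must be supplied.
#'
#' @param path YAML file path, or `NULL` to get the defaults (still missing
#'   `pixel_size_um`).
#' @return A named list; unspecified keys are filled from [default_config()].
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

#' @rdname read_config
#' @export
default_config <- function() {
  list(
    pixel_size_um = NULL,                    # required, no default
    channels = c("dapi", "er", "atf6"),      # page order within each slice
    connectivity = 8,
    nucleus_min_area_um2 = 40,
    nucleus_max_area_um2 = 400,
    eres_d_min_um = 0.167,
    eres_d_max_um = 1.67,
    threshold_bin_width = 0.05,
    threshold_run_length = 3,
    threshold_mode = "frequency",
    min_cells_per_well = 50,
    hit_sd_multiplier = 3
  )
}

#' Read one multichannel field from a TIFF
#'
#' Pages are interpreted channel-fastest: for each z-slice, one page per
#' channel in the order given by `channels`. Integer TIFFs (8/16-bit) are
#' restored to their exact stored values; 32-bit float TIFFs are read as-is.
#'
#' @param path TIFF / OME-TIFF file path.
#' @param pixel_size_um Physical pixel size in micrometres (required; a
#'   config-supplied value always wins over file metadata, which is not
#'   parsed).
#' @param channels Character vector naming the channels in page order.
#' @param well_id,field_id Identity metadata attached to every image.
#' @return A list of [channel_image()] objects, length
#'   `n_channels * n_slices`.
#' @export
read_field <- function(path, pixel_size_um, channels = c("dapi", "er", "atf6"),
                       well_id = "A01", field_id = 0L) {
  if (is.null(pixel_size_um)) {
    stop("`pixel_size_um` is required (no metadata default)", call. = FALSE)
  }
  if (pixel_size_um <= 0) stop("non-positive pixel size", call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nc <- length(channels)
  if (length(pages) %% nc != 0) {
    stop(sprintf("file has %d pages, not a multiple of %d channels",
                 length(pages), nc), call. = FALSE)
  }
  dims <- lapply(pages, dim)
  if (length(unique(lapply(dims, function(d) d[1:2]))) != 1) {
    stop("channels/pages have mismatched dimensions", call. = FALSE)
  }
  n_slices <- length(pages) %/% nc
  out <- vector("list", length(pages))
  k <- 1
  for (s in seq_len(n_slices) - 1L) {
    for (ci in seq_len(nc)) {
      m <- pages[[s * nc + ci]]
      if (length(dim(m)) == 3) m <- m[, , 1]  # ignore extra samples
      bits <- attr(m, "bits.per.sample")
      if (!is.null(bits) && bits %in% c(8L, 16L)) {
        # tiff normalizes unsigned ints to [0,1]; undo exactly
        m <- round(m * (2^bits - 1))
      }
      attributes(m) <- list(dim = dim(m))
      out[[k]] <- channel_image(m, pixel_size_um, channels[ci],
                                slice_index = s, well_id = well_id,
                                field_id = field_id)
      k <- k + 1
    }
  }
  validate_field(out)
}

#' Write one multichannel field as a 16-bit multi-page TIFF
#'
#' Pages are written channel-fastest (the order [read_field()] expects).
#' Intensities are rounded to the nearest integer and clamped to
#' \[0, 65535\]; integer-valued images round-trip losslessly.
#'
#' @param field List of [channel_image()] objects (one field, any number of
#'   slices).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  validate_field(field)
  # stable: slices ascending, channels kept in the order supplied
  ord <- order(purrr::map_int(field, "slice_index"))
  field <- field[ord]
  pages <- lapply(field, function(ci) {
    m <- pmin(pmax(round(ci$pixels), 0), 65535)
    m / 65535
  })
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  if (!ok) stop("failed to write TIFF: ", path, call. = FALSE)
  invisible(path)
}

#' Write a label map as 16-bit label TIFF
#'
#' @param lm A [label_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(lm, path) {
  if (max(lm$labels) > 65535) stop("more than 65535 labels", call. = FALSE)
  tiff::writeTIFF(lm$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read back a label TIFF written by [write_label_tiff()]
#' @param path File path.
#' @param pixel_size_um Pixel size to attach.
#' @return A [label_map()].
#' @export
read_label_tiff <- function(path, pixel_size_um) {
  m <- tiff::readTIFF(path)
  label_map(round(m * 65535), pixel_size_um)
}

#' Write a result table to CSV with full numeric precision
#'
#' Column names are stable and documented per result type; floats are
#' serialized with 15 significant digits so a write-then-read round trip is
#' accurate to better than 1e-9 relative.
#'
#' @param rows Data frame (may be empty: a header-only CSV is written).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  df <- as.data.frame(rows)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a CSV written by [write_table()]
#' @param path File path.
#' @return A tibble.
#' @export
read_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
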