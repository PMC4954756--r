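#' Channel image: one 2D fluorescence slice
#'
#' A `channel_image` is the package's unit of raw data: one 2D slice of one
#' fluorescence channel, with its physical pixel size and identity metadata.
#' Pixels are stored as a base R numeric matrix in row-major display
#' convention (origin top-left, `pixels[row, col]`); intensities are
#' arbitrary fluorescence units (photon-like counts), non-negative and
#' finite. All object sizes reported downstream are converted to micrometres
#' via `pixel_size_um`.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities.
#' @param pixel_size_um Physical edge length of one pixel in micrometres
#'   (must be > 0).
#' @param channel Channel label, one of
#'   `"dapi"`, `"er"`, `"atf6"`, `"sec31a"`, `"sec16"`, `"golgi"`, or
#'   `"product"` (the derived Sec31A x Sec16 image).
#' @param slice_index Zero-based z-slice index.
#' @param well_id Plate coordinate string, e.g. `"B03"`.
#' @param field_id Zero-based field (site) index within the well.
#'
#' @return An object of class `channel_image`.
#' @examples
#' img <- channel_image(matrix(0, 8, 8), pixel_size_um = 0.11, channel = "dapi")
#' dim(img$pixels)
#' @export
channel_image <- function(pixels, pixel_size_um, channel,
                          slice_index = 0L, well_id = "A01", field_id = 0L) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  storage.mode(pixels) <- "double"
  if (anyNA(pixels) || any(!is.finite(pixels)) || any(pixels < 0)) {
    stop("all intensities must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop("`pixel_size_um` must be a single positive number", call. = FALSE)
  }
  channel <- match.arg(channel, channel_levels())
  if (slice_index < 0 || field_id < 0) {
    stop("`slice_index` and `field_id` must be >= 0", call. = FALSE)
  }
  structure(
    list(
      pixels = pixels,
      pixel_size_um = as.numeric(pixel_size_um),
      channel = channel,
      slice_index = as.integer(slice_index),
      well_id = as.character(well_id),
      field_id = as.integer(field_id)
    ),
    class = "channel_image"
  )
}

channel_levels <- function() {
  c("dapi", "er", "atf6", "sec31a", "sec16", "golgi", "product")
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf(
    "<channel_image> %s  %d x %d px  %.4g um/px  well %s field %d slice %d\n",
    x$channel, nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
    x$well_id, x$field_id, x$slice_index
  ))
  invisible(x)
}

#' Extract one channel (and slice) from a field
#'
#' A *field* is a plain list of [channel_image()] objects sharing one well,
#' field and pixel size. `field_channel()` pulls out a single slice of a
#' single channel.
#'
#' @param field List of `channel_image` objects.
#' @param channel Channel label to extract.
#' @param slice_index Zero-based slice; default 0.
#' @return A `channel_image`.
#' @export
field_channel <- function(field, channel, slice_index = 0L) {
  hit <- purrr::keep(field, function(ci) {
    ci$channel == channel && ci$slice_index == slice_index
  })
  if (length(hit) == 0) {
    stop(sprintf("field has no channel '%s' at slice %d", channel, slice_index),
         call. = FALSE)
  }
  hit[[1]]
}

#' Label map: integer-labelled segmentation mask
#'
#' Non-negative integer matrix where 0 is background and each positive value
#' labels one connected object, plus the pixel size needed to express areas
#' and diameters in physical units.
#'
#' @param labels Integer matrix (>= 0).
#' @param pixel_size_um Pixel edge length in micrometres.
#' @return An object of class `label_map`.
#' @export
label_map <- function(labels, pixel_size_um) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  lab <- labels
  storage.mode(lab) <- "integer"
  if (anyNA(lab) || any(lab < 0)) {
    stop("labels must be non-negative integers", call. = FALSE)
  }
  structure(list(labels = lab, pixel_size_um = as.numeric(pixel_size_um)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  n <- length(setdiff(unique(as.vector(x$labels)), 0L))
  cat(sprintf("<label_map> %d x %d px, %d objects, %.4g um/px\n",
              nrow(x$labels), ncol(x$labels), n, x$pixel_size_um))
  invisible(x)
}

n_objects <- function(lm) length(setdiff(unique(as.vector(lm$labels)), 0L))

# checks that a list of channel_images is a consistent field
validate_field <- function(field) {
  stopifnot(length(field) >= 1)
  d <- dim(field[[1]]$pixels)
  px <- field[[1]]$pixel_size_um
  for (ci in field) {
    if (!identical(dim(ci$pixels), d)) {
      stop("all channels of one field must share identical pixel dimensions",
           call. = FALSE)
    }
    if (!isTRUE(all.equal(ci$pixel_size_um, px))) {
      stop("all channels of one field must share one pixel_size_um",
           call. = FALSE)
    }
  }
  invisible(field)
}
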