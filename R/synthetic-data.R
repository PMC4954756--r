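#' Specify a synthetic microscopy scene
#'
#' A `scene_spec` collects every knob of the synthetic field generators:
#' geometry (field size, pixel size, cell and nucleus diameters), the
#' per-cell nuclear:ER ratio model, the ERES punctum model, and the noise
#' model. Defaults emulate the assay the package quantifies: U2-OS-like
#' cells imaged at 20x for translocation scoring (0.65 um/px) — pass
#' `pixel_size_um = 0.11` and a smaller field for 100x ERES scenes.
#'
#' The per-cell true nuclear:ER ratio is drawn lognormally: median
#' `inactive_mean` (< 1, ER-retained ATF6) for inactive cells and
#' `active_mean` (> 1, nuclear ATF6) for activated cells, with
#' `lognormal_sd` on the log scale. Noise is Poisson shot noise at
#' `photon_scale` detected photons per intensity unit followed by additive
#' zero-mean Gaussian read noise (`read_sd`), on top of a constant
#' `background` offset present in all channels. Setting `photon_scale = 0`,
#' `read_sd = 0`, `background = 0` gives exact noise-free construction
#' identities.
#'
#' @param field_shape_px Integer `(rows, cols)` of the field.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param n_cells Number of cells to place.
#' @param activated_fraction Probability a cell is activated (nuclear ATF6).
#' @param ratio_params List with `inactive_mean`, `active_mean`,
#'   `lognormal_sd` of the true nuclear:ER ratio distribution.
#' @param nucleus_diameter_um,cell_diameter_um Cell geometry (nucleus disk
#'   inside cell disk; the annulus is the ER region).
#' @param eres_spec List with `n_puncta_per_cell`, `diameter_range_um`,
#'   `coloc_fraction` (probability a punctum carries both Sec31A and Sec16),
#'   `target_rho` (expected pixelwise Pearson correlation of the ATF6
#'   channel with Sec31A inside double-positive puncta), and
#'   `min_separation_um` between punctum centres.
#' @param noise List with `photon_scale`, `read_sd`, `background`.
#' @param amplitudes List of noise-free signal levels: `dapi` (nucleus),
#'   `er` (GRP94 in the ER region), `atf6_er` (ATF6 in the ER; the nucleus
#'   gets `atf6_er * true_ratio`), `punctum` (mean punctum peak),
#'   `atf6_punctum_base` and `atf6_punctum_scale` (location/scale of the
#'   correlated ATF6 signal inside puncta).
#' @param seed Integer seed; every generator call is reproducible from it.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(field_shape_px = c(512, 512),
                       pixel_size_um = 0.65,
                       n_cells = 20,
                       activated_fraction = 0.5,
                       ratio_params = list(inactive_mean = 0.8,
                                           active_mean = 2.5,
                                           lognormal_sd = 0.2),
                       nucleus_diameter_um = 14,
                       cell_diameter_um = 30,
                       eres_spec = list(n_puncta_per_cell = 15,
                                        diameter_range_um = c(0.3, 1.4),
                                        coloc_fraction = 0.8,
                                        target_rho = 0.8,
                                        min_separation_um = 1.6),
                       noise = list(photon_scale = 1, read_sd = 2,
                                    background = 10),
                       amplitudes = list(dapi = 100, er = 80, atf6_er = 60,
                                         punctum = 150,
                                         atf6_punctum_base = 80,
                                         atf6_punctum_scale = 15),
                       seed = 1L) {
  spec <- list(
    field_shape_px = as.integer(field_shape_px),
    pixel_size_um = pixel_size_um,
    n_cells = as.integer(n_cells),
    activated_fraction = activated_fraction,
    ratio_params = utils::modifyList(
      list(inactive_mean = 0.8, active_mean = 2.5, lognormal_sd = 0.2),
      ratio_params),
    nucleus_diameter_um = nucleus_diameter_um,
    cell_diameter_um = cell_diameter_um,
    eres_spec = utils::modifyList(
      list(n_puncta_per_cell = 15, diameter_range_um = c(0.3, 1.4),
           coloc_fraction = 0.8, target_rho = 0.8, min_separation_um = 1.6),
      eres_spec),
    noise = utils::modifyList(
      list(photon_scale = 1, read_sd = 2, background = 10), noise),
    amplitudes = utils::modifyList(
      list(dapi = 100, er = 80, atf6_er = 60, punctum = 150,
           atf6_punctum_base = 80, atf6_punctum_scale = 15),
      amplitudes),
    seed = as.integer(seed)
  )
  stopifnot(
    spec$activated_fraction >= 0, spec$activated_fraction <= 1,
    spec$eres_spec$coloc_fraction >= 0, spec$eres_spec$coloc_fraction <= 1,
    spec$eres_spec$target_rho >= -1, spec$eres_spec$target_rho <= 1,
    spec$nucleus_diameter_um < spec$cell_diameter_um,
    spec$pixel_size_um > 0, spec$n_cells >= 0
  )
  class(spec) <- "scene_spec"
  spec
}

#' Photon scale needed for a target signal-to-noise ratio
#'
#' For a feature of amplitude `a` over background `b` under the generator's
#' noise model, the per-pixel noise SD at the feature peak is
#' `sqrt((a + b) / photon_scale + read_sd^2)`. This helper inverts
#' SNR = a / sd for `photon_scale`, so tests can state scenes by SNR.
#'
#' @param amplitude Feature amplitude above background.
#' @param snr Desired amplitude / noise-SD ratio.
#' @param background Constant background level.
#' @param read_sd Additive read-noise SD.
#' @return Photon scale (detected photons per intensity unit).
#' @export
photon_scale_for_snr <- function(amplitude, snr, background = 10, read_sd = 2) {
  var_needed <- (amplitude / snr)^2 - read_sd^2
  if (var_needed <= 0) {
    stop("read noise alone exceeds the requested SNR", call. = FALSE)
  }
  (amplitude + background) / var_needed
}

# Poisson shot noise + additive read noise on expected-intensity matrix
apply_noise <- function(expected, noise) {
  m <- expected
  if (noise$photon_scale > 0) {
    m <- matrix(
      stats::rpois(length(m), lambda = as.vector(m) * noise$photon_scale),
      nrow(m)) / noise$photon_scale
  }
  if (noise$read_sd > 0) {
    m <- m + matrix(stats::rnorm(length(m), 0, noise$read_sd), nrow(m))
  }
  pmax(m, 0)
}

# rejection-sample n non-overlapping disk centers fully inside the field
place_disks <- function(shape, n, radius_px, max_attempts = 5000 * max(n, 1)) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  margin <- radius_px + 2
  if (2 * margin >= min(shape)) {
    stop("generation error: cells do not fit in the field", call. = FALSE)
  }
  centers <- matrix(NA_real_, n, 2)
  placed <- 0
  for (i in seq_len(max_attempts)) {
    cand <- c(stats::runif(1, margin, shape[1] - margin),
              stats::runif(1, margin, shape[2] - margin))
    if (placed == 0 ||
        all((centers[seq_len(placed), 1] - cand[1])^2 +
            (centers[seq_len(placed), 2] - cand[2])^2 > (2 * radius_px)^2)) {
      placed <- placed + 1
      centers[placed, ] <- cand
      if (placed == n) return(centers)
    }
  }
  stop("generation error: could not place ", n, " cells after ",
       max_attempts, " attempts (density infeasible)", call. = FALSE)
}

# label matrix of disks around centers (rows x cols), label = row index
disk_labels <- function(shape, centers, radius_px) {
  lab <- matrix(0L, shape[1], shape[2])
  if (nrow(centers) == 0) return(lab)
  r2 <- radius_px^2
  for (i in seq_len(nrow(centers))) {
    rr <- max(1, floor(centers[i, 1] - radius_px)):
          min(shape[1], ceiling(centers[i, 1] + radius_px))
    cc <- max(1, floor(centers[i, 2] - radius_px)):
          min(shape[2], ceiling(centers[i, 2] + radius_px))
    d2 <- outer((rr - centers[i, 1])^2, (cc - centers[i, 2])^2, "+")
    block <- lab[rr, cc]
    block[d2 <= r2] <- i
    lab[rr, cc] <- block
  }
  lab
}

# multiplicative lognormal texture with mean exactly... mean 1 in expectation
texture_field <- function(shape, sdlog = 0.3) {
  matrix(stats::rlnorm(prod(shape), meanlog = -sdlog^2 / 2, sdlog = sdlog),
         shape[1])
}

#' Generate a synthetic nuclear-translocation field
#'
#' Places non-overlapping disk cells (nucleus disk inside a larger cell
#' disk; the annulus is the ER region), draws each cell's activation state
#' and true nuclear:ER ratio, and renders DAPI, ER (GRP94-like) and ATF6
#' channels. Before noise, the ATF6 channel's mean over the nucleus divided
#' by its mean over the ER region equals the cell's true ratio exactly.
#'
#' @param spec A [scene_spec()].
#' @return A list with `field` (list of [channel_image()]: dapi, er, atf6)
#'   and `truth` (list with per-cell tibble `cells`, [label_map()]s
#'   `nuclei` and `er`, and the scene specification).
#' @export
generate_translocation_field <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, {
    shape <- spec$field_shape_px
    px <- spec$pixel_size_um
    r_cell <- spec$cell_diameter_um / 2 / px
    r_nuc <- spec$nucleus_diameter_um / 2 / px
    centers <- place_disks(shape, spec$n_cells, r_cell)
    cell_lab <- disk_labels(shape, centers, r_cell)
    nuc_lab <- disk_labels(shape, centers, r_nuc)
    er_lab <- cell_lab
    er_lab[nuc_lab > 0] <- 0L

    activated <- stats::runif(spec$n_cells) < spec$activated_fraction
    rp <- spec$ratio_params
    med <- ifelse(activated, rp$active_mean, rp$inactive_mean)
    true_ratio <- stats::rlnorm(spec$n_cells, meanlog = log(med),
                                sdlog = rp$lognormal_sd)

    amp <- spec$amplitudes
    dapi_sig <- amp$dapi * (nuc_lab > 0)
    er_sig <- amp$er * (er_lab > 0) * texture_field(shape)
    atf6_sig <- matrix(0, shape[1], shape[2])
    if (spec$n_cells > 0) {
      atf6_sig[er_lab > 0] <- amp$atf6_er
      nuc_level <- amp$atf6_er * true_ratio
      idx <- nuc_lab > 0
      atf6_sig[idx] <- nuc_level[nuc_lab[idx]]
    }

    bg <- spec$noise$background
    mk <- function(sig, ch) {
      channel_image(apply_noise(sig + bg, spec$noise), px, ch)
    }
    field <- list(mk(dapi_sig, "dapi"), mk(er_sig, "er"), mk(atf6_sig, "atf6"))

    cells <- tibble::tibble(
      cell_id = seq_len(spec$n_cells),
      activated = activated,
      true_ratio = true_ratio,
      center_row = centers[, 1],
      center_col = centers[, 2],
      touches_border = FALSE
    )
    list(field = field,
         truth = list(cells = cells,
                      nuclei = label_map(nuc_lab, px),
                      er = label_map(er_lab, px),
                      cell_labels = label_map(cell_lab, px),
                      spec = spec))
  })
}

#' Render 2D Gaussian spots
#'
#' Sum of isotropic Gaussians with given peak amplitudes; the full width at
#' half maximum equals the nominal spot diameter, emulating
#' diffraction-limited puncta.
#'
#' @param shape `(rows, cols)` of the output matrix.
#' @param centers Two-column matrix of (row, col) centres.
#' @param fwhm_px FWHM of each spot in pixels (recycled).
#' @param amplitude Peak amplitude of each spot (recycled).
#' @return Numeric matrix.
#' @export
render_gaussian_spots <- function(shape, centers, fwhm_px, amplitude = 1) {
  m <- matrix(0, shape[1], shape[2])
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 2)
  n <- nrow(centers)
  if (n == 0) return(m)
  fwhm_px <- rep_len(fwhm_px, n)
  amplitude <- rep_len(amplitude, n)
  for (i in seq_len(n)) {
    sigma <- fwhm_px[i] / (2 * sqrt(2 * log(2)))
    w <- ceiling(3.5 * sigma) + 1
    rr <- max(1, floor(centers[i, 1] - w)):min(shape[1], ceiling(centers[i, 1] + w))
    cc <- max(1, floor(centers[i, 2] - w)):min(shape[2], ceiling(centers[i, 2] + w))
    g <- amplitude[i] * exp(-(outer((rr - centers[i, 1])^2,
                                    (cc - centers[i, 2])^2, "+")) /
                              (2 * sigma^2))
    m[rr, cc] <- m[rr, cc] + g
  }
  m
}

#' Generate a synthetic ER-exit-site field
#'
#' Renders diffraction-limited puncta in the Sec31A and Sec16 channels
#' inside disk cells. A punctum marked double-positive appears in both
#' channels; otherwise in exactly one. Inside double-positive puncta the
#' ATF6 channel is generated by Gaussian-copula mixing so its pixelwise
#' Pearson correlation with Sec31A has expectation `target_rho`; with
#' `target_rho = 1` and noise off the relation is exactly affine (sample
#' r = 1).
#'
#' @param spec A [scene_spec()]; `eres_spec` and `pixel_size_um` matter most
#'   (use ~0.11 um/px).
#' @return List with `field` (channel images: sec31a, sec16, atf6, er) and
#'   `truth` (tibbles `puncta` and `cells`, [label_map()] `puncta_mask`
#'   labelling every punctum's nominal-diameter disk, `target_rho`, spec).
#' @export
generate_eres_field <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  es <- spec$eres_spec
  px <- spec$pixel_size_um
  if (min(es$diameter_range_um) / px < 1) {
    stop("diameter_range_um below the resolvable range for this pixel size",
         call. = FALSE)
  }
  withr::with_seed(spec$seed, {
    shape <- spec$field_shape_px
    r_cell <- spec$cell_diameter_um / 2 / px
    r_nuc <- spec$nucleus_diameter_um / 2 / px
    centers <- place_disks(shape, spec$n_cells, r_cell)
    cell_lab <- disk_labels(shape, centers, r_cell)
    nuc_lab <- disk_labels(shape, centers, r_nuc)
    er_lab <- cell_lab
    er_lab[nuc_lab > 0] <- 0L

    # puncta centers in the ER annulus, pairwise-separated
    min_sep_px <- es$min_separation_um / px
    pl <- list()
    for (cid in seq_len(spec$n_cells)) {
      got <- matrix(numeric(0), 0, 2)
      attempts <- 0
      while (nrow(got) < es$n_puncta_per_cell && attempts < 20000) {
        attempts <- attempts + 1
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1, (r_nuc / r_cell)^2, 0.9^2)) * r_cell
        cand <- centers[cid, ] + rad * c(cos(ang), sin(ang))
        if (nrow(got) == 0 ||
            all((got[, 1] - cand[1])^2 + (got[, 2] - cand[2])^2 >
                min_sep_px^2)) {
          got <- rbind(got, cand)
        }
      }
      if (nrow(got) < es$n_puncta_per_cell) {
        stop("generation error: could not place puncta (density infeasible)",
             call. = FALSE)
      }
      pl[[cid]] <- cbind(got, cid)
    }
    pc <- do.call(rbind, c(pl, list(matrix(numeric(0), 0, 3))))
    n_p <- nrow(pc)
    diam_um <- stats::runif(n_p, es$diameter_range_um[1],
                            es$diameter_range_um[2])
    in_both <- stats::runif(n_p) < es$coloc_fraction
    side <- stats::runif(n_p) < 0.5   # channel for single-positive puncta
    amp <- spec$amplitudes
    a31 <- amp$punctum * stats::rlnorm(n_p, -0.35^2 / 2, 0.35)
    a16 <- amp$punctum * stats::rlnorm(n_p, -0.35^2 / 2, 0.35)

    fwhm_px <- diam_um / px
    i31 <- in_both | side
    i16 <- in_both | !side
    sec31_sig <- render_gaussian_spots(shape, pc[i31, 1:2, drop = FALSE],
                                       fwhm_px[i31], a31[i31])
    sec16_sig <- render_gaussian_spots(shape, pc[i16, 1:2, drop = FALSE],
                                       fwhm_px[i16], a16[i16])

    # nominal-diameter disk mask per punctum, labelled by punctum id
    pm <- matrix(0L, shape[1], shape[2])
    for (i in seq_len(n_p)) {
      one <- disk_labels(shape, pc[i, 1:2, drop = FALSE],
                         max(fwhm_px[i] / 2, 1))
      pm[one > 0] <- i
    }

    # ATF6: ER baseline plus copula-correlated signal inside ERES
    atf6_sig <- matrix(0, shape[1], shape[2])
    atf6_sig[er_lab > 0] <- amp$atf6_er / 2
    idx_pos <- which(pm > 0)
    pix_both <- idx_pos[in_both[pm[idx_pos]]]
    rho <- es$target_rho
    if (length(pix_both) >= 2 && stats::sd(sec31_sig[pix_both]) > 0) {
      z <- as.vector(scale(sec31_sig[pix_both]))
      e <- stats::rnorm(length(pix_both))
      y <- rho * z + sqrt(1 - rho^2) * e
      atf6_sig[pix_both] <- pmax(amp$atf6_punctum_base +
                                   amp$atf6_punctum_scale * y, 0)
    }
    er_sig <- amp$er * (er_lab > 0) * texture_field(shape)

    bg <- spec$noise$background
    mk <- function(sig, ch) {
      channel_image(apply_noise(sig + bg, spec$noise), px, ch)
    }
    field <- list(mk(sec31_sig, "sec31a"), mk(sec16_sig, "sec16"),
                  mk(atf6_sig, "atf6"), mk(er_sig, "er"))

    puncta <- tibble::tibble(
      punctum_id = seq_len(n_p),
      cell_id = as.integer(pc[, 3]),
      center_row = pc[, 1],
      center_col = pc[, 2],
      diameter_um = diam_um,
      in_both_channels = in_both
    )
    cells <- tibble::tibble(cell_id = seq_len(spec$n_cells),
                            center_row = centers[, 1],
                            center_col = centers[, 2])
    list(field = field,
         truth = list(puncta = puncta, cells = cells,
                      puncta_mask = label_map(pm, px),
                      nuclei = label_map(nuc_lab, px),
                      cell_labels = label_map(cell_lab, px),
                      target_rho = rho, spec = spec))
  })
}

#' Measurement-level simulator of one well's cell ratios
#'
#' Draws per-cell activation states and true nuclear:ER ratios from the
#' scene model and applies multiplicative lognormal measurement noise,
#' without rendering images — the fast path for plate-scale studies of the
#' threshold and percent-activation rules.
#'
#' @param n Number of cells.
#' @param activated_fraction Probability a cell is activated.
#' @param ratio_params As in [scene_spec()].
#' @param measurement_cv Lognormal SD of the multiplicative measurement
#'   error on the ratio.
#' @param well_id Well label attached to the output.
#' @param seed Optional seed (left `NULL`, the current RNG stream is used).
#' @return Tibble with `cell_id`, `well_id`, `activated`, `true_ratio`,
#'   `ratio`.
#' @export
simulate_well_ratios <- function(n, activated_fraction,
                                 ratio_params = list(inactive_mean = 0.8,
                                                     active_mean = 2.5,
                                                     lognormal_sd = 0.2),
                                 measurement_cv = 0.05,
                                 well_id = "A01", seed = NULL) {
  run <- function() {
    rp <- utils::modifyList(
      list(inactive_mean = 0.8, active_mean = 2.5, lognormal_sd = 0.2),
      ratio_params)
    activated <- stats::runif(n) < activated_fraction
    med <- ifelse(activated, rp$active_mean, rp$inactive_mean)
    true_ratio <- stats::rlnorm(n, log(med), rp$lognormal_sd)
    ratio <- true_ratio * stats::rlnorm(n, 0, measurement_cv)
    tibble::tibble(cell_id = seq_len(n), well_id = well_id,
                   activated = activated, true_ratio = true_ratio,
                   ratio = ratio)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate and write a whole synthetic plate
#'
#' One translocation field per well is generated (seeded deterministically
#' from `seed` and the well's position in the layout), written as 16-bit
#' multi-page TIFF via [write_field()], and the per-cell ground truth is
#' collected into a master CSV. Identical `seed` + specs reproduce the
#' output byte for byte.
#'
#' @param layout A [plate_layout()].
#' @param well_specs Either one [scene_spec()] used for every well, or a
#'   named list mapping `well_id` to a `scene_spec`.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @return Manifest tibble (`well_id`, `role`, `path`, `n_cells`),
#'   invisibly; files `"<well_id>_f0.tif"` and `truth.csv` in `out_dir`.
#' @export
generate_plate <- function(layout, well_specs, out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  per_well <- inherits(well_specs, "scene_spec") == FALSE
  paths <- character(nrow(layout))
  truths <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    wid <- layout$well_id[i]
    spec <- if (per_well) well_specs[[wid]] else well_specs
    if (is.null(spec)) stop("no scene_spec for well ", wid, call. = FALSE)
    spec$seed <- as.integer((seed + i * 1009L) %% .Machine$integer.max)
    sim <- generate_translocation_field(spec)
    sim$field <- lapply(sim$field, function(ci) {
      ci$well_id <- wid
      ci$pixels <- round(ci$pixels)  # integer counts: lossless 16-bit write
      ci
    })
    path <- file.path(out_dir, paste0(wid, "_f0.tif"))
    if (file.exists(path)) stop("duplicate well output: ", path, call. = FALSE)
    write_field(sim$field, path)
    paths[i] <- path
    truths[[i]] <- dplyr::mutate(sim$truth$cells, well_id = wid,
                                 .before = 1)
  }
  truth <- dplyr::bind_rows(truths)
  write_table(truth, file.path(out_dir, "truth.csv"))
  manifest <- tibble::tibble(well_id = layout$well_id, role = layout$role,
                             path = paths,
                             n_cells = vapply(truths, nrow, integer(1)))
  invisible(manifest)
}
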