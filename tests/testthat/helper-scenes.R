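# Shared scene constructors for the test suite. Scenes are kept small so
# the whole suite runs in a few minutes on one CPU.

noise_off <- list(photon_scale = 0, read_sd = 0, background = 0)

# translocation scene at a given DAPI SNR (20x-like geometry)
trans_scene <- function(n_cells = 20, activated_fraction = 0.5, snr = NULL,
                        seed = 1, shape = c(512, 512), ...) {
  noise <- if (is.null(snr)) list(photon_scale = 1, read_sd = 2,
                                  background = 10)
           else list(photon_scale = photon_scale_for_snr(100, snr = snr),
                     read_sd = 2, background = 10)
  scene_spec(field_shape_px = shape, pixel_size_um = 0.65,
             n_cells = n_cells, activated_fraction = activated_fraction,
             noise = noise, seed = seed, ...)
}

# ERES scene (100x-like geometry); snr = NULL keeps generator defaults,
# snr = 0 disables noise entirely
eres_scene <- function(n_cells = 1, n_puncta = 25, coloc_fraction = 1,
                       target_rho = 0.8, snr = 6, seed = 1,
                       shape = c(360, 360), diameter_range = c(0.3, 1.4),
                       min_sep = 1.6, cell_d = if (n_cells > 1) 20 else 26) {
  noise <- if (identical(snr, 0)) noise_off
           else list(photon_scale = photon_scale_for_snr(150, snr = snr),
                     read_sd = 2, background = 10)
  scene_spec(field_shape_px = shape, pixel_size_um = 0.11,
             n_cells = n_cells, cell_diameter_um = cell_d,
             nucleus_diameter_um = 8,
             eres_spec = list(n_puncta_per_cell = n_puncta,
                              diameter_range_um = diameter_range,
                              coloc_fraction = coloc_fraction,
                              target_rho = target_rho,
                              min_separation_um = min_sep),
             noise = noise, seed = seed)
}

# single Gaussian spot pair rendered into both ERES channels
spot_product <- function(d_um, px = 0.11, shape = c(96, 96), amp = 150,
                         centers = matrix(c(shape[1] / 2, shape[2] / 2), 1)) {
  s <- render_gaussian_spots(shape, centers, d_um / px, amp)
  product_image(channel_image(s + 10, px, "sec31a"),
                channel_image(s + 10, px, "sec16"))
}

# greedy centroid matching within a pixel radius: recall and precision
centroid_match <- function(truth_rc, pred_rc, max_dist = 2) {
  if (nrow(pred_rc) == 0) return(c(recall = 0, precision = NA))
  d <- sqrt(outer(truth_rc[, 1], pred_rc[, 1], "-")^2 +
            outer(truth_rc[, 2], pred_rc[, 2], "-")^2)
  c(recall = mean(apply(d, 1, min) <= max_dist),
    precision = mean(apply(d, 2, min) <= max_dist))
}
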