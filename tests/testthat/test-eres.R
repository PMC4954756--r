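# brute-force Pearson from first principles, no cor()
pearson_brute <- function(a, b) {
  n <- length(a)
  num <- sum((a - sum(a) / n) * (b - sum(b) / n))
  den <- sqrt(sum((a - sum(a) / n)^2) * sum((b - sum(b) / n)^2))
  num / den
}

test_that("product image is the pixelwise product after background clamp", {
  a <- channel_image(matrix(c(3, 0, 5, 0), 2), 0.11, "sec31a")
  b <- channel_image(matrix(c(4, 7, 0, 0), 2), 0.11, "sec16")
  # medians are 1.5 and 2: background-subtracted then multiplied
  p <- product_image(a, b)
  expect_equal(p$pixels[1, 1], (3 - 1.5) * (4 - 2))
  expect_equal(p$pixels[2, 2], 0)          # clamped, not negative product
  expect_equal(p$channel, "product")
  # zero channel kills the product everywhere
  z <- channel_image(matrix(0, 2, 2), 0.11, "sec16")
  expect_equal(max(product_image(a, z)$pixels), 0)
  bad <- channel_image(matrix(1, 3, 2), 0.11, "sec16")
  expect_error(product_image(a, bad), "dimensions")
})

test_that("size gate retains 1.0 um puncta and rejects 2.5 um and blanks", {
  d1 <- detect_eres(spot_product(1.0))
  expect_equal(nrow(d1$objects), 1)
  expect_gte(d1$objects$equivalent_diameter_um, 0.167)
  expect_lte(d1$objects$equivalent_diameter_um, 1.67)
  expect_equal(nrow(detect_eres(spot_product(2.5, shape = c(160, 160)))$objects), 0)
  blank <- channel_image(matrix(0, 64, 64), 0.11, "product")
  expect_equal(nrow(detect_eres(blank)$objects), 0)
})

test_that("gate soundness: every retained diameter lies inside [d_min, d_max]", {
  sim <- generate_eres_field(eres_scene(n_puncta = 25, seed = 13))
  prod <- product_image(field_channel(sim$field, "sec31a"),
                        field_channel(sim$field, "sec16"))
  det <- detect_eres(prod)
  expect_gt(nrow(det$objects), 0)
  expect_true(all(det$objects$equivalent_diameter_um >= 0.167))
  expect_true(all(det$objects$equivalent_diameter_um <= 1.67))
})

test_that("overlapping puncta with distinct peaks are declumped into two", {
  f <- 0.8 / 0.11
  m <- render_gaussian_spots(c(96, 96), rbind(c(44, 48), c(52, 48)), f, 150)
  prod <- product_image(channel_image(m + 10, 0.11, "sec31a"),
                        channel_image(m + 10, 0.11, "sec16"))
  det <- detect_eres(prod)
  expect_equal(nrow(det$objects), 2)
  # peak rows recovered near the planted centers
  expect_equal(sort(round(det$objects$centroid_row)), c(44, 52),
               tolerance = 0.05)
})

test_that("detection recovery on planted scenes at SNR >= 5", {
  recs <- precs <- c()
  for (seed in 1:3) {
    sim <- generate_eres_field(eres_scene(n_puncta = 25, snr = 6,
                                          seed = seed))
    prod <- product_image(field_channel(sim$field, "sec31a"),
                          field_channel(sim$field, "sec16"))
    det <- detect_eres(prod)
    tp <- sim$truth$puncta[sim$truth$puncta$in_both_channels, ]
    m <- centroid_match(cbind(tp$center_row, tp$center_col),
                        cbind(det$objects$centroid_row,
                              det$objects$centroid_col))
    recs <- c(recs, m["recall"]); precs <- c(precs, m["precision"])
  }
  expect_gte(mean(recs), 0.9)
  expect_gte(mean(precs), 0.9)
})

test_that("assignment to cells uses the centroid's label; background excluded", {
  lab <- matrix(0L, 64, 64)
  lab[10:30, 10:30] <- 3L
  det <- structure(list(
    objects = tibble::tibble(object_id = 1:2, slice_index = 0L,
                             cell_id = 0L, area_px = c(5L, 5L),
                             equivalent_diameter_um = c(0.3, 0.3),
                             centroid_row = c(20, 50),
                             centroid_col = c(20, 50)),
    labels = label_map(matrix(0L, 64, 64), 0.11)),
    class = "eres_detection")
  out <- assign_to_cells(det, label_map(lab, 0.11))
  expect_equal(out$objects$cell_id, c(3L, 0L))
})

test_that("per-cell ERES counts match the planted truth on clean scenes", {
  sim <- generate_eres_field(eres_scene(n_puncta = 15, snr = 0, seed = 17))
  prod <- product_image(field_channel(sim$field, "sec31a"),
                        field_channel(sim$field, "sec16"))
  det <- detect_eres(prod)
  det <- assign_to_cells(det, sim$truth$cell_labels)
  counts <- count_eres_per_cell(det)
  expect_equal(counts$per_cell$n_eres, 15)
  # counts invariant under constant intensity rescaling (auto threshold)
  prod2 <- prod
  prod2$pixels <- prod$pixels * 3.7
  det2 <- assign_to_cells(detect_eres(prod2), sim$truth$cell_labels)
  expect_equal(count_eres_per_cell(det2)$per_cell$n_eres, 15)
  # empty detection -> zero rows
  none <- count_eres_per_cell(tibble::tibble(cell_id = integer()))
  expect_equal(nrow(none$per_cell), 0)
})

test_that("measured mean intensities are exact on forced pixels", {
  lab <- matrix(0L, 8, 8)
  lab[2, 2:5] <- 1L
  det <- structure(list(
    objects = tibble::tibble(object_id = 1L, slice_index = 0L, cell_id = 1L,
                             area_px = 4L, equivalent_diameter_um = 0.25,
                             centroid_row = 2, centroid_col = 3.5),
    labels = label_map(lab, 0.11)), class = "eres_detection")
  ch <- matrix(0, 8, 8)
  ch[2, 2:5] <- c(1, 2, 3, 6)
  out <- measure_eres(det, list(sec31a = channel_image(ch, 0.11, "sec31a"),
                                atf6 = channel_image(matrix(7, 8, 8), 0.11,
                                                     "atf6")))
  expect_equal(out$objects$mean_sec31a, 3.0)
  expect_equal(out$objects$mean_atf6, 7.0)
  expect_error(measure_eres(det, list(channel_image(ch, 0.11, "er"))),
               "named")
})

test_that("measured means over detected vs true masks agree on clean scenes", {
  sim <- generate_eres_field(eres_scene(n_puncta = 15, snr = 0, seed = 19))
  chans <- list(sec31a = field_channel(sim$field, "sec31a"),
                atf6 = field_channel(sim$field, "atf6"))
  prod <- product_image(chans$sec31a, field_channel(sim$field, "sec16"))
  det <- measure_eres(detect_eres(prod), chans)
  truth_det <- measure_eres(eres_objects_from_truth(sim$truth), chans)
  # compare field-level mean of per-object sec31a means
  expect_equal(mean(det$objects$mean_sec31a),
               mean(truth_det$objects$mean_sec31a), tolerance = 0.35)
})

test_that("within-ERES correlation equals brute-force Pearson to 1e-12", {
  sim <- generate_eres_field(eres_scene(n_puncta = 20, target_rho = 0.6,
                                        snr = 6, seed = 23))
  det <- assign_to_cells(eres_objects_from_truth(sim$truth),
                         sim$truth$cell_labels)
  a <- field_channel(sim$field, "atf6")
  b <- field_channel(sim$field, "sec31a")
  cc <- correlate_within_eres(det, a, b)
  idx <- which(det$labels$labels > 0)
  expect_equal(cc$r, pearson_brute(a$pixels[idx], b$pixels[idx]),
               tolerance = 1e-12)
  # trivial identities
  expect_equal(correlate_within_eres(det, a, a)$r, 1.0, tolerance = 1e-12)
  neg <- a
  neg$pixels <- max(a$pixels) - a$pixels
  expect_equal(correlate_within_eres(det, a, neg)$r, -1.0, tolerance = 1e-12)
})

test_that("undefined correlations (few pixels, constant channel) are skipped", {
  lab <- matrix(0L, 8, 8)
  lab[2, 2:3] <- 1L           # 2 px < 3 minimum
  det <- structure(list(
    objects = tibble::tibble(object_id = 1L, slice_index = 0L, cell_id = 2L,
                             area_px = 2L, equivalent_diameter_um = 0.2,
                             centroid_row = 2, centroid_col = 2.5),
    labels = label_map(lab, 0.11)), class = "eres_detection")
  a <- channel_image(matrix(runif(64), 8), 0.11, "atf6")
  expect_message(cc <- correlate_within_eres(det, a, a), "undefined")
  expect_true(is.na(cc$r))
  # constant channel on enough pixels is also undefined
  lab3 <- matrix(0L, 8, 8); lab3[2, 2:5] <- 1L
  det$labels <- label_map(lab3, 0.11)
  det$objects$area_px <- 4L
  const <- channel_image(matrix(5, 8, 8), 0.11, "sec31a")
  expect_message(cc2 <- correlate_within_eres(det, a, const), "undefined")
  expect_true(is.na(cc2$r))
})

test_that("estimated r is monotone in target_rho on the detected path", {
  est <- vapply(c(0, 0.3, 0.6, 0.9), function(rho) {
    sim <- generate_eres_field(eres_scene(n_puncta = 25, target_rho = rho,
                                          snr = 8, seed = 29))
    prod <- product_image(field_channel(sim$field, "sec31a"),
                          field_channel(sim$field, "sec16"))
    det <- assign_to_cells(detect_eres(prod), sim$truth$cell_labels)
    cc <- correlate_within_eres(det, field_channel(sim$field, "atf6"),
                                field_channel(sim$field, "sec31a"))
    mean(cc$r, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("correlation aggregation hierarchy is exact", {
  per_slice <- tibble::tibble(
    cell_id = rep(1:2, each = 6),
    slice_index = rep(0:5, 2),
    r = c(rep(0.5, 6), seq(0.2, 0.7, by = 0.1)))
  agg <- aggregate_correlations(per_slice)
  expect_equal(agg$mean_r[agg$cell_id == 1], 0.5)
  expect_equal(agg$sd_r[agg$cell_id == 1], 0)
  expect_equal(agg$mean_r[agg$cell_id == 2], mean(seq(0.2, 0.7, by = 0.1)))
  # two-slice toy case
  two <- aggregate_correlations(tibble::tibble(cell_id = 1, slice_index = 0:1,
                                               r = c(0.2, 0.4)))
  expect_equal(two$mean_r, 0.3)
  # experiment mean equals the mean of its cells' means exactly
  agg$treatment <- "tg"
  agg$experiment <- "e1"
  s <- summarize_correlations(agg)
  expect_equal(s$per_experiment$mean_r, mean(agg$mean_r))
  # cells with no valid slice are excluded and counted
  with_na <- tibble::tibble(cell_id = c(1, 1, 2), slice_index = c(0, 1, 0),
                            r = c(0.1, 0.3, NA))
  expect_message(agg2 <- aggregate_correlations(with_na), "excluded")
  expect_equal(agg2$cell_id, 1)
  expect_equal(attr(agg2, "n_excluded"), 1L)
})
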