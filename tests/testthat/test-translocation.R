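# independent brute-force oracle for the threshold rule: literal bin scan
# over right-closed histogram bins of width bw starting at 0
brute_force_threshold <- function(stressed, unstressed, bw,
                                  mode = "frequency", run_length = 3) {
  hi <- ceiling(max(c(stressed, unstressed)) / bw) + run_length + 2
  breaks <- seq(0, hi * bw, by = bw)
  cs <- hist(stressed, breaks = breaks, plot = FALSE)$counts
  cu <- hist(unstressed, breaks = breaks, plot = FALSE)$counts
  if (mode == "frequency") {
    cs <- cs / length(stressed); cu <- cu / length(unstressed)
  }
  for (k in seq_along(cs)) {
    left <- breaks[k]
    if (left <= 1 + 1e-9) next
    if (cs[k] > cu[k]) {
      succ <- (k + 1):(k + run_length - 1)
      succ <- succ[succ <= length(cs)]
      if (run_length == 1 || all(cs[succ] >= cu[succ])) return(left)
    }
  }
  NA_real_
}

test_that("score_cells computes mask means and ratios exactly", {
  # hand-built segmentation: 1 cell, nucleus 4 px, ER 4 px
  lab0 <- matrix(0L, 16, 16)
  nuc <- lab0; nuc[4:5, 4:5] <- 1L
  er <- lab0; er[10:11, 10:11] <- 1L
  cells <- lab0; cells[4:5, 4:5] <- 1L; cells[10:11, 10:11] <- 1L
  seg <- structure(list(
    nuclei = label_map(nuc, 0.65), cells = label_map(cells, 0.65),
    er = label_map(er, 0.65),
    cells_tbl = tibble::tibble(cell_id = 1L, touches_border = FALSE,
                               nucleus_area_um2 = 4 * 0.65^2,
                               er_area_um2 = 4 * 0.65^2),
    pixel_size_um = 0.65, n_dropped_no_er = 0L),
    class = "cell_segmentation")
  px <- matrix(0, 16, 16)
  px[nuc > 0] <- 200
  px[er > 0] <- 100
  sc <- score_cells(channel_image(px, 0.65, "atf6"), seg)
  expect_equal(sc$nuclear_mean, 200)
  expect_equal(sc$er_mean, 100)
  expect_equal(sc$ratio, 2.0)
  # uniform intensity -> ratio exactly 1; zero nucleus -> ratio 0
  sc1 <- score_cells(channel_image(matrix(7, 16, 16), 0.65, "atf6"), seg)
  expect_equal(sc1$ratio, 1.0)
  px0 <- px; px0[nuc > 0] <- 0
  expect_equal(score_cells(channel_image(px0, 0.65, "atf6"), seg)$ratio, 0)
})

test_that("threshold matches the worked two-population example and the oracle", {
  unstressed <- rep(0.9, 1000)
  stressed <- c(rep(0.9, 500), rep(2.5, 500))
  thr <- derive_threshold(stressed, unstressed, bin_width = 0.1)
  expect_equal(thr$value, 2.4)
  expect_equal(thr$value,
               brute_force_threshold(stressed, unstressed, 0.1))
})

test_that("threshold equals the brute-force bin scan on random mixtures", {
  for (seed in 1:10) {
    s <- simulate_well_ratios(300, 0.5, seed = seed)$ratio
    u <- simulate_well_ratios(300, 0.02, seed = seed + 1000)$ratio
    got <- derive_threshold(s, u, bin_width = 0.05)$value
    want <- brute_force_threshold(s, u, 0.05)
    expect_equal(got, want, info = paste("seed", seed))
    expect_gt(got, 1)
  }
})

test_that("identical populations give a threshold-derivation error", {
  x <- simulate_well_ratios(200, 0.5, seed = 4)$ratio
  expect_error(derive_threshold(x, x), "threshold derivation failed")
})

test_that("count mode and frequency mode differ only under unequal well sizes", {
  s <- c(rep(0.9, 50), rep(2.5, 50))
  u <- rep(0.9, 1000)
  f <- derive_threshold(s, u, bin_width = 0.1, mode = "frequency")$value
  cnt <- derive_threshold(s, u, bin_width = 0.1, mode = "count")$value
  expect_equal(f, 2.4)
  expect_equal(cnt, 2.4)
  # raw counts can miss excess that frequencies see
  s2 <- c(rep(0.9, 90), rep(1.31, 3))
  u2 <- c(rep(0.9, 880), rep(1.31, 5), rep(1.11, 20))
  expect_error(derive_threshold(s2, u2, bin_width = 0.1, mode = "count"),
               "threshold")
  expect_equal(derive_threshold(s2, u2, bin_width = 0.1,
                                mode = "frequency")$value, 1.3)
})

test_that("threshold is scale-equivariant when the bin grid rescales with it", {
  s <- c(rep(0.9, 500), rep(2.5, 500))
  u <- rep(0.9, 1000)
  base <- derive_threshold(s, u, bin_width = 0.1)$value
  for (cc in c(1.5, 2, 3)) {
    scaled <- derive_threshold(s * cc, u * cc, bin_width = 0.1 * cc)$value
    expect_equal(scaled, base * cc, tolerance = 1e-12)
  }
})

test_that("percent activation uses the strict inequality and groups by well", {
  ratios <- tibble::tibble(
    well_id = rep(c("A01", "A02"), c(4, 3)),
    ratio = c(0.5, 1.2, 3.0, 0.8, 0.2, 0.4, 0.9))
  suppressMessages({
    wa <- percent_activation(ratios, 1.0)
  })
  expect_equal(wa$percent_activation[wa$well_id == "A01"], 50.0)
  expect_equal(wa$percent_activation[wa$well_id == "A02"], 0.0)
  # ties at the threshold count as inactive
  suppressMessages({
    tie <- percent_activation(tibble::tibble(well_id = "w",
                                             ratio = c(1.0, 1.0, 2.0)), 1.0)
  })
  expect_equal(tie$percent_activation, 100 / 3)
  expect_error(percent_activation(ratios[0, ], 1.0), "empty")
})

test_that("percent activation is non-increasing in the threshold", {
  r <- simulate_well_ratios(300, 0.5, seed = 8)
  pa <- vapply(seq(1.05, 3, by = 0.1), function(th) {
    suppressMessages(percent_activation(r, th)$percent_activation)
  }, numeric(1))
  expect_true(all(diff(pa) <= 0))
})

test_that("hit calling implements the 3-SD rule with sample SD", {
  wells <- tibble::tibble(
    well_id = c("C1", "C2", "C3", "T1", "T2"),
    role = c(rep("stressed_control", 3), "test", "test"),
    percent_activation = c(50, 52, 48, 40, 45))
  hits <- call_hits(wells)
  expect_equal(hits$control_mean[1], 50)
  expect_equal(hits$control_sd[1], 2)
  # cut at 50 - 3*2 = 44: 40 is a hit, 45 is not
  expect_true(hits$is_hit[hits$well_id == "T1"])
  expect_false(hits$is_hit[hits$well_id == "T2"])
  expect_true(all(is.na(hits$is_hit[hits$role != "test"])))
  expect_equal(hits$z_like[hits$well_id == "T1"], 5)
  # idempotence: re-calling on the output is unchanged
  again <- call_hits(hits)
  expect_equal(again$is_hit, hits$is_hit)
  expect_equal(again$control_mean, hits$control_mean)
  expect_error(call_hits(wells[wells$role != "stressed_control", ]), ">= 2")
  # fewer than 2 stressed controls
  expect_error(call_hits(wells[-(1:2), ]), ">= 2")
})

test_that("box-plot summary: quartiles, min/max whiskers, small groups dropped", {
  # one group of identical values: zero-width box, whiskers at the value
  one <- tibble::tibble(ratio = rep(1.5, 25), treatment = "vehicle")
  two <- tibble::tibble(ratio = c(2, 3, 4, 5, 6), treatment = "tg")
  tiny <- tibble::tibble(ratio = c(1, 2), treatment = "tiny")
  expect_warning(
    s <- summarize_nuclear_translocation(dplyr::bind_rows(one, two, tiny)),
    "tiny")
  tv <- s$summary[s$summary$treatment == "vehicle", ]
  expect_equal(tv$whisker_low, 1.5)
  expect_equal(tv$whisker_high, 1.5)
  expect_equal(tv$q1, 1.5)
  expect_equal(tv$q3, 1.5)
  tg <- s$summary[s$summary$treatment == "tg", ]
  expect_equal(tg$median, 4)
  expect_equal(tg$whisker_low, 2)
  expect_equal(tg$whisker_high, 6)
  expect_equal(nrow(s$tests), 1)
  expect_equal(s$tests$test_name, "t_unpaired_two_tailed")
})

test_that("percent-activation recovery across activated fractions (<= 5 pp MAE)", {
  # image-free plate at the generator's measurement level, n = 300 cells/well
  withr::with_seed(99, {
    u <- simulate_well_ratios(300, 0.02, well_id = "U1")
    s <- simulate_well_ratios(300, 0.60, well_id = "S1")
    thr <- derive_threshold(s, u)
    errs <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
      w <- simulate_well_ratios(300, f, well_id = "T")
      pa <- suppressMessages(percent_activation(w, thr))
      abs(pa$percent_activation - 100 * mean(w$activated))
    }, numeric(1))
  })
  expect_lte(mean(errs), 5)
})

test_that("full image pipeline recovers percent activation on a small well", {
  sim <- generate_translocation_field(trans_scene(n_cells = 30,
                                                  activated_fraction = 0.5,
                                                  seed = 61,
                                                  shape = c(640, 640)))
  nuc <- segment_nuclei(field_channel(sim$field, "dapi"))
  seg <- segment_cells(field_channel(sim$field, "er"), nuc)
  sc <- suppressMessages(score_cells(field_channel(sim$field, "atf6"), seg))
  pa <- suppressMessages(percent_activation(sc, 1.4))
  truth_pct <- 100 * mean(sim$truth$cells$activated)
  expect_lt(abs(pa$percent_activation - truth_pct), 10)
})
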