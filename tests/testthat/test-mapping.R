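test_that("binning sums full blocks, drops partials, and reproduces the sensor geometry", {
  ax <- gate_axis(n_steps = 2)
  full <- time_scan(array(1L, c(256, 472, 2)), ax)
  b <- bin_scan(full, 8)
  expect_equal(dim(b$counts)[1:2], c(32L, 59L))
  expect_true(all(b$counts == 64))

  expect_identical(bin_scan(full, 1), full)

  ten <- time_scan(array(1, c(10, 10, 2)), ax)
  b10 <- bin_scan(ten, 8)
  expect_equal(dim(b10$counts)[1:2], c(1L, 1L))
  expect_true(all(b10$counts == 64))

  expect_error(bin_scan(ten, 16), "exceeds")
})

test_that("binned block sums match manual block arithmetic", {
  ax <- gate_axis(n_steps = 3)
  set.seed(12)
  counts <- array(rpois(12 * 9 * 3, 5), c(12, 9, 3))
  scan <- time_scan(counts, ax)
  b <- bin_scan(scan, 3)
  expect_equal(b$counts[2, 3, 2], sum(counts[4:6, 7:9, 2]))
  expect_equal(sum(b$counts), sum(counts))
})

test_that("per-superpixel map fits equal independent profile-level fits", {
  ax <- test_axis(256)
  irf_tp <- make_irf(ax, 110)
  scene <- phantom_scene(matrix(c(2, 3, 2, 3), 2, 2), il_percent = 2,
                         peak_counts = 1500)
  sens <- sensor_response(frames_per_gate_sequence = 65536,
                          dark_count_rate = 50)
  scan <- simulate_scan(scene, ax, sens, "fluorescence", seed = 7)
  irf_scan <- simulate_scan(scene, ax, sens, "irf", seed = 8)
  maps <- fit_map(scan, irf_scan, tau = 0.7)

  # manual pipeline for pixel (2, 1): identical result, no cross-talk
  tp <- normalize_profile(
    time_profile(scan$counts[2, 1, ], ax), 36, 36)
  irf_px <- time_profile(irf_scan$counts[2, 1, ], ax, modality = "irf")
  f <- fit_fluorescence(tp, irf_px, tau = 0.7)
  expect_equal(maps$delta_tissue$values[2, 1],
               unname(coef(f)["delta_tissue"]), tolerance = 1e-12)
  expect_equal(maps$r_squared$values[2, 1], f$r_squared, tolerance = 1e-12)
})

test_that("fitted maps order the two-cylinder scene by depth and mask background", {
  ax <- test_axis(256)
  scene <- two_cylinder_scene(rows = 6, cols = 12, depths = c(2.5, 5.6),
                              il_percent = 2, peak_counts = 2000)
  sens <- sensor_response(frames_per_gate_sequence = 65536,
                          dark_count_rate = 20)
  scan <- simulate_scan(scene, ax, sens, "fluorescence", seed = 21)
  irf_scan <- simulate_scan(scene, ax, sens, "irf", seed = 22)
  maps <- fit_map(scan, irf_scan, tau = 0.7)
  fp <- scene$footprints
  m <- function(mp, f) mean(mp$values[f$rows, f$cols], na.rm = TRUE)
  expect_lt(m(maps$delta_tissue, fp[[1]]), m(maps$delta_tissue, fp[[2]]))
  expect_lt(m(maps$sigma, fp[[1]]), m(maps$sigma, fp[[2]]))
  # background-only pixels carry no pulse: masked invalid
  bg <- is.na(scene$depth)
  expect_true(all(!maps$delta_tissue$mask[bg]))
})

test_that("a uniform scene yields a TOF map constant to within a gate step", {
  ax <- test_axis(256)
  scene <- phantom_scene(matrix(2, 3, 4), il_percent = 2,
                         peak_counts = 2000)
  sens <- sensor_response(frames_per_gate_sequence = 65536,
                          dark_count_rate = 0)
  scan <- simulate_scan(scene, ax, sens, "fluorescence", seed = 31)
  irf_scan <- simulate_scan(scene, ax, sens, "irf", seed = 32)
  maps <- fit_map(scan, irf_scan, tau = 0.7)
  v <- maps$delta_tissue$values[maps$delta_tissue$mask]
  expect_true(all(is.finite(v)))
  expect_lt(max(v) - min(v), 2 * ax$dt)
})

test_that("intensity masking keeps inclusion pixels and rejects background", {
  ax <- test_axis(256)
  scene <- two_cylinder_scene(rows = 8, cols = 16, depths = c(1.5, 2.5),
                              il_percent = 2, peak_counts = 3000)
  sens <- sensor_response(frames_per_gate_sequence = 65536,
                          dark_count_rate = 200)
  scan <- simulate_scan(scene, ax, sens, "fluorescence", seed = 41)
  img <- intensity_image(scan)
  base <- parameter_map(matrix(1, 8, 16), "delta_tissue",
                        matrix(TRUE, 8, 16))
  inc <- !is.na(scene$depth)

  masked <- mask_by_intensity(base, img, min_snr = 3,
                              background_roi = c(0, 0, 8, 2))
  expect_gte(mean(masked$mask[inc]), 0.95)
  expect_gte(mean(!masked$mask[!inc & col(inc) > 2]), 0.95)

  ident <- mask_by_intensity(base, img, threshold = 0)
  expect_true(all(ident$mask))
  expect_warning(mask_by_intensity(base, img,
                                   threshold = max(img$values) + 1),
                 "every pixel")
})

test_that("masked Gaussian smoothing is exact on kernels, constants and holes", {
  m <- matrix(0, 15, 15); m[8, 8] <- 1
  mp <- parameter_map(m, "delta_tissue", matrix(TRUE, 15, 15))
  sm <- smooth_map(mp, 1)
  k <- exp(-((-3):3)^2 / 2); k2 <- outer(k, k); k2 <- k2 / sum(k2)
  # compare on the interior window, clear of edge renormalization
  expect_equal(sm$values[5:11, 5:11], k2, tolerance = 1e-9)

  expect_identical(smooth_map(mp, 0), mp)

  holes <- matrix(TRUE, 11, 11); holes[4:5, 7:8] <- FALSE
  cmap <- parameter_map(matrix(3.3, 11, 11), "sigma", holes)
  smc <- smooth_map(cmap, 1.5)
  expect_equal(smc$values[holes], rep(3.3, sum(holes)), tolerance = 1e-12)
  expect_identical(smc$mask, holes)

  # values never propagate into regions fully masked beyond 3 sigma
  far <- matrix(FALSE, 11, 11); far[1, 1] <- TRUE; far[11, 11] <- TRUE
  fmap <- parameter_map(matrix(c(10, rep(NA, 119), 20), 11, 11), "A", far)
  smf <- smooth_map(fmap, 0.5)
  expect_equal(smf$values[1, 1], 10)
  expect_equal(smf$values[11, 11], 20)
})

test_that("topology conversion re-references the TOF map and scales by the calibrated slope", {
  tb <- exact_tables(k_corr = 10, c_corr = 2, c_fluo = 20, k_med = 3,
                     c_med = 1)
  chain <- build_chain(tb$depth, tb$medium, branch = "sfdi")
  il <- 2; k_fluo <- 10 * il + 2; feat <- 3 * il + 1
  delta <- matrix(20 + k_fluo * c(2.5, 2.5, 5.6, 5.6), 2, 2)
  dm <- parameter_map(delta, "delta_tissue", matrix(TRUE, 2, 2))
  topo <- tof_to_topology(dm, chain, feat)
  expect_equal(topo$values, (delta - min(delta)) / k_fluo,
               tolerance = 1e-9)
  expect_equal(topo$values[1, 2] - topo$values[1, 1], 3.1,
               tolerance = 1e-9)

  const <- parameter_map(matrix(7, 3, 3), "delta_tissue",
                         matrix(TRUE, 3, 3))
  expect_true(all(tof_to_topology(const, chain, feat)$values == 0))
  none <- parameter_map(matrix(NA_real_, 2, 2), "delta_tissue",
                        matrix(FALSE, 2, 2))
  expect_error(tof_to_topology(none, chain, feat), "no valid pixels")
})

test_that("maps serialize to row/col/value/valid CSV", {
  mp <- parameter_map(matrix(1:6 / 2, 2, 3), "sigma")
  f <- file.path(tempdir(), "map.csv")
  write_map_csv(mp, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 6L)
  expect_equal(df$value[df$row == 1 & df$col == 2], 3)
  expect_true(all(df$valid))
  unlink(f)
})
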