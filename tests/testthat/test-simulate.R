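test_that("gate axis enforces its invariants and default timing", {
  ax <- gate_axis()
  expect_equal(ax$dt, 17.857)
  expect_equal(ax$n_steps, 1400L)
  expect_equal(axis_span(ax), 17.857 * 1400)
  expect_error(gate_axis(dt = 0), "positive")
  expect_error(gate_axis(n_steps = 1), ">= 2")
})

test_that("synthetic IRF has the requested width, area and edge cases", {
  ax <- test_axis()
  irf <- make_irf(ax, pulse_fwhm = 120, amplitude = 3.5)
  expect_equal(sum(irf$values), 3.5, tolerance = 1e-9)
  # samples above half maximum ~ fwhm / dt = 120 / 17.857 = 6.7
  n_above <- sum(irf$values > max(irf$values) / 2)
  expect_true(n_above %in% 6:7)
  expect_equal(make_irf(ax, 120, amplitude = 0)$values, rep(0, ax$n_steps))
  expect_error(make_irf(ax, pulse_fwhm = 2 * ax$dt), "under-sampled")
})

test_that("delta-IRF forward profile reproduces the Gaussian and EMG closed forms", {
  ax <- test_axis()
  dirf <- delta_irf(ax, at = 50)
  t_rel <- axis_times(ax) - axis_times(ax)[50]

  gauss <- forward_profile(dirf, medium_transfer(1, 300, 150))
  expect_identical(gauss$modality, "reflectance")
  ref <- dnorm(t_rel, 300, 150) * ax$dt
  keep <- ref > 1e-6 * max(ref)
  expect_lt(max(abs(gauss$values[keep] - ref[keep]) / ref[keep]), 1e-6)

  A <- 2.5
  emg <- forward_profile(dirf, medium_transfer(A, 300, 150),
                         fluorophore(0.7))
  expect_identical(emg$modality, "fluorescence")
  ref2 <- A * ax$dt * emg_oracle(t_rel, 300, 150, 700)
  keep2 <- ref2 > 1e-6 * max(ref2)
  expect_lt(max(abs(emg$values[keep2] - ref2[keep2]) / ref2[keep2]), 1e-6)
})

test_that("FFT convolution equals a direct nested-sum oracle on a short axis", {
  ax <- test_axis(n_steps = 64, dt = 10)
  set.seed(11)
  irf <- time_profile(rgamma(64, 2, 0.5), ax, modality = "irf")
  out <- forward_profile(irf, medium_transfer(1.7, 120, 60),
                         fluorophore(0.7))
  # direct O(n^2) sum with the same medium kernel over all padded lags
  N <- 256
  lags <- -(N / 2):(N / 2 - 1)
  kern <- emg_density(lags * ax$dt, 120, 60, 700)
  kern <- kern / sum(kern)
  direct <- sapply(seq_len(64), function(n) {
    s <- 0
    for (j in seq_len(64)) {
      l <- n - j
      if (l >= min(lags) && l <= max(lags))
        s <- s + irf$values[j] * kern[l - min(lags) + 1]
    }
    1.7 * s
  })
  expect_equal(out$values, direct, tolerance = 1e-12)
})

test_that("analytic medium kernel agrees with sequential discrete Gaussian and exponential convolutions", {
  # triple nested sum: irf (*) sampled Gaussian (*) sampled causal
  # exponential, each kernel unit-normalized. The sequential scheme
  # carries O(dt/tau) discretization error relative to the analytic
  # Gaussian-exponential product, so agreement is checked at 5%.
  # parameters chosen so both kernels are fully resolvable on a short
  # padded axis: tau and sigma well under the +-640 ps padded lag range
  ax <- test_axis(n_steps = 64, dt = 5)
  dirf <- delta_irf(ax, at = 8)
  tau_ps <- 80
  out <- forward_profile(dirf, medium_transfer(1, 80, 40),
                         fluorophore(tau_ps / 1000))
  lags <- -64:63
  ne <- 2048L                  # exponential support ~ 10 ns >> tau
  g <- dnorm(lags * ax$dt, 80, 40); g <- g / sum(g)
  e <- exp(-(0:(ne - 1L)) * ax$dt / tau_ps); e <- e / sum(e)
  ge <- sapply(lags, function(l) {
    idx <- l - lags            # exponential lag for each Gaussian lag
    ok <- idx >= 0 & idx < ne
    sum(g[ok] * e[idx[ok] + 1])
  })
  seq_out <- sapply(seq_len(64), function(n) {
    l <- n - 8
    if (l >= min(lags) && l <= max(lags)) ge[l - min(lags) + 1] else 0
  })
  # the sequential scheme carries a rectangle-rule error of order
  # dt / (2 tau) ~ 3% here, so agreement is judged at 5% of the peak
  expect_lt(max(abs(seq_out - out$values)) / max(out$values), 0.05)
})

test_that("forward profile is linear in A, shift-equivariant, and photon-conserving", {
  ax <- test_axis(n_steps = 256)
  irf <- make_irf(ax, 110, amplitude = 7)
  m1 <- forward_profile(irf, medium_transfer(1, 400, 120), fluorophore(0.7))
  m2 <- forward_profile(irf, medium_transfer(2, 400, 120), fluorophore(0.7))
  expect_equal(m2$values, 2 * m1$values, tolerance = 1e-12)

  # shifting delta by k*dt shifts the profile by k samples (interior);
  # Gaussian kernel, whose padded-tail truncation is far below 1e-9
  k <- 5
  g1 <- forward_profile(irf, medium_transfer(1, 400, 120))
  g3 <- forward_profile(irf, medium_transfer(1, 400 + k * ax$dt, 120))
  mid <- 30:200
  expect_equal(g3$values[mid + k], g1$values[mid], tolerance = 1e-9)

  # unit-area kernels conserve the expected photon total (A * sum(irf));
  # the fluorescence case needs an axis long enough to hold the exp tail
  expect_equal(sum(forward_profile(irf, medium_transfer(3, 300, 100))$values),
               3 * 7, tolerance = 1e-6)
  axl <- test_axis(n_steps = 1024)
  irfl <- make_irf(axl, 110, amplitude = 7)
  ml <- forward_profile(irfl, medium_transfer(1, 300, 120), fluorophore(0.7))
  expect_equal(sum(ml$values), 7, tolerance = 1e-6)

  expect_warning(forward_profile(irf, medium_transfer(1, 300, ax$dt / 4)),
                 "under-resolved")
  expect_error(medium_transfer(1, 300, -5), "sigma")
  expect_error(medium_transfer(-1, 300, 5), "A")
})

test_that("photon noise reproduces Poisson statistics, pile-up saturation and determinism", {
  ax <- test_axis(n_steps = 10000)
  sens <- sensor_response(frames_per_gate_sequence = 100,
                          dark_count_rate = 0)
  FF <- 100

  zero <- add_photon_noise(time_profile(rep(0, ax$n_steps), ax), sens, 1)
  expect_true(all(zero$values == 0))

  # strong pile-up: lambda/frames = 10 -> mean ~ F * (1 - exp(-10))
  lam <- rep(10 * FF, ax$n_steps)
  sat <- add_photon_noise(time_profile(lam, ax), sens, 2)
  expect_lt(abs(mean(sat$values) / (FF * (1 - exp(-10))) - 1), 0.01)
  expect_true(all(sat$values <= FF))

  # linear regime: lambda/frames = 0.01 -> mean ~ lambda within 1%
  # (frames raised so the Monte-Carlo mean is precise to ~0.1%)
  sens2 <- sensor_response(frames_per_gate_sequence = 10000,
                           dark_count_rate = 0)
  lam2 <- rep(0.01 * 10000, ax$n_steps)
  lin <- add_photon_noise(time_profile(lam2, ax), sens2, 3)
  expect_lt(abs(mean(lin$values) / (0.01 * 10000) - 1), 0.01)

  expect_identical(add_photon_noise(time_profile(lam, ax), sens, 42)$values,
                   add_photon_noise(time_profile(lam, ax), sens, 42)$values)
})

test_that("counter-based stream seeds are deterministic and spread", {
  s <- vapply(0:99, function(i) derive_seed(123, i), integer(1))
  expect_identical(s, vapply(0:99, function(i) derive_seed(123, i), integer(1)))
  expect_equal(length(unique(s)), 100L)
  expect_true(all(s >= 1 & s < 2^31))
  expect_false(derive_seed(1, 0) == derive_seed(2, 0))
})

test_that("simulated two-cylinder scan orders intensity and TOF by depth", {
  ax <- test_axis(n_steps = 256)
  scene <- two_cylinder_scene(rows = 12, cols = 22, depths = c(2.5, 5.6),
                              il_percent = 2, peak_counts = 40)
  scan <- simulate_scan(scene, ax, sensor_response(), "fluorescence",
                        seed = 5)
  gt <- scan$provenance$ground_truth
  fp <- scene$footprints
  img <- intensity_image(scan)
  mean_fp <- function(m, f) mean(m[f$rows, f$cols])
  # shallower cylinder: strictly brighter, strictly smaller delta_tissue
  expect_gt(mean_fp(img$values, fp[[1]]), mean_fp(img$values, fp[[2]]))
  expect_lt(mean_fp(gt$delta_tissue, fp[[1]]),
            mean_fp(gt$delta_tissue, fp[[2]]))
  # ground truth follows the scene's linear TOF-depth law
  expect_equal(gt$delta_tissue[fp[[1]]$rows[1], fp[[1]]$cols[1]],
               scene$k_fluo * 2.5 + scene$c_fluo)
})

test_that("simulation is deterministic given the seed and zero depth maps to c_fluo", {
  ax <- test_axis(n_steps = 128)
  scene <- phantom_scene(matrix(0, 4, 5), il_percent = 1)
  s1 <- simulate_scan(scene, ax, sensor_response(), "fluorescence", seed = 9)
  s2 <- simulate_scan(scene, ax, sensor_response(), "fluorescence", seed = 9)
  expect_identical(s1$counts, s2$counts)
  expect_true(all(s1$provenance$ground_truth$delta_tissue == scene$c_fluo))
  s3 <- simulate_scan(scene, ax, sensor_response(), "fluorescence", seed = 10)
  expect_false(identical(s1$counts, s3$counts))
})
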