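test_that("ordinary least squares recovers exact and noisy lines", {
  f <- fit_linear(c(0, 1), c(1, 3))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(fit_linear(1:5, rep(4, 5))$slope, 0)
  expect_error(fit_linear(rep(2, 5), 1:5), "degenerate")

  x <- 1:50
  slopes <- vapply(1:100, function(s) {
    set.seed(s)
    fit_linear(x, 4 * x + 7 + rnorm(50, 0, 0.1))$slope
  }, numeric(1))
  expect_true(all(slopes > 3.9 & slopes < 4.1))
})

test_that("the calibration chain recovers an exact synthetic chain to 1e-9", {
  tb <- exact_tables(k_corr = 10, c_corr = 2, c_fluo = 20,
                     k_med = 3, c_med = 1)
  for (branch in c("reflectance", "sfdi")) {
    chain <- build_chain(tb$depth, tb$medium, branch = branch)
    expect_equal(chain$k_corr, 10, tolerance = 1e-9)
    expect_equal(chain$c_corr, 2, tolerance = 1e-9)
    expect_equal(chain$c_fluo, 20, tolerance = 1e-9)
    med_k <- if (branch == "reflectance") chain$k_refl else chain$k_sfdi
    med_c <- if (branch == "reflectance") chain$c_refl else chain$c_sfdi
    expect_equal(med_k, 3, tolerance = 1e-9)
    expect_equal(med_c, 1, tolerance = 1e-9)
    expect_true(all(abs(unlist(chain$diagnostics) - 1) < 1e-9))
  }
})

test_that("depths outside the calibrated span are excluded from the fits", {
  tb <- exact_tables(depths = c(0.2, 0.6, 1:5))
  # corrupt the sub-millimetre rows: surface tension makes them unreliable
  bad <- tb$depth$depth_mm < 1
  tb$depth$delta_tissue_ps[bad] <- tb$depth$delta_tissue_ps[bad] + 300
  chain <- build_chain(tb$depth, tb$medium, branch = "sfdi",
                       depth_range = c(1, 5))
  expect_equal(chain$k_corr, tb$truth$k_corr, tolerance = 1e-9)
  expect_equal(chain$c_fluo, tb$truth$c_fluo, tolerance = 1e-9)
})

test_that("chain construction reports what is missing", {
  tb <- exact_tables(ils = 2)
  expect_error(build_chain(tb$depth, tb$medium, "sfdi"), "2 IL levels")
  tb2 <- exact_tables(depths = 3)
  expect_error(build_chain(tb2$depth, tb2$medium, "sfdi"), ">= 2 in the depth range")
  expect_error(build_chain(data.frame(a = 1), exact_tables()$medium, "sfdi"),
               "must have columns")
})

test_that("an identity-configured chain returns the TOF value as depth", {
  ds <- expand.grid(il_percent = c(1, 2), depth_mm = 1:5)
  ds$delta_tissue_ps <- ds$depth_mm          # k_fluo = 1, c_fluo = 0
  ms <- data.frame(il_percent = c(1, 2), delta_refl_ps = c(4, 7))
  chain <- build_chain(ds, ms, branch = "reflectance")
  expect_equal(chain$k_corr, 0, tolerance = 1e-12)
  expect_equal(chain$c_corr, 1, tolerance = 1e-12)
  est <- depth_from_tof(3.25, 5.5, chain)
  expect_true(est$valid)
  expect_equal(est$depth_mm, 3.25, tolerance = 1e-12)
})

test_that("depth inversion is the exact inverse of the forward maps on both branches", {
  tb <- exact_tables(k_corr = 10, c_corr = 2, c_fluo = 20, k_med = 3,
                     c_med = 1)
  for (branch in c("reflectance", "sfdi")) {
    chain <- build_chain(tb$depth, tb$medium, branch = branch)
    ils <- c(1, 2, 3)
    for (il in ils) {
      z <- seq(1, 5, by = 0.5)
      delta <- (10 * il + 2) * z + 20
      feat <- 3 * il + 1
      est <- depth_from_tof(delta, feat, chain)
      expect_true(all(est$valid))
      expect_equal(est$depth_mm, z, tolerance = 1e-9)
      # strictly increasing in delta_tissue at fixed medium feature
      expect_true(all(diff(est$depth_mm) > 0))
    }
  }
})

test_that("a non-positive calibrated slope flags the estimate instead of erroring", {
  tb <- exact_tables()
  chain <- build_chain(tb$depth, tb$medium, branch = "sfdi")
  # mu_s' far below c_sfdi makes the inferred slope negative
  est <- depth_from_tof(100, -40, chain)
  expect_false(est$valid)
  expect_true(is.na(est$depth_mm))
  expect_match(est$reason, "non-positive")
  out <- depth_from_tof(1e4, 7, chain)
  expect_true(out$extrapolated)
})

test_that("predict() on a calibration chain maps a table of fits to depths", {
  tb <- exact_tables()
  chain <- build_chain(tb$depth, tb$medium, branch = "sfdi")
  nd <- data.frame(delta_tissue_ps = (10 * 2 + 2) * c(2, 3) + 20,
                   mu_s_prime_per_mm = 3 * 2 + 1)
  est <- predict(chain, nd)
  expect_equal(est$depth_mm, c(2, 3), tolerance = 1e-9)
  expect_error(predict(chain, data.frame(a = 1)), "must have columns")
})

test_that("chain JSON serialization round-trips", {
  tb <- exact_tables()
  chain <- build_chain(tb$depth, tb$medium, branch = "reflectance")
  f <- file.path(tempdir(), "chain.json")
  write_chain(chain, f)
  back <- read_chain(f)
  expect_equal(coef(back), coef(chain), tolerance = 1e-12)
  expect_identical(back$branch, "reflectance")
  est1 <- depth_from_tof(80, 5, chain)
  est2 <- depth_from_tof(80, 5, back)
  expect_equal(est1$depth_mm, est2$depth_mm, tolerance = 1e-12)
  unlink(f)
})

test_that("effective attenuation follows the diffusion closed form and is monotone", {
  expect_equal(mu_eff(0, 2), 0)
  expect_equal(mu_eff(1, 2), 3)
  expect_equal(mu_eff(0.01, 1.0), sqrt(3 * 0.01 * 1.01))
  expect_equal(mu_eff(0.01, 1.0), 0.1740689, tolerance = 1e-6)
  expect_error(mu_eff(-0.1, 1), "non-negative")
  grid <- seq(0.01, 0.2, length.out = 10)
  expect_true(all(diff(vapply(grid, mu_eff, numeric(1),
                              mu_s_prime = 1)) > 0))
  expect_true(all(diff(vapply(grid * 10, function(m) mu_eff(0.01, m),
                              numeric(1))) > 0))
  props <- optical_properties(0.01, 1.0)
  expect_equal(props$mu_eff, mu_eff(0.01, 1.0))
})

test_that("intensity correction inverts depth attenuation exactly", {
  props <- optical_properties(0.01, 1.0)
  expect_equal(correct_intensity(5, 0, props), 5)
  I0 <- 123.4
  att <- attenuate_intensity(I0, 3.2, props)
  expect_equal(correct_intensity(att, 3.2, props), I0, tolerance = 1e-12)
  att2 <- attenuate_intensity(I0, 3.2, props, convention = "squared")
  expect_equal(correct_intensity(att2, 3.2, props, convention = "squared"),
               I0, tolerance = 1e-12)
  expect_gt(att, att2 * 0)  # sanity: both positive
  expect_error(correct_intensity(1, -1, props), ">= 0")
})

test_that("corrected intensities flatten a noisy depth series that decays when raw", {
  props <- optical_properties(0.01, 2.05)
  z <- 1:4
  L <- 100
  set.seed(31)
  raw <- attenuate_intensity(L, z, props) * exp(rnorm(4, 0, 0.03))
  expect_true(all(diff(raw) < 0))
  corr <- correct_intensity(raw, z, props)
  expect_lt(sd(corr) / mean(corr), 0.10)
})
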