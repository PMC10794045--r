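#' Fluorophore model
#'
#' @param tau Fluorescence lifetime in ns (mono-exponential decay). Default
#'   0.7 ns, the measured lifetime of the dye used throughout; `tau` is a
#'   user input here, never fitted.
#' @param quantum_yield_scale Dimensionless emission scale.
#' @return An object of class `fluorophore`.
#' @export
fluorophore <- function(tau = 0.7, quantum_yield_scale = 1) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("fluorescence lifetime `tau` must be a single positive number (ns)")
  if (quantum_yield_scale < 0) stop("`quantum_yield_scale` must be >= 0")
  structure(list(tau = tau, quantum_yield_scale = quantum_yield_scale),
            class = "fluorophore")
}

#' Gaussian medium transfer function parameters
#'
#' The medium transfer function is modeled as a Gaussian: `A` is its area
#' (amplitude), `delta_tissue` its mean — the relative time of flight that
#' serves as the depth surrogate — and `sigma` its standard deviation, the
#' temporal dispersion added by scattering.
#'
#' @param A Amplitude (area, in count units after convolution with a raw
#'   IRF; dimensionless for normalized work).
#' @param delta_tissue Gaussian mean, relative TOF in ps.
#' @param sigma Gaussian standard deviation in ps.
#' @return An object of class `medium_transfer`.
#' @export
medium_transfer <- function(A, delta_tissue, sigma) {
  if (!is.finite(A) || A < 0) stop("amplitude `A` must be >= 0")
  if (!is.finite(delta_tissue)) stop("`delta_tissue` must be finite (ps)")
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be > 0 (ps)")
  structure(list(A = A, delta_tissue = delta_tissue, sigma = sigma),
            class = "medium_transfer")
}

#' Gated SPAD sensor accumulation model
#'
#' Photon detection is binary per frame; a gate sequence accumulates
#' `frames_per_gate_sequence` binary frames into one count value, so counts
#' saturate (pile up) when the per-frame detection probability approaches 1.
#'
#' @param exposure_per_binary_frame Exposure per binary frame, in
#'   microseconds. Default 4.
#' @param frames_per_gate_sequence Binary frames accumulated per gate
#'   position. Default 256 (8-bit counts).
#' @param linear_range_ceiling Mean counts per gate sequence up to which the
#'   response is considered linear. Default `0.2 * frames`.
#' @param dark_count_rate Dark counts per pixel per second. Default 100.
#' @return An object of class `sensor_response`.
#' @export
sensor_response <- function(exposure_per_binary_frame = 4,
                            frames_per_gate_sequence = 256,
                            linear_range_ceiling =
                              0.2 * frames_per_gate_sequence,
                            dark_count_rate = 100) {
  if (frames_per_gate_sequence < 1) stop("`frames_per_gate_sequence` must be >= 1")
  frames_per_gate_sequence <- as.integer(frames_per_gate_sequence)
  if (linear_range_ceiling <= 0 || linear_range_ceiling > frames_per_gate_sequence)
    stop("`linear_range_ceiling` must be in (0, frames_per_gate_sequence]")
  if (exposure_per_binary_frame <= 0) stop("`exposure_per_binary_frame` must be > 0")
  if (dark_count_rate < 0) stop("`dark_count_rate` must be >= 0")
  structure(list(exposure_per_binary_frame = exposure_per_binary_frame,
                 frames_per_gate_sequence = frames_per_gate_sequence,
                 linear_range_ceiling = linear_range_ceiling,
                 dark_count_rate = dark_count_rate),
            class = "sensor_response")
}

#' Expected dark counts per gate sequence for a sensor
#' @param sensor A [sensor_response()].
#' @return Expected dark counts accumulated over one gate sequence.
#' @export
dark_counts_per_sequence <- function(sensor) {
  stopifnot(inherits(sensor, "sensor_response"))
  sensor$dark_count_rate * sensor$exposure_per_binary_frame * 1e-6 *
    sensor$frames_per_gate_sequence
}

# ---- kernels and discrete convolution --------------------------------------

#' Exponentially modified Gaussian density
#'
#' Density of the convolution of a Gaussian (mean `delta`, sd `sigma`) with
#' a causal unit-area exponential of time constant `tau` (all in ps),
#' evaluated in a numerically stable log form.
#'
#' @param t Times (ps).
#' @param delta Gaussian mean (ps).
#' @param sigma Gaussian sd (ps).
#' @param tau Exponential time constant (ps).
#' @return Density values (1/ps) at `t`.
#' @export
emg_density <- function(t, delta, sigma, tau) {
  stopifnot(sigma > 0, tau > 0)
  z <- sigma / tau - (t - delta) / sigma
  # f = (1/2tau) exp(sigma^2/2tau^2 - (t-delta)/tau) * erfc(z/sqrt(2))
  # erfc(z/sqrt(2)) = 2*pnorm(-z); combine in log space to avoid overflow
  logf <- -log(tau) + sigma^2 / (2 * tau^2) - (t - delta) / tau +
    stats::pnorm(-z, log.p = TRUE)
  exp(logf)
}

# Medium-transfer kernel sampled on a circular padded grid of length N.
# Offsets j = 0..N-1 map to signed lags ((j + N/2) %% N) - N/2 times dt.
# The Gaussian x causal-exponential product is evaluated analytically (EMG),
# so a delta IRF reproduces the continuous-model profile exactly on the grid.
transfer_kernel <- function(N, dt, delta, sigma, tau_ps = NULL) {
  j <- 0:(N - 1)
  lag <- ((j + N %/% 2) %% N) - N %/% 2
  u <- lag * dt
  k <- if (is.null(tau_ps)) {
    stats::dnorm(u, mean = delta, sd = sigma)
  } else {
    emg_density(u, delta = delta, sigma = sigma, tau = tau_ps)
  }
  s <- sum(k)
  if (s <= 0) stop("degenerate transfer kernel (all mass outside padded axis)")
  k / s
}

# Linear convolution of x with a circular kernel, zero-padded to >= pad_mult
# times the axis length; result cropped back to length(x). A precomputed
# conv_cache(x, ...) avoids re-transforming the IRF inside optimizer loops.
conv_cache <- function(x, pad_mult = 3) {
  n <- length(x)
  N <- stats::nextn(pad_mult * n, factors = 2)
  list(n = n, N = N, xfft = stats::fft(c(x, rep(0, N - n))))
}

conv_padded <- function(x, dt, delta, sigma, tau_ps = NULL, pad_mult = 3,
                        cache = NULL) {
  if (is.null(cache)) cache <- conv_cache(x, pad_mult)
  k <- transfer_kernel(cache$N, dt, delta, sigma, tau_ps)
  out <- Re(stats::fft(cache$xfft * stats::fft(k), inverse = TRUE)) / cache$N
  out[seq_len(cache$n)]
}

# ---- simulator operations --------------------------------------------------

#' Synthesize an instrument response function profile
#'
#' Models the system IRF (laser pulse + detector + gating, as acquired from
#' a Lambertian white target) as a smooth unimodal Gaussian pulse of the
#' stated full width at half maximum. The functional form is a modeling
#' choice; the instrument only bounds the laser pulse below 120 ps.
#'
#' @param axis A [gate_axis()].
#' @param pulse_fwhm Pulse FWHM in ps; must span at least 3 gate steps.
#' @param amplitude Total counts in the returned profile (its sum).
#' @param center Peak position in ps relative to `t0`. Default places the
#'   peak at 10% of the axis span so the rising edge and tail are fully
#'   resolved.
#' @return A noise-free `time_profile` of modality `"irf"` whose values sum
#'   to `amplitude`.
#' @export
make_irf <- function(axis, pulse_fwhm = 110, amplitude = 1,
                     center = 0.1 * axis_span(axis)) {
  stopifnot(inherits(axis, "gate_axis"))
  if (!is.finite(pulse_fwhm) || pulse_fwhm <= 0)
    stop("`pulse_fwhm` must be > 0 (ps)")
  if (pulse_fwhm < 3 * axis$dt)
    stop(sprintf(paste("IRF FWHM (%.3g ps) spans fewer than 3 gate steps",
                       "(dt = %.3g ps): pulse under-sampled on this axis"),
                 pulse_fwhm, axis$dt))
  if (amplitude < 0) stop("`amplitude` must be >= 0")
  sd <- pulse_fwhm / (2 * sqrt(2 * log(2)))
  t <- axis_times(axis) - axis$t0
  v <- stats::dnorm(t, mean = center, sd = sd)
  s <- sum(v)
  if (s <= 0) stop("IRF pulse falls outside the axis")
  time_profile(amplitude * v / s, axis, modality = "irf",
               provenance = list(pulse_fwhm_ps = pulse_fwhm,
                                 center_ps = center))
}

#' Forward model: IRF convolved with the medium transfer function
#'
#' Computes the noise-free expected profile: the discrete convolution of
#' the IRF with a unit-area Gaussian of mean `delta_tissue` and standard
#' deviation `sigma`, scaled by `A`; when a fluorophore is given the
#' Gaussian is additionally convolved with a causal unit-area exponential
#' `exp(-t / tau)` (t >= 0). The Gaussian-exponential product is evaluated
#' in closed form (exponentially modified Gaussian) sampled on the gate
#' grid, then convolved once with the IRF with zero-padding to at least
#' three axis lengths before cropping.
#'
#' @param irf A `time_profile` (modality `"irf"`).
#' @param medium A [medium_transfer()].
#' @param fluor A [fluorophore()], or `NULL` for the reflectance model.
#' @return A noise-free `time_profile` on the IRF's axis.
#' @export
forward_profile <- function(irf, medium, fluor = NULL) {
  stopifnot(inherits(irf, "time_profile"), inherits(medium, "medium_transfer"))
  ax <- irf$axis
  if (medium$sigma < ax$dt / 2)
    warning(sprintf("sigma (%.3g ps) below half the gate step (%.3g ps): model under-resolved",
                    medium$sigma, ax$dt))
  tau_ps <- NULL
  scale <- medium$A
  modality <- "reflectance"
  if (!is.null(fluor)) {
    stopifnot(inherits(fluor, "fluorophore"))
    tau_ps <- fluor$tau * 1000
    scale <- scale * fluor$quantum_yield_scale
    modality <- "fluorescence"
  }
  # FFT roundoff can leave ~1e-17-scale negatives; expected counts are >= 0
  v <- pmax(scale * conv_padded(irf$values, ax$dt, medium$delta_tissue,
                                medium$sigma, tau_ps), 0)
  time_profile(v, ax, modality = modality,
               provenance = list(model = "irf (*) gaussian (*) exp",
                                 A = medium$A,
                                 delta_tissue_ps = medium$delta_tissue,
                                 sigma_ps = medium$sigma,
                                 tau_ns = if (is.null(fluor)) NA_real_
                                          else fluor$tau))
}

# Counter-based per-pixel stream seeds: multiplicative hash mod 2^31 - 1,
# with exact modular multiplication in doubles (operands split to 16 bits).
mulmod31 <- function(a, b, m = 2147483647) {
  a <- a %% m; b <- b %% m
  ah <- a %/% 65536; al <- a %% 65536
  (((ah * b) %% m) * 65536 + al * b) %% m
}

#' Derive an independent stream seed from a master seed and a counter
#'
#' @param seed Master integer seed.
#' @param counter Non-negative stream index (e.g. pixel linear index).
#' @return An integer seed in `[1, 2^31 - 2]`, deterministic in both inputs.
#' @export
derive_seed <- function(seed, counter) {
  m <- 2147483647
  h <- mulmod31(seed %% m + 1, 48271)
  h <- (h + mulmod31(counter %% m + 1, 69621)) %% m
  as.integer(mulmod31(h + 1, 16807) %% (m - 1) + 1)
}

#' Apply gated single-photon counting noise to an expected profile
#'
#' Per gate step, the accumulated count is drawn as
#' `Binomial(F, 1 - exp(-lambda / F))` with `F` binary frames per gate
#' sequence and `lambda` the expected photon count (signal plus dark).
#' This reproduces Poisson statistics at low flux and pile-up saturation
#' at high flux, clamping at `F` by construction.
#'
#' @param profile Noise-free expected-count `time_profile` (values >= 0).
#' @param sensor A [sensor_response()].
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A `time_profile` of integer counts.
#' @export
add_photon_noise <- function(profile, sensor, seed) {
  stopifnot(inherits(profile, "time_profile"),
            inherits(sensor, "sensor_response"))
  if (any(profile$values < 0)) stop("expected counts must be >= 0")
  lam <- profile$values + dark_counts_per_sequence(sensor)
  FF <- sensor$frames_per_gate_sequence
  p <- -expm1(-lam / FF)
  out <- profile
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  out$values <- as.numeric(stats::rbinom(length(lam), FF, p))
  out$provenance <- c(profile$provenance, list(noise_seed = seed))
  out
}

# ---- phantom scenes --------------------------------------------------------

# Synthetic scene constants: linear maps from Intralipid concentration to
# reduced scattering and to the TOF-depth slope, plus reflectance-timing
# parameters. Magnitudes follow diffuse-optics conventions for Intralipid
# phantoms in the 635-660 nm band; slopes are positive as required.
scene_defaults <- function() {
  list(
    mu_s_prime_per_il = 1.0,    # mm^-1 per IL%
    mu_s_prime_offset = 0.05,   # mm^-1
    mu_a_default      = 0.005,  # mm^-1 (near-zero absorption, aqueous IL)
    k_corr            = 10,     # ps/mm per IL% (slope of k_fluo vs IL)
    c_corr            = 5,      # ps/mm
    c_fluo            = 20,     # ps, setup-geometry TOF offset
    sigma0            = 120,    # ps, dispersion at zero depth
    sigma_slope       = 25,     # ps per (mm^-1 * mm), growth with mu_s' * z
    refl_delta0       = 30,     # ps, reflectance Gaussian mean offset
    refl_delta_slope  = 6,      # ps per mm^-1 of mu_s'
    refl_sigma0       = 60,     # ps
    refl_sigma_slope  = 10,     # ps per mm^-1 of mu_s'
    irf_fwhm          = 110     # ps (laser pulse bounded below 120 ps)
  )
}

#' Phantom scene for scan simulation
#'
#' Describes a grid of pixels over a turbid medium, with an optional
#' fluorescent inclusion depth per pixel, the medium optical properties,
#' and the ground-truth linear TOF-depth map used by the simulator
#' (`delta_tissue = k_fluo * depth + c_fluo`).
#'
#' @param depth Numeric matrix of inclusion depths in mm; `NA` marks
#'   background pixels with no inclusion.
#' @param il_percent Intralipid concentration (%), the scattering pivot.
#' @param mu_a Absorption coefficient (1/mm). Default from scene constants.
#' @param mu_s_prime Reduced scattering coefficient (1/mm); by default the
#'   linear Intralipid map `1.0 * IL + 0.05`.
#' @param k_fluo Ground-truth TOF-depth slope (ps/mm); by default
#'   `k_corr * IL + c_corr` with the package's synthetic constants.
#' @param c_fluo Ground-truth TOF offset (ps).
#' @param concentration_scale Fluorophore concentration scale multiplying
#'   the emitted amplitude.
#' @param peak_counts Expected peak counts of a zero-depth inclusion
#'   profile before noise.
#' @return An object of class `phantom_scene`.
#' @export
phantom_scene <- function(depth, il_percent = 2,
                          mu_a = NULL, mu_s_prime = NULL,
                          k_fluo = NULL, c_fluo = NULL,
                          concentration_scale = 1, peak_counts = 40) {
  d <- scene_defaults()
  depth <- as.matrix(depth)
  if (any(depth < 0, na.rm = TRUE)) stop("depths must be >= 0 (mm)")
  if (il_percent < 0) stop("`il_percent` must be >= 0")
  if (is.null(mu_s_prime))
    mu_s_prime <- d$mu_s_prime_per_il * il_percent + d$mu_s_prime_offset
  if (is.null(mu_a)) mu_a <- d$mu_a_default
  if (mu_a < 0) stop("`mu_a` must be >= 0")
  if (mu_s_prime <= 0) stop("`mu_s_prime` must be > 0")
  if (is.null(k_fluo)) k_fluo <- d$k_corr * il_percent + d$c_corr
  if (is.null(c_fluo)) c_fluo <- d$c_fluo
  structure(list(depth = depth, rows = nrow(depth), cols = ncol(depth),
                 il_percent = il_percent, mu_a = mu_a,
                 mu_s_prime = mu_s_prime, k_fluo = k_fluo, c_fluo = c_fluo,
                 concentration_scale = concentration_scale,
                 peak_counts = peak_counts, constants = d),
            class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene> %dx%d px, IL %.2g%%, mu_s' %.3g /mm, mu_a %.3g /mm\n",
              x$rows, x$cols, x$il_percent, x$mu_s_prime, x$mu_a))
  dd <- x$depth[is.finite(x$depth)]
  if (length(dd))
    cat(sprintf("  inclusion depths %.2g-%.2g mm over %d px; k_fluo %.3g ps/mm, c_fluo %.3g ps\n",
                min(dd), max(dd), length(dd), x$k_fluo, x$c_fluo))
  invisible(x)
}

#' Two-cylinder phantom scene
#'
#' A tissue-like block with two horizontal cylindrical inclusions at two
#' depths (defaults 2.5 and 5.6 mm), mimicking the sealed fluorescent
#' tubes embedded in a gelatin/blood/Intralipid phantom.
#'
#' @param rows,cols Grid size in (super)pixels.
#' @param depths Two inclusion depths in mm.
#' @param radius_px Cylinder footprint half-width in pixels.
#' @param ... Passed to [phantom_scene()].
#' @return A `phantom_scene` whose provenance records the two footprints.
#' @export
two_cylinder_scene <- function(rows = 24, cols = 44, depths = c(2.5, 5.6),
                               radius_px = max(2, rows %/% 6), ...) {
  stopifnot(length(depths) == 2)
  depth <- matrix(NA_real_, rows, cols)
  centers <- round(c(0.3, 0.7) * cols)
  rows_idx <- seq_len(rows)
  band <- rows_idx[abs(rows_idx - (rows + 1) / 2) <= rows / 3]
  fp <- list()
  for (i in 1:2) {
    cols_idx <- pmax(1, centers[i] - radius_px):pmin(cols, centers[i] + radius_px)
    depth[band, cols_idx] <- depths[i]
    fp[[i]] <- list(rows = band, cols = cols_idx, depth_mm = depths[i])
  }
  sc <- phantom_scene(depth, ...)
  sc$footprints <- fp
  sc
}

#' Simulate a full time-gated scan of a phantom scene
#'
#' Builds, per pixel, the noise-free expected profile and applies gated
#' photon-counting noise with an independent counter-based stream per
#' pixel. For fluorescence, the medium transfer mean is
#' `k_fluo * z + c_fluo`, the dispersion grows as
#' `sigma0 + sigma_slope * mu_s' * z`, and the surface amplitude is
#' attenuated by `exp(-2 * mu_eff * z)`; background pixels carry dark
#' counts only. Reflectance is a surface-weighted non-fluorescent return
#' whose timing and width depend on the medium scattering. The IRF
#' modality replicates the instrument pulse at every pixel.
#'
#' @param scene A [phantom_scene()].
#' @param axis A [gate_axis()].
#' @param sensor A [sensor_response()].
#' @param modality `"fluorescence"`, `"reflectance"` or `"irf"`.
#' @param seed Integer master seed.
#' @param irf Optional `time_profile` to use as the instrument response;
#'   default a [make_irf()] pulse with the scene's IRF constants.
#' @param noise If `FALSE`, return expected counts without photon noise.
#' @return A [time_scan()] whose provenance stores the ground truth
#'   (per-pixel `delta_tissue`, `sigma`, amplitude and the scene).
#' @export
simulate_scan <- function(scene, axis, sensor = sensor_response(),
                          modality = c("fluorescence", "reflectance", "irf"),
                          seed = 1, irf = NULL, noise = TRUE) {
  stopifnot(inherits(scene, "phantom_scene"), inherits(axis, "gate_axis"),
            inherits(sensor, "sensor_response"))
  modality <- match.arg(modality)
  d <- scene$constants
  if (is.null(irf))
    irf <- make_irf(axis, pulse_fwhm = d$irf_fwhm, amplitude = 1)
  if (!same_axis(irf$axis, axis)) stop("`irf` must be on the given axis")
  nr <- scene$rows; nc <- scene$cols; nt <- axis$n_steps
  counts <- array(0, c(nr, nc, nt))
  truth <- list(delta_tissue = matrix(NA_real_, nr, nc),
                sigma = matrix(NA_real_, nr, nc),
                amplitude = matrix(NA_real_, nr, nc))
  me <- mu_eff(scene$mu_a, scene$mu_s_prime)

  if (modality == "fluorescence") {
    fl <- fluorophore()
    depths <- unique(scene$depth[is.finite(scene$depth)])
    cache <- list()
    for (z in depths) {
      delta <- scene$k_fluo * z + scene$c_fluo
      sig <- d$sigma0 + d$sigma_slope * scene$mu_s_prime * z
      shape <- pmax(conv_padded(irf$values, axis$dt, delta, sig,
                                fl$tau * 1000), 0)
      amp <- scene$peak_counts * scene$concentration_scale * exp(-2 * me * z)
      expected <- amp * shape / max(shape)
      cache[[as.character(z)]] <-
        list(expected = expected, delta = delta, sigma = sig, amp = amp)
    }
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      z <- scene$depth[i, j]
      if (is.finite(z)) {
        cc <- cache[[as.character(z)]]
        counts[i, j, ] <- cc$expected
        truth$delta_tissue[i, j] <- cc$delta
        truth$sigma[i, j] <- cc$sigma
        truth$amplitude[i, j] <- cc$amp
      }
    }
  } else if (modality == "reflectance") {
    delta <- d$refl_delta0 + d$refl_delta_slope * scene$mu_s_prime
    sig <- d$refl_sigma0 + d$refl_sigma_slope * scene$mu_s_prime
    shape <- pmax(conv_padded(irf$values, axis$dt, delta, sig), 0)
    amp <- scene$peak_counts
    expected <- amp * shape / max(shape)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      counts[i, j, ] <- expected
      truth$delta_tissue[i, j] <- delta
      truth$sigma[i, j] <- sig
      truth$amplitude[i, j] <- amp
    }
  } else { # irf
    expected <- scene$peak_counts * irf$values / max(irf$values)
    for (i in seq_len(nr)) for (j in seq_len(nc)) counts[i, j, ] <- expected
  }

  if (noise) {
    FF <- sensor$frames_per_gate_sequence
    dk <- dark_counts_per_sequence(sensor)
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      lam <- counts[i, j, ] + dk
      s <- derive_seed(seed, (i - 1) * nc + (j - 1))
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(s)
      counts[i, j, ] <- stats::rbinom(nt, FF, -expm1(-lam / FF))
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    }
  }

  time_scan(counts, axis, modality = if (modality == "irf") "irf" else modality,
            provenance = list(source = "fluortof simulator", seed = seed,
                              noise = noise,
                              scene = scene, ground_truth = truth,
                              irf_center_ps = irf$provenance$center_ps))
}
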