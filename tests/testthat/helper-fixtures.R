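# Shared fixture builders. All data is generated in code at test time.

test_axis <- function(n_steps = 512, dt = 17.857, t0 = 0)
  gate_axis(t0 = t0, dt = dt, n_steps = n_steps)

# Single-sample (delta) IRF for closed-form convolution oracles.
delta_irf <- function(axis, at = 50) {
  v <- rep(0, axis$n_steps); v[at] <- 1
  time_profile(v, axis, modality = "irf")
}

# Closed-form exponentially modified Gaussian, written independently of
# the package's emg_density (plain erfc form; parameters chosen so it
# does not overflow).
emg_oracle <- function(t, delta, sigma, tau_ps) {
  erfc <- function(x) 2 * stats::pnorm(-sqrt(2) * x)
  (1 / (2 * tau_ps)) * exp(sigma^2 / (2 * tau_ps^2) - (t - delta) / tau_ps) *
    erfc((sigma / tau_ps - (t - delta) / sigma) / sqrt(2))
}

# Noise-free fluorescence profile plus Poisson counts at a given peak
# expectation (ROI-accumulated counts: binomial frames chosen large, so
# the detector operates in its linear range).
noisy_fluo_profile <- function(irf, delta, sigma, peak_counts,
                               tau = 0.7, seed = 1) {
  clean <- forward_profile(irf, medium_transfer(1, delta, sigma),
                           fluorophore(tau))
  lam <- peak_counts * clean$values / max(clean$values)
  sens <- sensor_response(frames_per_gate_sequence = 65536,
                          dark_count_rate = 0)
  add_photon_noise(time_profile(lam, irf$axis), sens, seed = seed)
}

# Exact calibration tables produced by the linear forward maps; used by
# chain-recovery and round-trip identity tests.
exact_tables <- function(k_corr = 10, c_corr = 2, c_fluo = 20,
                         k_med = 3, c_med = 1,
                         ils = c(1, 2, 3), depths = 1:5) {
  ds <- expand.grid(il_percent = ils, depth_mm = depths)
  ds$delta_tissue_ps <- (k_corr * ds$il_percent + c_corr) * ds$depth_mm +
    c_fluo
  ms <- data.frame(il_percent = ils,
                   delta_refl_ps = k_med * ils + c_med,
                   mu_s_prime_per_mm = k_med * ils + c_med)
  list(depth = ds, medium = ms,
       truth = list(k_corr = k_corr, c_corr = c_corr, c_fluo = c_fluo,
                    k_med = k_med, c_med = c_med))
}

# Small scan of i.i.d. Poisson counts around a constant expectation.
poisson_scan <- function(rows, cols, n_steps, lambda, seed,
                         modality = "fluorescence", dt = 17.857) {
  ax <- gate_axis(dt = dt, n_steps = n_steps)
  set.seed(seed)
  counts <- array(stats::rpois(rows * cols * n_steps, lambda),
                  c(rows, cols, n_steps))
  time_scan(counts, ax, modality = modality)
}
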