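#' Spatial map of one fitted quantity
#'
#' @param values Numeric matrix of the quantity.
#' @param quantity One of `"delta_tissue"`, `"sigma"`, `"A"`,
#'   `"r_squared"`, `"depth"`, `"intensity"`.
#' @param mask Logical matrix, `TRUE` where the entry is valid.
#' @param bin_factor Spatial binning factor of the source scan.
#' @param provenance Free-form record (scan id, chain id).
#' @return An object of class `parameter_map`.
#' @export
parameter_map <- function(values, quantity, mask = NULL, bin_factor = 1L,
                          provenance = NULL) {
  values <- as.matrix(values)
  quantity <- match.arg(quantity, c("delta_tissue", "sigma", "A",
                                    "r_squared", "depth", "intensity"))
  if (is.null(mask)) mask <- is.finite(values)
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(values))) stop("mask shape must match values")
  values[!mask] <- NA_real_
  structure(list(values = values, quantity = quantity, mask = mask,
                 bin_factor = as.integer(bin_factor),
                 provenance = provenance),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("<parameter_map> %s, %d x %d (bin %d), %d/%d valid, range [%.4g, %.4g]\n",
              x$quantity, nrow(x$values), ncol(x$values), x$bin_factor,
              sum(x$mask), length(x$mask),
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' @export
plot.parameter_map <- function(x, ...,
                               col = grDevices::hcl.colors(64, "viridis")) {
  v <- x$values
  graphics::image(t(v[nrow(v):1, , drop = FALSE]), col = col, axes = FALSE,
                  main = x$quantity, ...)
  invisible(x)
}

#' Spatially bin a time scan
#'
#' Sums non-overlapping `factor x factor` pixel blocks per gate step
#' (sums, not means, to preserve photon statistics; the later profile
#' normalization removes the scale). Trailing partial blocks are dropped.
#'
#' @param scan A [time_scan()].
#' @param factor Positive integer binning factor; default 8.
#' @return Binned `time_scan`.
#' @export
bin_scan <- function(scan, factor = 8L) {
  stopifnot(inherits(scan, "time_scan"))
  factor <- as.integer(factor)
  if (factor < 1) stop("`factor` must be >= 1")
  if (factor == 1L) return(scan)
  d <- dim(scan$counts)
  if (factor > d[1] || factor > d[2])
    stop("binning factor exceeds a spatial dimension")
  nr <- d[1] %/% factor; nc <- d[2] %/% factor
  a <- scan$counts[seq_len(nr * factor), seq_len(nc * factor), , drop = FALSE]
  dim(a) <- c(factor, nr, factor, nc, d[3])
  b <- colSums(a)                       # (nr, factor, nc, nt)
  b <- colSums(aperm(b, c(2, 1, 3, 4))) # (nr, nc, nt)
  time_scan(b, scan$axis, modality = scan$modality,
            provenance = c(scan$provenance, list(bin_factor = factor)),
            averaged = scan$averaged)
}

default_norm_window <- function(n) min(200L, max(3L, n %/% 7L))

#' Per-superpixel model fitting over a time scan
#'
#' Runs the full profile pipeline on every (super)pixel: normalization,
#' then the convolution-model fit ([fit_fluorescence()] or
#' [fit_reflectance()] by modality) using the corresponding pixel of the
#' IRF scan. Per-pixel failures are recorded in the validity mask and
#' never abort the map.
#'
#' @param scan A (typically binned) [time_scan()].
#' @param irf_scan IRF [time_scan()] of the same axis and shape.
#' @param tau Fluorescence lifetime (ns) for fluorescence scans.
#' @param chain Optional [build_chain()] calibration; with
#'   `medium_feature` it adds a depth map.
#' @param medium_feature Medium feature (scalar, or matrix matching the
#'   map) for the chain's branch.
#' @param n_top,n_tail Normalization windows; defaults scale with axis
#'   length (200 on a full-length axis).
#' @param r_squared_min Entries with lower goodness of fit are masked.
#' @return Named list of [parameter_map()]s: `delta_tissue`, `sigma`,
#'   `A`, `r_squared`, and `depth` when a chain is given.
#' @export
fit_map <- function(scan, irf_scan, tau = 0.7, chain = NULL,
                    medium_feature = NULL,
                    n_top = NULL, n_tail = NULL, r_squared_min = 0.5) {
  stopifnot(inherits(scan, "time_scan"), inherits(irf_scan, "time_scan"))
  if (!same_axis(scan$axis, irf_scan$axis))
    stop("scan and IRF scan must share the same gate axis")
  d <- dim(scan$counts)
  if (!all(dim(irf_scan$counts)[1:2] == d[1:2]))
    stop("scan and IRF scan must share the same (binned) spatial shape")
  n <- scan$axis$n_steps
  if (is.null(n_top)) n_top <- default_norm_window(n)
  if (is.null(n_tail)) n_tail <- default_norm_window(n)
  fluo <- scan$modality == "fluorescence"
  maps <- list(delta_tissue = matrix(NA_real_, d[1], d[2]),
               sigma = matrix(NA_real_, d[1], d[2]),
               A = matrix(NA_real_, d[1], d[2]),
               r_squared = matrix(NA_real_, d[1], d[2]))
  ok <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    res <- try({
      tp <- time_profile(scan$counts[i, j, ], scan$axis,
                         modality = scan$modality)
      irf <- time_profile(irf_scan$counts[i, j, ], scan$axis,
                          modality = "irf")
      tpn <- normalize_profile(tp, n_top = n_top, n_tail = n_tail)
      if (fluo) fit_fluorescence(tpn, irf, tau = tau)
      else fit_reflectance(tpn, irf)
    }, silent = TRUE)
    if (inherits(res, "try-error")) next
    maps$delta_tissue[i, j] <- res$coefficients["delta_tissue"]
    maps$sigma[i, j] <- res$coefficients["sigma"]
    maps$A[i, j] <- res$coefficients["A"]
    maps$r_squared[i, j] <- res$r_squared
    ok[i, j] <- isTRUE(res$converged) && isTRUE(res$r_squared >= r_squared_min)
  }
  bf <- scan$provenance$bin_factor
  if (is.null(bf)) bf <- 1L
  prov <- list(modality = scan$modality, tau_ns = if (fluo) tau else NA_real_)
  out <- list(
    delta_tissue = parameter_map(maps$delta_tissue, "delta_tissue", ok, bf, prov),
    sigma = parameter_map(maps$sigma, "sigma", ok, bf, prov),
    A = parameter_map(maps$A, "A", ok, bf, prov),
    r_squared = parameter_map(maps$r_squared, "r_squared", ok, bf, prov))
  if (!is.null(chain)) {
    if (is.null(medium_feature))
      stop("`medium_feature` is required to produce a depth map from a chain")
    feat <- if (length(medium_feature) == 1)
      rep(medium_feature, length(maps$delta_tissue)) else as.matrix(medium_feature)
    est <- depth_from_tof(as.vector(maps$delta_tissue), as.vector(feat), chain)
    depth <- matrix(est$depth_mm, d[1], d[2])
    out$depth <- parameter_map(depth, "depth",
                               ok & matrix(est$valid, d[1], d[2]), bf, prov)
  }
  out
}

#' Mask a map by fluorescence intensity
#'
#' Retains only entries whose intensity is credibly above background:
#' either an SNR-style rule (`(I - mean(bg)) / sd(bg) >= min_snr` against
#' a designated background region) or an absolute threshold.
#'
#' @param map A [parameter_map()].
#' @param intensity An [intensity_image()] binned to the map's shape.
#' @param min_snr SNR-style threshold (default 2), used when
#'   `background_roi` is given.
#' @param background_roi `(row0, col0, height, width)` background region
#'   on the intensity image.
#' @param threshold Absolute intensity threshold, used when no
#'   `background_roi` is given. Default 0 (identity mask).
#' @return The masked `parameter_map`.
#' @export
mask_by_intensity <- function(map, intensity, min_snr = 2,
                              background_roi = NULL, threshold = 0) {
  stopifnot(inherits(map, "parameter_map"),
            inherits(intensity, "intensity_image"))
  if (!all(dim(intensity$values) == dim(map$values)))
    stop("intensity image must be binned to the map's shape")
  if (!is.null(background_roi)) {
    b <- roi_indices(background_roi, nrow(intensity$values),
                     ncol(intensity$values))
    bg <- as.vector(intensity$values[b$rows, b$cols])
    if (length(bg) < 2 || stats::sd(bg) == 0)
      stop("degenerate background region")
    keep <- (intensity$values - mean(bg)) / stats::sd(bg) >= min_snr
  } else {
    keep <- intensity$values >= threshold
  }
  out <- map
  out$mask <- map$mask & keep
  out$values[!out$mask] <- NA_real_
  if (!any(out$mask))
    warning("intensity mask removed every pixel")
  out
}

gaussian_kernel_2d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  u <- (-r):r
  k1 <- exp(-u^2 / (2 * sigma^2))
  k <- outer(k1, k1)
  k / sum(k)
}

#' Gaussian smoothing of a map, ignoring masked entries
#'
#' Normalized convolution: both the masked values (zeros filled) and the
#' validity indicator are convolved with the same Gaussian kernel and
#' their ratio is taken, so masked holes neither leak values nor bias
#' their neighbourhood. The mask itself is preserved.
#'
#' @param map A [parameter_map()].
#' @param gaussian_sigma_px Kernel standard deviation in (super)pixels;
#'   0 is the identity. Default 1.
#' @return Smoothed `parameter_map`.
#' @export
smooth_map <- function(map, gaussian_sigma_px = 1) {
  stopifnot(inherits(map, "parameter_map"))
  if (gaussian_sigma_px < 0) stop("`gaussian_sigma_px` must be >= 0")
  if (gaussian_sigma_px == 0) return(map)
  k <- gaussian_kernel_2d(gaussian_sigma_px)
  r <- (nrow(k) - 1L) %/% 2L
  v <- map$values; v[!map$mask] <- 0
  w <- map$mask * 1
  nr <- nrow(v); nc <- ncol(v)
  conv2 <- function(m) {
    out <- matrix(0, nr, nc)
    for (a in (-r):r) for (b in (-r):r) {
      kv <- k[a + r + 1L, b + r + 1L]
      rs <- pmin(pmax(seq_len(nr) - a, 1L), nr)
      cs <- pmin(pmax(seq_len(nc) - b, 1L), nc)
      # zero outside the grid: drop out-of-range shifts instead of clamping
      rvalid <- seq_len(nr) - a >= 1L & seq_len(nr) - a <= nr
      cvalid <- seq_len(nc) - b >= 1L & seq_len(nc) - b <= nc
      tmp <- matrix(0, nr, nc)
      tmp[rvalid, cvalid] <- m[rs[rvalid], cs[cvalid], drop = FALSE]
      out <- out + kv * tmp
    }
    out
  }
  num <- conv2(v); den <- conv2(w)
  sm <- ifelse(den > 0, num / den, NA_real_)
  out <- map
  out$values[map$mask] <- sm[map$mask]
  out
}

#' Convert a TOF map to a relative-depth topology map
#'
#' Re-references the fitted `delta_tissue` map so its minimum valid value
#' maps to zero (the shortest inclusion-surface distance defines the
#' surface reference), then converts the relative TOF to relative depth
#' with the calibrated slope `k_corr * IL + c_corr` reconstructed from
#' the medium feature. The output is a depth map (mm) suitable for
#' topology rendering.
#'
#' @param delta_map `parameter_map` of `delta_tissue` (ps).
#' @param chain A [build_chain()] calibration.
#' @param medium_feature Medium feature for the chain's branch (scalar or
#'   matrix).
#' @return `parameter_map` of relative depth (mm).
#' @export
tof_to_topology <- function(delta_map, chain, medium_feature) {
  stopifnot(inherits(delta_map, "parameter_map"),
            inherits(chain, "tof_calibration"))
  if (!any(delta_map$mask)) stop("no valid pixels in the TOF map")
  v <- delta_map$values
  v0 <- v - min(v[delta_map$mask])
  feat <- if (length(medium_feature) == 1)
    matrix(medium_feature, nrow(v), ncol(v)) else as.matrix(medium_feature)
  il <- if (chain$branch == "reflectance")
    (feat - chain$c_refl) / chain$k_refl
  else
    (feat - chain$c_sfdi) / chain$k_sfdi
  slope <- chain$k_corr * il + chain$c_corr
  ok <- delta_map$mask & is.finite(slope) & slope > 0
  depth <- ifelse(ok, v0 / slope, NA_real_)
  parameter_map(depth, "depth", ok, delta_map$bin_factor,
                c(delta_map$provenance, list(chain_branch = chain$branch,
                                             referenced = "min-to-zero")))
}

#' Write a parameter map as CSV (row, col, value, valid)
#'
#' @param map A [parameter_map()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "parameter_map"))
  d <- dim(map$values)
  df <- data.frame(row = rep(seq_len(d[1]) - 1L, d[2]),
                   col = rep(seq_len(d[2]) - 1L, each = d[1]),
                   value = as.vector(map$values),
                   valid = as.vector(map$mask))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
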