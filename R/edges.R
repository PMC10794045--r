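#' Extract a spatially averaged profile from a time scan
#'
#' @param scan A [time_scan()].
#' @param roi `(row0, col0, height, width)`, 0-based.
#' @return A `time_profile`: per-step spatial mean over the ROI.
#' @export
extract_profile <- function(scan, roi) {
  stopifnot(inherits(scan, "time_scan"))
  d <- dim(scan$counts)
  ri <- roi_indices(roi, d[1], d[2])
  v <- apply(scan$counts[ri$rows, ri$cols, , drop = FALSE], 3, mean)
  time_profile(v, scan$axis, modality = scan$modality, roi = roi)
}

#' Linear fit of a pulse edge
#'
#' Fits a least-squares line to the samples of a normalized profile whose
#' values lie within `[level_lo, level_hi]` on the selected edge: the run
#' ending at the first up-crossing of `level_hi` for the rising edge, or
#' starting at the last down-crossing for the falling edge. The fitted
#' line's zero-crossing `t_ref` serves as the acquisition's time
#' reference.
#'
#' @param tp A normalized [time_profile()].
#' @param edge `"rising"` or `"falling"`.
#' @param level_lo,level_hi Normalized window bounds; defaults 0.2 and 0.8.
#' @return An object of class `edge_fit` with `slope` (1/ps),
#'   `intercept`, `fit_window` (sample indices) and `t_ref` (ps).
#' @export
fit_edge <- function(tp, edge = c("rising", "falling"),
                     level_lo = 0.2, level_hi = 0.8) {
  stopifnot(inherits(tp, "time_profile"))
  edge <- match.arg(edge)
  if (!tp$normalized) stop("`tp` must be normalized (see normalize_profile)")
  if (!(level_lo < level_hi)) stop("`level_lo` must be < `level_hi`")
  v <- tp$values; n <- length(v); t <- axis_times(tp$axis)
  if (edge == "rising") {
    ihi <- which(v >= level_hi)[1]
    if (is.na(ihi)) stop("profile never reaches level_hi: no rising edge")
    i <- ihi
    while (i > 1 && v[i - 1] >= level_lo && v[i - 1] <= v[i] + 0.05) i <- i - 1
    idx <- i:ihi
  } else {
    ihi <- which(v >= level_hi)
    if (!length(ihi)) stop("profile never reaches level_hi: no falling edge")
    i0 <- max(ihi)  # last sample at/above level_hi
    i <- i0
    while (i < n && v[i + 1] >= level_lo && v[i + 1] <= v[i] + 0.05) i <- i + 1
    idx <- i0:i
  }
  idx <- idx[v[idx] >= level_lo & v[idx] <= level_hi]
  if (length(idx) < 3)
    stop("fewer than 3 samples inside the edge-fit window")
  vv <- v[idx]
  dirv <- if (edge == "rising") vv else rev(vv)
  if (max(cummax(dirv) - dirv) > 0.25 * (level_hi - level_lo))
    stop("ambiguous edge: values are not monotone within the fit window")
  fit <- stats::lm.fit(cbind(1, t[idx]), vv)
  slope <- fit$coefficients[2]; intercept <- fit$coefficients[1]
  if ((edge == "rising" && slope <= 0) || (edge == "falling" && slope >= 0))
    stop("edge fit slope has the wrong sign for a ", edge, " edge")
  structure(list(slope = unname(slope), intercept = unname(intercept),
                 fit_window = idx, edge = edge,
                 t_ref = unname(-intercept / slope)),
            class = "edge_fit")
}

#' @export
print.edge_fit <- function(x, ...) {
  cat(sprintf("<edge_fit> %s edge, slope %.4g /ps, t_ref %.2f ps (%d samples)\n",
              x$edge, x$slope, x$t_ref, length(x$fit_window)))
  invisible(x)
}

#' Time-correct a fluorescence profile to a reference reflectance edge
#'
#' Setup changes (working distance, sample surface) shift both modalities
#' identically; the reflectance rising edge serves as time reference.
#' The fluorescence profile is shifted by
#' `dt_shift = refl_ref$t_ref - refl_new$t_ref` so profiles from different
#' acquisitions become comparable. Sub-sample shifts use linear
#' interpolation.
#'
#' @param fluo Fluorescence [time_profile()].
#' @param refl_ref Reference acquisition's reflectance [fit_edge()].
#' @param refl_new Current acquisition's reflectance [fit_edge()].
#' @return Shifted `time_profile`; the applied shift is recorded in its
#'   provenance.
#' @export
align_to_reference <- function(fluo, refl_ref, refl_new) {
  stopifnot(inherits(fluo, "time_profile"),
            inherits(refl_ref, "edge_fit"), inherits(refl_new, "edge_fit"))
  dt_shift <- refl_ref$t_ref - refl_new$t_ref
  if (abs(dt_shift) > 0.25 * axis_span(fluo$axis))
    stop(sprintf("implausible time correction (%.0f ps > 25%% of the axis span)",
                 dt_shift))
  shift_profile(fluo, dt_shift)
}

#' Threshold-crossing time of a normalized profile
#'
#' Finds the time at which the profile crosses `level`, by linear
#' interpolation between the two bracketing samples: the first up-crossing
#' for the rising edge, the last down-crossing for the falling edge. The
#' 2% falling-edge crossing of a normalized reflectance profile is the
#' fast scattering surrogate used for calibration.
#'
#' @param tp A normalized [time_profile()].
#' @param level Threshold as a fraction of the normalized pulse, in (0, 1).
#'   Default 0.02.
#' @param edge `"rising"` or `"falling"`.
#' @return Crossing time in ps (absolute axis time).
#' @export
threshold_time <- function(tp, level = 0.02, edge = c("rising", "falling")) {
  stopifnot(inherits(tp, "time_profile"))
  edge <- match.arg(edge)
  if (!tp$normalized) stop("`tp` must be normalized (see normalize_profile)")
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  v <- tp$values; t <- axis_times(tp$axis); n <- length(v)
  if (edge == "rising") {
    i <- which(v[-1] >= level & v[-n] < level)[1]
    if (is.na(i)) stop("no rising crossing at level ", level)
  } else {
    cand <- which(v[-n] >= level & v[-1] < level)
    if (!length(cand)) stop("no falling crossing at level ", level)
    i <- max(cand)
  }
  t[i] + (level - v[i]) / (v[i + 1] - v[i]) * tp$axis$dt
}

#' Relative reflectance timing at a threshold
#'
#' Aligns each normalized reflectance profile to the first profile on the
#' chosen alignment edge (linear edge fit, then time shift) and reports
#' the threshold-crossing time of each aligned profile relative to the
#' reference profile's crossing. The default aligns on the rising edge
#' (the fitted rising edge is the acquisition's time reference) and
#' compares at 2% of the normalized pulse on the falling tail, where
#' scattering-induced broadening accumulates; this keeps the timing
#' feature close to linear in the scattering level. Falling-edge
#' alignment is available for pulses whose rising edge is corrupted
#' (e.g. by specular reflections).
#'
#' @param profiles List of normalized reflectance [time_profile()]s; the
#'   first is the reference (its `delta_refl` is 0 by construction).
#' @param level Comparison threshold (fraction). Default 0.02.
#' @param compare_edge Edge for the threshold comparison. Default
#'   `"falling"`.
#' @param align_edge Edge used for alignment. Default `"rising"`.
#' @param align_lo,align_hi Normalized window for the alignment edge fit.
#' @return Numeric vector `delta_refl` (ps), one per profile; first is 0.
#' @export
measure_delta_refl <- function(profiles, level = 0.02,
                               compare_edge = "falling",
                               align_edge = "rising",
                               align_lo = 0.2, align_hi = 0.8) {
  stopifnot(is.list(profiles), length(profiles) >= 1)
  ref_fit <- fit_edge(profiles[[1]], edge = align_edge,
                      level_lo = align_lo, level_hi = align_hi)
  t0 <- threshold_time(profiles[[1]], level = level, edge = compare_edge)
  vapply(profiles, function(p) {
    f <- fit_edge(p, edge = align_edge, level_lo = align_lo,
                  level_hi = align_hi)
    aligned <- align_to_reference(p, ref_fit, f)
    threshold_time(aligned, level = level, edge = compare_edge) - t0
  }, numeric(1))
}
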