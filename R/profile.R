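#' Temporal profile (counts versus gate delay)
#'
#' A time profile (TP) is the basic 1D signal of the pipeline: photon counts
#' as a function of gate delay for one pixel or one spatially averaged
#' region of interest.
#'
#' @param values Numeric vector, one value per gate position. Raw counts or,
#'   after [normalize_profile()], dimensionless values in roughly `[0, 1]`.
#' @param axis The [gate_axis()] the values are sampled on.
#' @param modality One of `"fluorescence"`, `"reflectance"`, `"irf"`,
#'   `"darkfield"`.
#' @param normalized Logical flag; set by [normalize_profile()].
#' @param roi Optional record of the source region `(row0, col0, height,
#'   width)`, 0-based.
#' @param provenance Optional free-text / list provenance record.
#' @return An object of class `time_profile`.
#' @export
time_profile <- function(values, axis, modality = "fluorescence",
                         normalized = FALSE, roi = NULL, provenance = NULL) {
  stopifnot(inherits(axis, "gate_axis"))
  values <- as.numeric(values)
  if (length(values) != axis$n_steps)
    stop(sprintf("profile length (%d) must equal axis$n_steps (%d)",
                 length(values), axis$n_steps))
  if (anyNA(values)) stop("profile values must not contain NA")
  modality <- match.arg(modality,
                        c("fluorescence", "reflectance", "irf", "darkfield"))
  structure(list(values = values, axis = axis, modality = modality,
                 normalized = isTRUE(normalized), roi = roi,
                 provenance = provenance),
            class = "time_profile")
}

#' @export
print.time_profile <- function(x, ...) {
  cat(sprintf("<time_profile> %s, %d steps, %s, range [%.4g, %.4g]\n",
              x$modality, x$axis$n_steps,
              if (x$normalized) "normalized" else "raw counts",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.time_profile <- function(x, ..., xlab = "time (ps)",
                              ylab = if (x$normalized) "normalized intensity"
                                     else "counts") {
  graphics::plot(axis_times(x$axis), x$values, type = "l",
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @export
as.data.frame.time_profile <- function(x, ...) {
  data.frame(time_ps = axis_times(x$axis), value = x$values)
}

#' Write a profile as two-column CSV (time_ps, value)
#'
#' @param tp A [time_profile()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(tp, path) {
  stopifnot(inherits(tp, "time_profile"))
  utils::write.csv(as.data.frame(tp), path, row.names = FALSE)
  invisible(path)
}

#' Normalize a temporal profile to its pulse maximum and tail baseline
#'
#' Maps a profile to `[0, 1]` using robust estimates of the pulse maximum
#' and the background level: the maximum estimate `M` is the mean of the
#' `n_top` largest values and the minimum estimate `m` is the mean of the
#' last `n_tail` values (the late tail, where no signal remains). The
#' normalized profile is `(v - m) / (M - m)`.
#'
#' @param tp A [time_profile()].
#' @param n_top Number of most intense samples averaged for the maximum
#'   estimate. Default 200. Ties are broken in favour of earlier samples.
#' @param n_tail Number of trailing samples averaged for the baseline.
#'   Default 200.
#' @return A normalized `time_profile`.
#' @export
normalize_profile <- function(tp, n_top = 200, n_tail = 200) {
  stopifnot(inherits(tp, "time_profile"))
  n <- length(tp$values)
  n_top <- as.integer(n_top); n_tail <- as.integer(n_tail)
  if (n_top < 1 || n_tail < 1 || n_top > n || n_tail > n)
    stop("`n_top` and `n_tail` must be in [1, profile length]")
  v <- tp$values
  # largest n_top values, ties broken by earlier index (stable order())
  M <- mean(v[order(-v)[seq_len(n_top)]])
  m <- mean(v[(n - n_tail + 1):n])
  if (M <= m)
    stop("no usable pulse: maximum estimate <= tail baseline (flat or inverted profile)")
  out <- tp
  out$values <- (v - m) / (M - m)
  out$normalized <- TRUE
  out
}

#' Moving-average smoothing of a profile
#'
#' Centered moving average with an odd window. Near the edges the window
#' shrinks symmetrically instead of zero-padding, so the pulse tails used
#' for normalization are not biased towards zero.
#'
#' @param tp A [time_profile()].
#' @param window Odd window length in samples. Default 35 (625 ps at the
#'   default 17.857 ps gate step).
#' @return Smoothed `time_profile`.
#' @export
smooth_profile <- function(tp, window = 35) {
  stopifnot(inherits(tp, "time_profile"))
  window <- as.integer(window)
  n <- length(tp$values)
  if (window < 1 || window > n) stop("`window` must be in [1, profile length]")
  if (window %% 2L == 0L) stop("`window` must be odd")
  if (window == 1L) return(tp)
  h <- window %/% 2L
  cs <- c(0, cumsum(tp$values))
  i <- seq_len(n)
  # symmetric shrinking half-width at the edges
  hw <- pmin(h, i - 1L, n - i)
  lo <- i - hw; hi <- i + hw
  out <- tp
  out$values <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out
}

#' Shift a profile in time by linear interpolation
#'
#' `shift_profile(tp, dt_shift)` returns the profile delayed by `dt_shift`
#' ps: the output at time `t` equals the input at `t - dt_shift`. Values
#' requested beyond the recorded window are held at the edge value.
#'
#' @param tp A [time_profile()].
#' @param dt_shift Shift in ps (positive delays the pulse).
#' @return Shifted `time_profile`.
#' @export
shift_profile <- function(tp, dt_shift) {
  stopifnot(inherits(tp, "time_profile"), is.finite(dt_shift))
  if (dt_shift == 0) return(tp)
  t <- axis_times(tp$axis)
  out <- tp
  out$values <- stats::approx(t, tp$values, xout = t - dt_shift,
                              rule = 2)$y
  out$provenance <- c(tp$provenance, list(time_shift_ps = dt_shift))
  out
}
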