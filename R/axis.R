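#' Gate-time axis of a time-gated acquisition
#'
#' Describes the temporal sampling of a gated single-photon time scan: the
#' gate offset from the laser sync pulse, the delay increment between
#' consecutive gate positions, the number of gate positions, and the
#' acquisition gate width. The instrument samples photon arrival on this
#' grid; all profile and model computations in the package are discrete at
#' resolution `dt`.
#'
#' @param t0 Gate offset from the sync pulse, in ps.
#' @param dt Gate step (delay between subsequent gate positions), in ps.
#'   Default 17.857 ps.
#' @param n_steps Number of gate positions. Default 1400, which with the
#'   default step spans a 25 ns window.
#' @param gate_width Acquisition gate width, in ns. Default 10.8 ns.
#'   Metadata only; it does not enter the discrete model.
#' @return An object of class `gate_axis`.
#' @examples
#' ax <- gate_axis()
#' axis_span(ax) / 1000  # ~25 ns
#' @export
gate_axis <- function(t0 = 0, dt = 17.857, n_steps = 1400, gate_width = 10.8) {
  stopifnot(is.numeric(t0), length(t0) == 1L, is.finite(t0))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("gate step `dt` must be a single positive number (ps)")
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 2)
    stop("`n_steps` must be >= 2")
  n_steps <- as.integer(n_steps)
  if (!is.numeric(gate_width) || gate_width <= 0)
    stop("`gate_width` must be positive (ns)")
  structure(list(t0 = t0, dt = dt, n_steps = n_steps,
                 gate_width = gate_width),
            class = "gate_axis")
}

#' @export
print.gate_axis <- function(x, ...) {
  cat(sprintf("<gate_axis> %d steps of %.3f ps (span %.3f ns), t0 = %.1f ps, gate %.1f ns\n",
              x$n_steps, x$dt, axis_span(x) / 1000, x$t0, x$gate_width))
  invisible(x)
}

#' Sample times of a gate axis
#'
#' @param axis A [gate_axis()].
#' @return Numeric vector of gate-position times in ps, `t0 + (0:(n-1)) * dt`.
#' @export
axis_times <- function(axis) {
  stopifnot(inherits(axis, "gate_axis"))
  axis$t0 + (seq_len(axis$n_steps) - 1) * axis$dt
}

#' Total temporal span of a gate axis (ps)
#'
#' @param axis A [gate_axis()].
#' @return `dt * n_steps`, in ps.
#' @export
axis_span <- function(axis) {
  stopifnot(inherits(axis, "gate_axis"))
  axis$dt * axis$n_steps
}

same_axis <- function(a, b, tol = 1e-9) {
  a$n_steps == b$n_steps &&
    abs(a$dt - b$dt) <= tol * max(1, abs(a$dt)) &&
    abs(a$t0 - b$t0) <= tol * max(1, abs(a$t0))
}
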