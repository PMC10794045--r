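#' Evaluate the convolution model for arbitrary parameters
#'
#' The analytical profile model: the measured IRF convolved with a
#' unit-area Gaussian medium transfer function (mean `delta_tissue`, sd
#' `sigma`), scaled by `A`, and — for fluorescence — further convolved
#' with the causal mono-exponential decay `exp(-t/tau)`. Shares its
#' implementation with [forward_profile()]; with `tau = NULL` it is the
#' reflectance model.
#'
#' @param irf A `time_profile` on a valid axis.
#' @param A Amplitude.
#' @param delta_tissue Gaussian mean (relative TOF), ps.
#' @param sigma Gaussian sd, ps.
#' @param tau Fluorescence lifetime in ns, or `NULL` for reflectance.
#' @return A `time_profile` of model values on the IRF's axis.
#' @export
model_profile <- function(irf, A, delta_tissue, sigma, tau = NULL) {
  fl <- if (is.null(tau)) NULL else fluorophore(tau = tau)
  forward_profile(irf, medium_transfer(A, delta_tissue, sigma), fl)
}

#' Coefficient of determination of a model profile
#'
#' `1 - SS_res / SS_tot` of `model` against `tp`.
#'
#' @param tp Observed [time_profile()] (or numeric vector).
#' @param model Model `time_profile` (or numeric vector) of equal length.
#' @return R-squared (dimensionless, `<= 1`).
#' @export
goodness_of_fit <- function(tp, model) {
  y <- if (inherits(tp, "time_profile")) tp$values else as.numeric(tp)
  f <- if (inherits(model, "time_profile")) model$values else as.numeric(model)
  if (length(y) != length(f)) stop("profile and model lengths differ")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("zero total sum of squares: constant profile")
  1 - sum((y - f)^2) / sst
}

fwhm_samples <- function(v) {
  base <- min(v); pk <- max(v)
  sum(v > base + (pk - base) / 2)
}

# Initial values: delta from the lag of peak cross-correlation with the
# IRF, sigma from the excess FWHM over the IRF's, A from the area ratio.
init_tof_fit <- function(y, irf_v, dt, tau_ps = NULL) {
  n <- length(y)
  cc <- stats::convolve(y, irf_v, type = "open")  # lag k at index n - 1 + ... cross-corr
  lag <- (which.max(cc) - n) * dt
  delta0 <- lag
  if (!is.null(tau_ps)) delta0 <- delta0 - tau_ps  # decay drags the c.o.m. right
  f_tp <- fwhm_samples(y) * dt
  f_irf <- fwhm_samples(irf_v) * dt
  extra <- if (!is.null(tau_ps)) tau_ps * 1.5 else 0
  sigma0 <- sqrt(max(f_tp^2 - f_irf^2 - extra^2, dt^2)) / 2.355
  A0 <- sum(pmax(y, 0)) / max(sum(irf_v), .Machine$double.eps)
  c(A = max(A0, 1e-6), delta = delta0, sigma = max(sigma0, dt))
}

tof_fit_engine <- function(tp, irf, tau = NULL, init = NULL, raw = FALSE,
                           maxit = 500) {
  stopifnot(inherits(tp, "time_profile"), inherits(irf, "time_profile"))
  if (!same_axis(tp$axis, irf$axis))
    stop("profile and IRF must share the same gate axis")
  if (!raw && !tp$normalized)
    stop("`tp` must be normalized (pass raw = TRUE to fit raw counts)")
  ax <- tp$axis; dt <- ax$dt; span <- axis_span(ax)
  y <- tp$values
  tau_ps <- if (is.null(tau)) NULL else tau * 1000
  # baseline-correct the IRF by its late-tail mean (dark counts): the
  # convolution model describes the pulse, not the constant dark floor
  n_tail <- default_norm_window(ax$n_steps)
  base <- mean(utils::tail(irf$values, n_tail))
  if (base > 0) irf$values <- pmax(irf$values - base, 0)
  if (max(irf$values) <= 0) stop("IRF profile carries no pulse above its baseline")
  if (is.null(init)) init <- init_tof_fit(y, irf$values, dt, tau_ps)
  lower <- c(1e-9, -span / 4, dt / 2)
  upper <- c(Inf, span, span / 4)
  init <- pmin(pmax(unname(init), lower), upper)

  cache <- conv_cache(irf$values)
  resid_fn <- function(p)
    p[1] * conv_padded(irf$values, dt, p[2], p[3], tau_ps, cache = cache) - y
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-8, ptol = 1e-8,
                                     maxiter = maxit)
  ans <- try(minpack.lm::nls.lm(par = init, lower = lower, upper = upper,
                                fn = resid_fn, control = ctrl),
             silent = TRUE)
  if (inherits(ans, "try-error")) {
    par <- rep(NA_real_, 3); converged <- FALSE; niter <- 0L
    rnorm_ <- NA_real_; diag_msg <- as.character(ans)
  } else {
    par <- ans$par
    converged <- ans$info %in% 1:4 && all(is.finite(par))
    niter <- ans$niter
    rnorm_ <- sqrt(ans$deviance)
    diag_msg <- ans$message
  }
  fitted_v <- if (all(is.finite(par)))
    par[1] * conv_padded(irf$values, dt, par[2], par[3], tau_ps)
  else rep(NA_real_, length(y))
  r2 <- if (all(is.finite(fitted_v))) goodness_of_fit(y, fitted_v) else NA_real_

  structure(list(
    coefficients = c(A = par[1], delta_tissue = par[2], sigma = par[3]),
    tau_used = if (is.null(tau)) NA_real_ else tau,
    modality = if (is.null(tau)) "reflectance" else "fluorescence",
    r_squared = r2,
    converged = converged,
    reliable = isTRUE(converged) && isTRUE(r2 >= 0.5),
    n_iterations = niter,
    residual_norm = rnorm_,
    message = diag_msg,
    fitted = fitted_v,
    data = tp, irf = irf), class = "tof_fit")
}

#' Fit the reflectance convolution model to a temporal profile
#'
#' Bounded nonlinear least squares for the three parameters `A`,
#' `delta_tissue` and `sigma` of the Gaussian medium transfer function
#' convolved with the IRF. Bounds: `A > 0`, `sigma` in
#' `[dt/2, span/4]`, `delta_tissue` within the axis. Non-convergence is
#' reported via `converged = FALSE` with diagnostics, never silent `NA`s.
#'
#' @param tp Normalized [time_profile()] (or raw counts with
#'   `raw = TRUE`).
#' @param irf `time_profile` on the same axis (the matching IRF region).
#' @param init Optional named start values `c(A, delta, sigma)`; by
#'   default from IRF cross-correlation, excess FWHM and area ratio.
#' @param raw Fit raw counts instead of requiring a normalized profile.
#' @return A `tof_fit` object; see [coef.tof_fit()], [predict.tof_fit()].
#' @export
fit_reflectance <- function(tp, irf, init = NULL, raw = FALSE) {
  tof_fit_engine(tp, irf, tau = NULL, init = init, raw = raw)
}

#' Fit the fluorescence convolution model to a temporal profile
#'
#' As [fit_reflectance()], with the model additionally convolved with the
#' causal mono-exponential fluorescence decay. The lifetime `tau` is a
#' fixed input measured externally — never a free parameter.
#'
#' @inheritParams fit_reflectance
#' @param tau Fluorescence lifetime in ns. Default 0.7.
#' @return A `tof_fit` object.
#' @export
fit_fluorescence <- function(tp, irf, tau = 0.7, init = NULL, raw = FALSE) {
  if (!is.numeric(tau) || tau <= 0) stop("`tau` must be > 0 (ns)")
  tof_fit_engine(tp, irf, tau = tau, init = init, raw = raw)
}

#' @export
print.tof_fit <- function(x, ...) {
  cat(sprintf("<tof_fit> %s model%s\n", x$modality,
              if (!is.na(x$tau_used)) sprintf(" (tau = %.3g ns, fixed)", x$tau_used) else ""))
  cat(sprintf("  A = %.4g, delta_tissue = %.2f ps, sigma = %.2f ps\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3]))
  cat(sprintf("  R^2 = %.4f, %s (%d iterations)\n", x$r_squared,
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' @export
summary.tof_fit <- function(object, ...) {
  out <- c(as.list(object$coefficients),
           list(tau_ns = object$tau_used, modality = object$modality,
                r_squared = object$r_squared, converged = object$converged,
                reliable = object$reliable,
                n_iterations = object$n_iterations,
                residual_norm = object$residual_norm))
  class(out) <- "summary.tof_fit"
  out
}

#' @export
print.summary.tof_fit <- function(x, ...) {
  cat(sprintf("Convolution-model fit (%s)\n", x$modality))
  cat(sprintf("  A            %.6g\n  delta_tissue %.6g ps\n  sigma        %.6g ps\n",
              x$A, x$delta_tissue, x$sigma))
  if (!is.na(x$tau_ns)) cat(sprintf("  tau (fixed)  %.6g ns\n", x$tau_ns))
  cat(sprintf("  R^2 = %.5f; converged = %s; reliable = %s; iter = %d\n",
              x$r_squared, x$converged, x$reliable, x$n_iterations))
  invisible(x)
}

#' @export
coef.tof_fit <- function(object, ...) object$coefficients

#' Model profile at the fitted (or supplied) parameters
#'
#' @param object A `tof_fit`.
#' @param newdata Optional named list/vector overriding any of `A`,
#'   `delta_tissue`, `sigma`.
#' @param ... Unused.
#' @return A `time_profile` of model values.
#' @export
predict.tof_fit <- function(object, newdata = NULL, ...) {
  p <- object$coefficients
  if (!is.null(newdata)) {
    nd <- as.list(newdata)
    for (nm in intersect(names(nd), c("A", "delta_tissue", "sigma")))
      p[nm] <- nd[[nm]]
  }
  model_profile(object$irf, p["A"], p["delta_tissue"], p["sigma"],
                tau = if (is.na(object$tau_used)) NULL else object$tau_used)
}

#' @export
residuals.tof_fit <- function(object, ...) object$data$values - object$fitted

#' @export
fitted.tof_fit <- function(object, ...) object$fitted

#' @export
plot.tof_fit <- function(x, ...) {
  t <- axis_times(x$data$axis)
  graphics::plot(t, x$data$values, type = "p", pch = 16, cex = 0.4,
                 col = "grey40", xlab = "time (ps)",
                 ylab = if (x$data$normalized) "normalized intensity" else "counts",
                 ...)
  graphics::lines(t, x$fitted, col = "red3", lwd = 2)
  graphics::legend("topright", c("data", "model"), col = c("grey40", "red3"),
                   lty = c(NA, 1), pch = c(16, NA), bty = "n")
  invisible(x)
}

#' One-row data frame serialization of a fit
#'
#' @param x A `tof_fit`.
#' @param ... Unused.
#' @return A one-row `data.frame` suitable for CSV export.
#' @export
as.data.frame.tof_fit <- function(x, ...) {
  data.frame(modality = x$modality, A = unname(x$coefficients[1]),
             delta_tissue_ps = unname(x$coefficients[2]),
             sigma_ps = unname(x$coefficients[3]),
             tau_ns = x$tau_used, r_squared = x$r_squared,
             converged = x$converged, n_iterations = x$n_iterations,
             residual_norm = x$residual_norm)
}
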