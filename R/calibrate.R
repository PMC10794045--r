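#' Bulk optical properties of a turbid medium
#'
#' @param mu_a Absorption coefficient (1/mm).
#' @param mu_s_prime Reduced scattering coefficient (1/mm).
#' @param wavelength Wavelength in nm (metadata). Default 659 nm, the
#'   compromise between the excitation (635 nm) and emission (~680 nm)
#'   bands.
#' @return An object of class `optical_properties` with the derived
#'   effective attenuation `mu_eff`.
#' @export
optical_properties <- function(mu_a, mu_s_prime, wavelength = 659) {
  if (mu_a < 0) stop("`mu_a` must be >= 0")
  if (mu_s_prime <= 0) stop("`mu_s_prime` must be > 0")
  structure(list(mu_a = mu_a, mu_s_prime = mu_s_prime,
                 wavelength = wavelength,
                 mu_eff = mu_eff(mu_a, mu_s_prime)),
            class = "optical_properties")
}

#' Effective attenuation coefficient (diffusion approximation)
#'
#' `mu_eff = sqrt(3 * mu_a * (mu_a + mu_s'))`, governing the exponential
#' depth attenuation of diffuse light.
#'
#' @param mu_a Absorption coefficient (1/mm), or an
#'   [optical_properties()] object.
#' @param mu_s_prime Reduced scattering coefficient (1/mm); ignored when
#'   `mu_a` is an `optical_properties` object.
#' @return Effective attenuation in 1/mm.
#' @export
mu_eff <- function(mu_a, mu_s_prime = NULL) {
  if (inherits(mu_a, "optical_properties")) {
    mu_s_prime <- mu_a$mu_s_prime; mu_a <- mu_a$mu_a
  }
  if (any(mu_a < 0) || any(mu_s_prime < 0))
    stop("optical properties must be non-negative")
  sqrt(3 * mu_a * (mu_a + mu_s_prime))
}

#' Ordinary least-squares line fit
#'
#' All relations of the calibration chain are stated linear; this is the
#' shared primitive (ordinary least squares via `lm`).
#'
#' @param x,y Numeric vectors, `length >= 2` with at least 2 distinct `x`.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
fit_linear <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` lengths differ")
  if (length(unique(x)) < 2) stop("degenerate x: need >= 2 distinct values")
  fit <- stats::lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2)
}

#' Build the linear depth-calibration chain
#'
#' From per-concentration depth series and a medium-feature series, fits
#' the chain of linear relations that enables depth inversion:
#' per-IL `delta_tissue = k_fluo * depth + c_fluo`; `k_fluo = k_corr * IL
#' + c_corr`; and the branch relation `delta_refl = k_refl * IL + c_refl`
#' (reflectance branch) or `mu_s' = k_sfdi * IL + c_sfdi` (SFDI branch).
#' `c_fluo` — in theory a constant of the setup geometry — is estimated
#' as the mean intercept of the per-IL depth regressions.
#'
#' IL (Intralipid concentration, %) is the chain's internal pivot
#' variable; for media that are not Intralipid it acts as a latent
#' scattering index and never needs to be physically meaningful on its
#' own.
#'
#' @param depth_series `data.frame` with columns `il_percent`, `depth_mm`,
#'   `delta_tissue_ps`; at least 2 IL levels with at least 2 depths each.
#' @param medium_series `data.frame` with columns `il_percent` and either
#'   `delta_refl_ps` (reflectance branch) or `mu_s_prime_per_mm` (SFDI
#'   branch).
#' @param branch `"reflectance"` or `"sfdi"`.
#' @param depth_range Depths (mm) retained for the calibration fits;
#'   default `c(1, 5)` — the shallowest millimetre is excluded because
#'   its geometry is not controlled reliably, and 5 mm is the sensing
#'   limit. Also the validity span for later inversion.
#' @return An object of class `tof_calibration`.
#' @export
build_chain <- function(depth_series, medium_series,
                        branch = c("reflectance", "sfdi"),
                        depth_range = c(1, 5)) {
  branch <- match.arg(branch)
  need <- c("il_percent", "depth_mm", "delta_tissue_ps")
  if (!all(need %in% names(depth_series)))
    stop("`depth_series` must have columns ", paste(need, collapse = ", "))
  feature_col <- if (branch == "reflectance") "delta_refl_ps"
                 else "mu_s_prime_per_mm"
  if (!all(c("il_percent", feature_col) %in% names(medium_series)))
    stop(sprintf("`medium_series` must have columns il_percent and %s for the %s branch",
                 feature_col, branch))
  ds <- depth_series[depth_series$depth_mm >= depth_range[1] &
                     depth_series$depth_mm <= depth_range[2], ]
  ils <- sort(unique(ds$il_percent))
  if (length(ils) < 2)
    stop("insufficient calibration data: need >= 2 IL levels (have ",
         length(ils), ")")
  per_il <- lapply(ils, function(il) {
    sub <- ds[ds$il_percent == il, ]
    if (length(unique(sub$depth_mm)) < 2)
      stop(sprintf("insufficient depths for IL = %g%%: need >= 2 in the depth range [%g, %g] mm",
                   il, depth_range[1], depth_range[2]))
    fit_linear(sub$depth_mm, sub$delta_tissue_ps)
  })
  k_fluo <- vapply(per_il, `[[`, numeric(1), "slope")
  c_fluo <- mean(vapply(per_il, `[[`, numeric(1), "intercept"))
  corr <- fit_linear(ils, k_fluo)
  med <- fit_linear(medium_series$il_percent, medium_series[[feature_col]])

  chain <- list(branch = branch,
                k_corr = corr$slope, c_corr = corr$intercept,
                c_fluo = c_fluo,
                k_fluo_table = data.frame(il_percent = ils, k_fluo = k_fluo),
                depth_range = depth_range,
                diagnostics = list(
                  r_squared_corr = corr$r_squared,
                  r_squared_medium = med$r_squared,
                  r_squared_per_il = vapply(per_il, `[[`, numeric(1),
                                            "r_squared")))
  if (branch == "reflectance") {
    chain$k_refl <- med$slope; chain$c_refl <- med$intercept
  } else {
    chain$k_sfdi <- med$slope; chain$c_sfdi <- med$intercept
  }
  structure(chain, class = "tof_calibration")
}

#' @export
print.tof_calibration <- function(x, ...) {
  cat(sprintf("<tof_calibration> %s branch, valid depths %g-%g mm\n",
              x$branch, x$depth_range[1], x$depth_range[2]))
  cat(sprintf("  k_corr = %.4g ps/mm per IL%%, c_corr = %.4g ps/mm, c_fluo = %.4g ps\n",
              x$k_corr, x$c_corr, x$c_fluo))
  if (x$branch == "reflectance")
    cat(sprintf("  k_refl = %.4g ps per IL%%, c_refl = %.4g ps (R^2 = %.4f)\n",
                x$k_refl, x$c_refl, x$diagnostics$r_squared_medium))
  else
    cat(sprintf("  k_sfdi = %.4g /mm per IL%%, c_sfdi = %.4g /mm (R^2 = %.4f)\n",
                x$k_sfdi, x$c_sfdi, x$diagnostics$r_squared_medium))
  cat(sprintf("  per-IL k_fluo: %s\n",
              paste(sprintf("%.3g", x$k_fluo_table$k_fluo), collapse = ", ")))
  invisible(x)
}

#' @export
coef.tof_calibration <- function(object, ...) {
  out <- c(k_corr = object$k_corr, c_corr = object$c_corr,
           c_fluo = object$c_fluo)
  if (object$branch == "reflectance")
    c(out, k_refl = object$k_refl, c_refl = object$c_refl)
  else
    c(out, k_sfdi = object$k_sfdi, c_sfdi = object$c_sfdi)
}

#' Invert relative TOF to inclusion depth
#'
#' Applies the calibration chain: the medium feature (relative
#' reflectance timing, or SFDI-derived reduced scattering) is converted
#' to the latent scattering index `IL`, the TOF-depth slope is
#' reconstructed as `k_corr * IL + c_corr`, and depth is
#' `(delta_tissue - c_fluo) / slope`. Estimates with a non-positive
#' reconstructed slope are flagged invalid (never an exception), and
#' depths outside the calibrated span are flagged as extrapolation.
#'
#' @param delta_tissue Fitted relative TOF(s), ps.
#' @param medium_feature `delta_refl` (ps, reflectance branch) or
#'   `mu_s_prime` (1/mm, SFDI branch); scalar or vector recycled against
#'   `delta_tissue`.
#' @param chain A [build_chain()] calibration.
#' @return A `data.frame` with columns `depth_mm`, `delta_tissue_ps`,
#'   `medium_feature`, `il_inferred`, `valid`, `extrapolated`, `reason`.
#' @export
depth_from_tof <- function(delta_tissue, medium_feature, chain) {
  stopifnot(inherits(chain, "tof_calibration"))
  n <- max(length(delta_tissue), length(medium_feature))
  delta_tissue <- rep_len(as.numeric(delta_tissue), n)
  medium_feature <- rep_len(as.numeric(medium_feature), n)
  il <- if (chain$branch == "reflectance")
    (medium_feature - chain$c_refl) / chain$k_refl
  else
    (medium_feature - chain$c_sfdi) / chain$k_sfdi
  slope <- chain$k_corr * il + chain$c_corr
  valid <- is.finite(slope) & slope > 0
  depth <- ifelse(valid, (delta_tissue - chain$c_fluo) / slope, NA_real_)
  extrap <- valid & (depth < chain$depth_range[1] |
                     depth > chain$depth_range[2])
  reason <- rep("", n)
  reason[!valid] <- "non-positive calibrated slope (medium feature outside calibrated range)"
  reason[extrap] <- "depth outside calibrated span"
  data.frame(depth_mm = depth, delta_tissue_ps = delta_tissue,
             medium_feature = medium_feature, il_inferred = il,
             valid = valid, extrapolated = extrap, reason = reason,
             stringsAsFactors = FALSE)
}

#' @export
predict.tof_calibration <- function(object, newdata, ...) {
  feature_col <- if (object$branch == "reflectance") "delta_refl_ps"
                 else "mu_s_prime_per_mm"
  if (!all(c("delta_tissue_ps", feature_col) %in% names(newdata)))
    stop("`newdata` must have columns delta_tissue_ps and ", feature_col)
  depth_from_tof(newdata$delta_tissue_ps, newdata[[feature_col]], object)
}

#' Correct a surface intensity for depth attenuation
#'
#' Inverts the exponential depth attenuation of diffuse light,
#' `I = L * exp(-2 * mu_eff * z)`, recovering the luminance `L` emitted at
#' depth `z` from the measured surface intensity `I`. The factor 2 is the
#' round-trip path; the alternative typographic reading
#' `exp(-mu_eff^2 * z)` is selectable.
#'
#' @param I_surface Measured surface intensity (counts).
#' @param z Depth in mm (`>= 0`).
#' @param props An [optical_properties()] object (or a `mu_eff` value via
#'   `mu_eff_value`).
#' @param convention `"round-trip"` (`exp(-2 mu_eff z)`, default) or
#'   `"squared"` (`exp(-mu_eff^2 z)`).
#' @param mu_eff_value Effective attenuation (1/mm), overriding `props`.
#' @return Corrected luminance, same shape as `I_surface`.
#' @export
correct_intensity <- function(I_surface, z, props = NULL,
                              convention = c("round-trip", "squared"),
                              mu_eff_value = NULL) {
  convention <- match.arg(convention)
  if (any(z < 0)) stop("`z` must be >= 0 (mm)")
  me <- if (!is.null(mu_eff_value)) mu_eff_value else mu_eff(props)
  expo <- if (convention == "round-trip") 2 * me * z else me^2 * z
  I_surface * exp(expo)
}

#' Forward depth attenuation of a luminance (inverse of
#' [correct_intensity()])
#'
#' @inheritParams correct_intensity
#' @param L Luminance at depth.
#' @return Surface intensity.
#' @export
attenuate_intensity <- function(L, z, props = NULL,
                                convention = c("round-trip", "squared"),
                                mu_eff_value = NULL) {
  convention <- match.arg(convention)
  if (any(z < 0)) stop("`z` must be >= 0 (mm)")
  me <- if (!is.null(mu_eff_value)) mu_eff_value else mu_eff(props)
  expo <- if (convention == "round-trip") 2 * me * z else me^2 * z
  L * exp(-expo)
}

# ---- serialization ---------------------------------------------------------

#' Write / read a calibration chain as JSON
#'
#' @param chain A `tof_calibration`.
#' @param path JSON file path.
#' @return `path` (write) or the `tof_calibration` (read).
#' @export
write_chain <- function(chain, path) {
  stopifnot(inherits(chain, "tof_calibration"))
  jsonlite::write_json(unclass(chain), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$k_fluo_table <- as.data.frame(obj$k_fluo_table)
  structure(obj, class = "tof_calibration")
}
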