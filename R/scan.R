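#' Time-scan stack (rows x cols x gate steps)
#'
#' @param counts Non-negative numeric array `rows x cols x n_steps`.
#'   Integer-valued for raw acquisitions; real-valued allowed after
#'   averaging (tracked by the `averaged` flag).
#' @param axis A [gate_axis()]; its `n_steps` must match `dim(counts)[3]`.
#' @param modality One of `"fluorescence"`, `"reflectance"`, `"irf"`,
#'   `"darkfield"`.
#' @param provenance Free-form source record (list or character).
#' @param averaged Logical: values are means over replicate scans.
#' @return An object of class `time_scan`.
#' @export
time_scan <- function(counts, axis, modality = "fluorescence",
                      provenance = NULL, averaged = FALSE) {
  stopifnot(inherits(axis, "gate_axis"))
  if (length(dim(counts)) != 3L)
    stop("`counts` must be a 3D array (rows x cols x gate steps)")
  if (dim(counts)[3] != axis$n_steps)
    stop(sprintf("third dimension of counts (%d) must equal axis$n_steps (%d)",
                 dim(counts)[3], axis$n_steps))
  if (any(counts < 0)) stop("counts must be >= 0")
  modality <- match.arg(modality,
                        c("fluorescence", "reflectance", "irf", "darkfield"))
  structure(list(counts = counts, axis = axis, modality = modality,
                 provenance = provenance, averaged = isTRUE(averaged)),
            class = "time_scan")
}

#' @export
print.time_scan <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<time_scan> %s, %d x %d px x %d steps (dt %.3f ps)%s\n",
              x$modality, d[1], d[2], d[3], x$axis$dt,
              if (x$averaged) ", averaged" else ""))
  invisible(x)
}

#' @export
dim.time_scan <- function(x) dim(x$counts)

# ---- I/O -------------------------------------------------------------------

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

required_meta <- c("t0_ps", "dt_ps", "n_steps", "gate_width_ns", "modality")

#' Write a time scan to disk
#'
#' The supported interchange format is a multi-page TIFF (one 16-bit
#' unsigned page per gate step) with a JSON metadata sidecar
#' (`<stem>.json`) carrying `t0_ps`, `dt_ps`, `n_steps`, `gate_width_ns`,
#' `modality`, and — for synthetic scans — the ground-truth scene record.
#'
#' @param scan A [time_scan()].
#' @param path Output file path (`.tif`/`.tiff`).
#' @param format Only `"tiff"` is supported in this build; `"hdf5"`
#'   signals an unsupported-format error.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, format = c("tiff", "hdf5")) {
  stopifnot(inherits(scan, "time_scan"))
  format <- match.arg(format)
  if (format == "hdf5")
    stop("format \"hdf5\" is not supported by this build; use \"tiff\"")
  counts <- scan$counts
  if (max(counts) > 65535)
    stop("counts exceed the 16-bit range of the TIFF format")
  if (scan$averaged && any(counts != round(counts)))
    warning("averaged scan has non-integer counts; TIFF storage rounds to integers")
  nt <- dim(counts)[3]
  pages <- lapply(seq_len(nt),
                  function(k) round(counts[, , k]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(t0_ps = scan$axis$t0, dt_ps = scan$axis$dt,
               n_steps = scan$axis$n_steps,
               gate_width_ns = scan$axis$gate_width,
               modality = scan$modality,
               rows = dim(counts)[1], cols = dim(counts)[2],
               averaged = scan$averaged)
  gt <- scan$provenance$ground_truth
  if (!is.null(gt))
    meta$ground_truth <- list(delta_tissue_ps = gt$delta_tissue,
                              sigma_ps = gt$sigma,
                              amplitude = gt$amplitude)
  sc <- scan$provenance$scene
  if (!is.null(sc))
    meta$scene <- list(il_percent = sc$il_percent, mu_a = sc$mu_a,
                       mu_s_prime = sc$mu_s_prime, k_fluo = sc$k_fluo,
                       c_fluo = sc$c_fluo, depth_mm = sc$depth)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, na = "null", matrix = "rowmajor")
  invisible(path)
}

#' Read a time scan from disk
#'
#' @param path TIFF path written by [write_scan()]; the JSON sidecar must
#'   be present alongside it.
#' @param format Only `"tiff"` is supported in this build.
#' @return A [time_scan()]; counts and timing metadata round-trip
#'   losslessly.
#' @export
read_scan <- function(path, format = c("tiff", "hdf5")) {
  format <- match.arg(format)
  if (format == "hdf5")
    stop("format \"hdf5\" is not supported by this build; use \"tiff\"")
  if (!file.exists(path)) stop("file not found: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing JSON metadata sidecar ", sp,
         "; required attributes: ", paste(required_meta, collapse = ", "))
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  missing <- setdiff(required_meta, names(meta))
  if (length(missing))
    stop("metadata sidecar lacks required field(s): ",
         paste(missing, collapse = ", "))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != meta$n_steps)
    stop(sprintf("shape mismatch: sidecar n_steps = %d but file has %d pages",
                 meta$n_steps, length(pages)))
  counts <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) counts[, , k] <- round(pages[[k]] * 65535)
  ax <- gate_axis(t0 = meta$t0_ps, dt = meta$dt_ps, n_steps = meta$n_steps,
                  gate_width = meta$gate_width_ns)
  prov <- list(source = path)
  if (!is.null(meta$ground_truth)) {
    prov$ground_truth <- lapply(
      list(delta_tissue = meta$ground_truth$delta_tissue_ps,
           sigma = meta$ground_truth$sigma_ps,
           amplitude = meta$ground_truth$amplitude),
      function(m) if (is.null(m)) NULL else as.matrix(m))
  }
  if (!is.null(meta$scene)) prov$scene_meta <- meta$scene
  time_scan(counts, ax, modality = meta$modality, provenance = prov,
            averaged = isTRUE(meta$averaged))
}

# ---- acquisition-level corrections ----------------------------------------

#' Darkfield subtraction
#'
#' Subtracts a darkfield acquisition (a full time scan or a single
#' intensity image, both acquired in total darkness under identical
#' camera settings), clamping at zero.
#'
#' @param scan A [time_scan()].
#' @param dark A `time_scan` of matching shape, or an [intensity_image()]
#'   of matching spatial shape (subtracted from every gate step).
#' @return Corrected `time_scan`; modality preserved.
#' @export
darkfield_subtract <- function(scan, dark) {
  stopifnot(inherits(scan, "time_scan"))
  d <- dim(scan$counts)
  if (inherits(dark, "time_scan")) {
    if (!all(dim(dark$counts) == d))
      stop("darkfield scan shape does not match")
    sub <- dark$counts
  } else if (inherits(dark, "intensity_image")) {
    if (!all(dim(dark$values) == d[1:2]))
      stop("darkfield image shape does not match")
    sub <- array(dark$values, d)
  } else stop("`dark` must be a time_scan or intensity_image")
  if (all(sub > scan$counts))
    warning("darkfield exceeds the scan everywhere: inputs possibly swapped")
  out <- scan
  out$counts <- pmax(scan$counts - sub, 0)
  out$provenance <- c(scan$provenance, list(darkfield_subtracted = TRUE))
  out
}

#' Average replicate time scans
#'
#' Element-wise mean of replicate acquisitions (same shape, axis and
#' modality), reducing thermal and shot noise. The result carries
#' real-valued counts and the `averaged` flag.
#'
#' @param scans List of [time_scan()] objects.
#' @return Averaged `time_scan`.
#' @export
average_scans <- function(scans) {
  if (!is.list(scans) || length(scans) == 0)
    stop("`scans` must be a non-empty list of time_scan objects")
  stopifnot(all(vapply(scans, inherits, TRUE, "time_scan")))
  ref <- scans[[1]]
  for (s in scans[-1]) {
    if (!all(dim(s$counts) == dim(ref$counts)))
      stop("scans have mismatched shapes")
    if (!same_axis(s$axis, ref$axis)) stop("scans have mismatched axes")
    if (s$modality != ref$modality) stop("scans have mixed modalities")
  }
  acc <- Reduce(`+`, lapply(scans, `[[`, "counts"))
  time_scan(acc / length(scans), ref$axis, modality = ref$modality,
            provenance = list(averaged_n = length(scans)),
            averaged = TRUE)
}

#' Mean-intensity image over a gate-step window
#'
#' @param scan A [time_scan()].
#' @param frame_window Integer range of gate steps (1-based, inclusive) to
#'   average; default the full axis.
#' @return An [intensity_image()] with `n_frames_averaged` recorded.
#' @export
intensity_image <- function(scan, frame_window = NULL) {
  stopifnot(inherits(scan, "time_scan"))
  nt <- dim(scan$counts)[3]
  if (is.null(frame_window)) frame_window <- c(1L, nt)
  frame_window <- as.integer(round(range(frame_window)))
  if (frame_window[1] < 1 || frame_window[2] > nt ||
      frame_window[1] > frame_window[2])
    stop("`frame_window` must be a non-empty range within the axis")
  idx <- frame_window[1]:frame_window[2]
  vals <- apply(scan$counts[, , idx, drop = FALSE], c(1, 2), mean)
  structure(list(values = vals, n_frames_averaged = length(idx),
                 modality = scan$modality),
            class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %s, %d x %d px, mean of %d frames\n",
              x$modality, nrow(x$values), ncol(x$values),
              x$n_frames_averaged))
  invisible(x)
}

roi_indices <- function(roi, nr, nc) {
  # roi = c(row0, col0, height, width), 0-based origin
  stopifnot(length(roi) == 4)
  r <- (roi[1] + 1):(roi[1] + roi[3])
  cl <- (roi[2] + 1):(roi[2] + roi[4])
  if (roi[3] < 1 || roi[4] < 1 || min(r) < 1 || max(r) > nr ||
      min(cl) < 1 || max(cl) > nc)
    stop("ROI out of bounds or empty")
  list(rows = r, cols = cl)
}

#' Signal-to-noise ratio of an intensity image
#'
#' SNR is the mean over a signal region divided by the standard deviation
#' of a background region adjacent to the emitting object where no light
#' is emitted (unbiased n-1 estimator).
#'
#' @param image An [intensity_image()].
#' @param signal_roi,background_roi `(row0, col0, height, width)` regions,
#'   0-based; must be disjoint, background with at least 2 pixels.
#' @return The SNR (dimensionless).
#' @export
snr <- function(image, signal_roi, background_roi) {
  stopifnot(inherits(image, "intensity_image"))
  nr <- nrow(image$values); nc <- ncol(image$values)
  s <- roi_indices(signal_roi, nr, nc)
  b <- roi_indices(background_roi, nr, nc)
  # disjointness via linear indices
  lin <- function(ri) as.vector(outer(ri$rows, (ri$cols - 1) * nr, "+"))
  if (length(intersect(lin(s), lin(b))))
    stop("signal and background ROIs must be disjoint")
  bg <- image$values[b$rows, b$cols]
  if (length(bg) < 2) stop("background ROI must contain >= 2 pixels")
  sdev <- stats::sd(as.vector(bg))
  if (sdev == 0) stop("degenerate background: zero standard deviation")
  mean(image$values[s$rows, s$cols]) / sdev
}
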