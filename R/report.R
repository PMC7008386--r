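#' Average spectrum over a region of interest
#'
#' Unweighted mean spectrum over the valid pixels inside `roi_mask` (e.g.
#' the ray area of an annual-ring section).
#'
#' @param image a [spectral_image()]
#' @param roi_mask logical `rows x cols` matrix
#' @return numeric spectrum (length = channels)
#' @export
roi_average <- function(image, roi_mask) {
  stopifnot(inherits(image, "spectral_image"))
  if (!identical(dim(roi_mask), dim(image$cube)[1:2]))
    stop("roi_mask shape does not match the image")
  eff <- roi_mask & image$mask
  if (!any(eff)) stop("ROI contains no valid pixels")
  mat <- unfold_full(image)[as.vector(t(eff)), , drop = FALSE]
  colMeans(mat)
}

#' Band intensity in a wavenumber window
#'
#' Maximum absorbance within `center +/- halfwidth`. With
#' `baseline = "local_linear"` the chord between the window endpoints is
#' subtracted first, which removes a locally linear background under the
#' band.
#'
#' @param y spectrum
#' @param axis wavenumber grid of `y`
#' @param center band position (cm^-1)
#' @param halfwidth window half width (cm^-1), default 10
#' @param baseline `"none"` or `"local_linear"`
#' @return band intensity (a.u.)
#' @export
band_intensity <- function(y, axis, center, halfwidth = 10,
                           baseline = c("none", "local_linear")) {
  baseline <- match.arg(baseline)
  stopifnot(length(y) == length(axis))
  lo <- center - halfwidth; hi <- center + halfwidth
  if (lo < min(axis) || hi > max(axis))
    stop("window [", lo, ", ", hi, "] outside the axis range [",
         min(axis), ", ", max(axis), "]")
  inw <- which(axis >= lo & axis <= hi)
  yy <- y[inw]
  if (baseline == "local_linear") {
    x <- axis[inw]
    chord <- yy[1] + (yy[length(yy)] - yy[1]) * (x - x[1]) / (x[length(x)] - x[1])
    yy <- yy - chord
  }
  max(yy)
}

#' Per-ring band intensity series
#'
#' @param ring_ids ordered ring identifiers
#' @param values per-ring intensities
#' @param band_center band position the series tracks (cm^-1)
#' @param window_halfwidth window half width used (cm^-1)
#' @return object of class `ring_series`
#' @export
ring_series <- function(ring_ids, values, band_center, window_halfwidth = 10) {
  if (length(values) != length(ring_ids))
    stop("values and ring_ids lengths differ")
  structure(list(ring_ids = ring_ids, values = as.numeric(values),
                 band_center = band_center,
                 window_halfwidth = window_halfwidth),
            class = "ring_series")
}

#' @export
print.ring_series <- function(x, ...) {
  cat(sprintf("<ring_series at %g cm-1: %s>\n", x$band_center,
              paste(sprintf("%s=%.3g", x$ring_ids, x$values), collapse = " ")))
  invisible(x)
}

#' Track a band across a ring series of images
#'
#' Convenience wrapper: ROI-average each image, then measure the band
#' intensity, yielding one [ring_series()].
#'
#' @param images ordered list of [spectral_image()]
#' @param roi_mask logical mask (recycled across images) or list of masks
#' @param center band position (cm^-1)
#' @param halfwidth window half width (cm^-1)
#' @param baseline passed to [band_intensity()]
#' @param ring_ids identifiers; default `meta$ring` or 1..n
#' @return a [ring_series()]
#' @export
track_band <- function(images, roi_mask, center, halfwidth = 10,
                       baseline = "none", ring_ids = NULL) {
  if (!is.list(roi_mask) || is.matrix(roi_mask))
    roi_mask <- rep(list(roi_mask), length(images))
  vals <- vapply(seq_along(images), function(i) {
    sp <- roi_average(images[[i]], roi_mask[[i]])
    band_intensity(sp, images[[i]]$axis, center, halfwidth, baseline)
  }, numeric(1))
  if (is.null(ring_ids)) {
    ring_ids <- vapply(seq_along(images), function(i) {
      r <- images[[i]]$meta$ring
      if (is.null(r)) i else r
    }, numeric(1))
  }
  ring_series(ring_ids, vals, center, halfwidth)
}

#' Locate the sapwood-to-heartwood transition ring
#'
#' Returns the first ring where the heartwood marker band dominates:
#' `I1640 / (I1640 + I1660) > rel_threshold`. The ratio is invariant to a
#' common positive rescaling of both series. When the ratio never crosses
#' the threshold, `NA` is returned with the ratio trace attached as
#' attribute `diagnostic`.
#'
#' @param series_1640 [ring_series()] of the emerging band (e.g. 1640 cm^-1)
#' @param series_1660 [ring_series()] of the declining band (e.g. 1660 cm^-1)
#' @param rel_threshold dominance threshold on the normalized ratio
#' @return ring id, or `NA` with attribute `diagnostic`
#' @export
transition_index <- function(series_1640, series_1660, rel_threshold = 0.5) {
  stopifnot(inherits(series_1640, "ring_series"), inherits(series_1660, "ring_series"))
  if (!identical(series_1640$ring_ids, series_1660$ring_ids))
    stop("ring id mismatch between the two series")
  if (length(series_1640$ring_ids) < 3L) stop("need at least 3 rings")
  a <- series_1640$values; b <- series_1660$values
  tot <- a + b
  ratio <- ifelse(tot > 0, a / tot, 0)
  hit <- which(ratio > rel_threshold)
  if (!length(hit))
    return(structure(NA, diagnostic = ratio))
  series_1640$ring_ids[hit[1]]
}

#' Export a structured result set for a fitted model
#'
#' Writes, under `out_dir`: `spectra.tsv` (wavenumber + one column per
#' component), per-image component maps with a manifest (via [save_maps()]),
#' `lof.tsv` (the LOF trace), `presence.tsv`, optional ring-series tables,
#' and `run_info.json` (parameters and package version; no timestamps, so
#' reruns are byte-identical).
#'
#' @param model a fitted [mcr_als_fit()] result
#' @param multiset the fitted multiset
#' @param out_dir output directory
#' @param ring_series_list optional named list of [ring_series()]
#' @return character vector of files written, invisibly
#' @export
export_report <- function(model, multiset, out_dir, ring_series_list = NULL) {
  if (!inherits(model, "mcr_model") || is.null(model$C) || !nrow(model$C))
    stop("model is empty or not fitted")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  k <- nrow(model$S_t)
  # component order stable across runs: descending total concentration
  ord <- order(colSums(model$C), decreasing = TRUE)
  spectra <- data.frame(wavenumber = model$axis, t(model$S_t[ord, , drop = FALSE]))
  names(spectra) <- c("wavenumber", sprintf("component%02d", seq_len(k)))
  f_spec <- file.path(out_dir, "spectra.tsv")
  utils::write.table(spectra, f_spec, sep = "\t", row.names = FALSE)
  maps <- refold_all(multiset, model$C[, ord, drop = FALSE])
  f_maps <- save_maps(maps, file.path(out_dir, "maps"))
  f_lof <- file.path(out_dir, "lof.tsv")
  utils::write.table(data.frame(iteration = seq_along(model$lof_trace),
                                lof_percent = model$lof_trace),
                     f_lof, sep = "\t", row.names = FALSE)
  f_pres <- file.path(out_dir, "presence.tsv")
  pres <- model$presence[, ord, drop = FALSE] * 1L
  utils::write.table(data.frame(image_id = model$blocks$image_id, pres),
                     f_pres, sep = "\t", row.names = FALSE)
  files <- c(f_spec, f_maps, f_lof, f_pres)
  if (!is.null(ring_series_list)) {
    for (nm in names(ring_series_list)) {
      rs <- ring_series_list[[nm]]
      f <- file.path(out_dir, paste0("series_", nm, ".tsv"))
      utils::write.table(data.frame(ring = rs$ring_ids, value = rs$values),
                         f, sep = "\t", row.names = FALSE)
      files <- c(files, f)
    }
  }
  f_info <- file.path(out_dir, "run_info.json")
  jsonlite::write_json(list(
    package = "hsimcr",
    version = as.character(utils::packageVersion("hsimcr")),
    k = k, n_iter = model$n_iter, converged = model$converged,
    final_lof_percent = tail(model$lof_trace, 1),
    component_order = ord,
    images = model$blocks$image_id),
    f_info, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, f_info))
}
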