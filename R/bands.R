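#' Spectral band specification
#'
#' A single absorption band used to compose synthetic pure spectra: a peak
#' position, a full width at half maximum, a height and a line shape.
#'
#' @param center band position (wavenumber, cm^-1)
#' @param width full width at half maximum (cm^-1), must be > 0
#' @param height peak absorbance (a.u.), must be >= 0
#' @param shape `"gaussian"` (default) or `"lorentzian"`
#' @return an object of class `band_spec`
#' @export
#' @examples
#' band_spec(1660, width = 24, height = 0.6)
band_spec <- function(center, width, height, shape = c("gaussian", "lorentzian")) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(center), length(center) == 1L, is.finite(center))
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0)
    stop("band width must be a positive number")
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) || height < 0)
    stop("band height must be non-negative")
  structure(list(center = center, width = width, height = height, shape = shape),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band %s at %g cm-1, fwhm %g, height %g>\n",
              x$shape, x$center, x$width, x$height))
  invisible(x)
}

.band_profiles <- c("cellulose", "lumen_blank", "extractives", "lignin_sw", "lignin_hw")

#' Default band libraries for wood constituent profiles
#'
#' Returns the list of [band_spec()] objects used by the synthetic generator
#' for one constituent profile, composed from the classical mid-IR band
#' assignments of softwood cell-wall polymers and extractives in the
#' 1200-1750 cm^-1 fingerprint window:
#'
#' * `cellulose` - CH2 rocking (1317), CH in-plane bending (1336), CH bending
#'   (1368), CH2 scissoring (1423) and related polysaccharide bands.
#' * `lignin_sw` - sapwood-type lignin: guaiacyl ring (1270), aromatic
#'   skeletal vibrations (1510, 1600), the coniferyl alcohol/aldehyde
#'   C=C / C=O band at 1660 cm^-1, and a hemicellulose ester shoulder at
#'   1738 cm^-1. Contains no 1640 band.
#' * `lignin_hw` - heartwood-type lignin: same aromatic backbone but the
#'   1660 band is replaced by the carbonyl band at 1640 cm^-1
#'   (para-substituted ketones / H-bonded aryl aldehydes). Contains no 1660
#'   band.
#' * `extractives` - flavonoid (taxifolin-like) carbonyl at 1640 and a
#'   comparable 1660 contribution, aromatic 1608, and the dominant
#'   resin-acid / ester C=O bands at 1700 and 1728 cm^-1.
#' * `lumen_blank` - broad, weak substrate/background features with no sharp
#'   biopolymer bands (the lumen carries no cell-wall material).
#'
#' @param profile one of `"cellulose"`, `"lumen_blank"`, `"extractives"`,
#'   `"lignin_sw"`, `"lignin_hw"`
#' @return list of `band_spec`
#' @export
#' @examples
#' vapply(build_band_library("cellulose"), `[[`, numeric(1), "center")
build_band_library <- function(profile) {
  if (!is.character(profile) || length(profile) != 1L || !(profile %in% .band_profiles))
    stop("unknown profile '", paste(profile, collapse = ","),
         "'; valid profiles: ", paste(.band_profiles, collapse = ", "))
  bl <- function(...) {
    rows <- list(...)
    lapply(rows, function(r) band_spec(r[1], r[2], r[3]))
  }
  switch(profile,
    cellulose = bl(
      c(1280, 24, 0.45),
      c(1317, 18, 0.90),
      c(1336, 18, 0.80),
      c(1368, 18, 0.85),
      c(1423, 22, 0.70),
      c(1462, 24, 0.35)),
    lignin_sw = bl(
      c(1270, 26, 0.55),
      c(1423, 22, 0.35),
      c(1510, 20, 1.00),
      c(1600, 26, 0.75),
      c(1660, 24, 0.60),
      c(1738, 26, 0.30)),
    lignin_hw = bl(
      c(1270, 26, 0.55),
      c(1423, 22, 0.35),
      c(1510, 20, 1.00),
      c(1600, 26, 0.75),
      c(1640, 24, 0.60)),
    extractives = bl(
      c(1608, 22, 0.50),
      c(1640, 20, 0.45),
      c(1660, 18, 0.50),
      c(1700, 20, 0.50),
      c(1728, 20, 1.00)),
    lumen_blank = bl(
      c(1240, 55, 0.35),
      c(1420, 65, 0.40),
      c(1580, 60, 0.30),
      c(1712, 50, 0.25))
  )
}

# evaluate one band on the axis
render_band <- function(band, axis) {
  u <- (axis - band$center) / band$width
  if (band$shape == "gaussian") {
    band$height * exp(-4 * log(2) * u^2)
  } else {
    band$height / (1 + (2 * u)^2)
  }
}

#' Render unit-norm pure spectra from band libraries
#'
#' Each component spectrum is the pointwise sum of its band shapes evaluated
#' on the wavenumber axis, then normalized to unit Euclidean (2-)norm, the
#' same normalization MCR-ALS applies to resolved spectra.
#'
#' @param library a list of band libraries (one `list` of [band_spec()] per
#'   component), e.g. `lapply(profiles, build_band_library)`
#' @param axis strictly monotonic wavenumber grid (cm^-1)
#' @return matrix (components x channels), rows >= 0 with unit 2-norm;
#'   row names taken from `names(library)` when present
#' @export
render_pure_spectra <- function(library, axis) {
  if (!is.list(library) || length(library) == 0L)
    stop("band library is empty")
  if (length(library) > 0 && inherits(library[[1]], "band_spec"))
    library <- list(library)
  d <- diff(axis)
  if (length(axis) < 2L || any(!is.finite(axis)) || !(all(d > 0) || all(d < 0)))
    stop("axis must be strictly monotonic")
  S <- t(vapply(library, function(bands) {
    if (length(bands) == 0L) stop("band library contains an empty component")
    y <- rep(0, length(axis))
    for (b in bands) {
      v <- render_band(b, axis)
      if (max(v) <= .Machine$double.eps * b$height && b$height > 0)
        stop("band at ", b$center, " cm-1 renders to zero on the axis [",
             min(axis), ", ", max(axis), "]")
      y <- y + v
    }
    y
  }, numeric(length(axis))))
  nrm <- sqrt(rowSums(S^2))
  if (any(nrm == 0)) stop("a component rendered to an all-zero spectrum")
  S <- S / nrm
  rownames(S) <- names(library)
  S
}
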