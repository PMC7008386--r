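#' AsLS baseline-correction parameters
#'
#' Parameters of the asymmetric least squares baseline estimator: the
#' baseline z minimizes `sum_i w_i (y_i - z_i)^2 + lam * sum (d2 z)^2` with
#' asymmetric weights `w_i = p` where `y_i > z_i` (points above the baseline,
#' i.e. peaks, barely pull it up) and `w_i = 1 - p` otherwise. Iterating the
#' weighted Whittaker solve to a stable weight vector yields a baseline that
#' hugs the lower envelope of the spectrum, which removes broad Mie-type
#' scatter oscillations while leaving absorption bands intact.
#'
#' Defaults `lam = 1e5`, `p = 0.001` are the conventional magnitudes for
#' FTIR scatter correction on a few-hundred-channel window.
#'
#' @param lam smoothness weight on the squared second difference (> 0)
#' @param p asymmetry weight in (0, 1)
#' @param max_iter maximum reweighting iterations (>= 1)
#' @param tol allowed fraction of weights changing at convergence (0 = exact
#'   weight stability, the fixed point of the scheme)
#' @return object of class `asls_params`
#' @export
asls_params <- function(lam = 1e5, p = 0.001, max_iter = 10L, tol = 0) {
  if (!is.numeric(lam) || lam <= 0) stop("lam must be > 0")
  if (!is.numeric(p) || p <= 0 || p >= 1) stop("p must be in (0, 1)")
  if (max_iter < 1) stop("max_iter must be >= 1")
  structure(list(lam = lam, p = p, max_iter = as.integer(max_iter), tol = tol),
            class = "asls_params")
}

#' @export
print.asls_params <- function(x, ...) {
  cat(sprintf("<asls_params lam=%g p=%g max_iter=%d>\n", x$lam, x$p, x$max_iter))
  invisible(x)
}

#' Truncate an image to a wavenumber window
#'
#' Retains exactly the channels with `lo <= wavenumber <= hi`. The analysis
#' window for oversaturation-prone wood sections is 1200-1750 cm^-1.
#'
#' @param image a [spectral_image()]
#' @param lo,hi window bounds (cm^-1), `lo < hi`
#' @return truncated [spectral_image()]; the window is recorded in
#'   `meta$window`
#' @export
truncate_range <- function(image, lo = 1200, hi = 1750) {
  stopifnot(inherits(image, "spectral_image"))
  if (lo >= hi) stop("lo must be < hi")
  keep <- image$axis >= lo & image$axis <= hi
  if (!any(keep)) stop("window [", lo, ", ", hi, "] does not overlap the axis")
  meta <- image$meta
  meta$window <- c(lo, hi)
  spectral_image(image$cube[, , keep, drop = FALSE], image$axis[keep],
                 mask = image$mask, meta = meta)
}

#' Estimate an AsLS baseline for one spectrum
#'
#' @param y numeric spectrum (length >= 4, finite)
#' @param params an [asls_params()]
#' @return the baseline `z` (same length as `y`), with attributes
#'   `iterations` and `converged`; the corrected spectrum is `y - z`
#' @export
asls_baseline <- function(y, params = asls_params()) {
  if (length(y) < 4L) stop("spectrum must have at least 4 points")
  if (any(!is.finite(y))) stop("non-finite values in spectrum")
  res <- cpp_asls(as.numeric(y), params$lam, params$p, params$max_iter)
  structure(res$baseline, iterations = res$iterations, converged = res$converged)
}

#' Weighted Whittaker smoother (inner solve of AsLS)
#'
#' Solves `(diag(w) + lam * D2'D2) z = w * y` exactly by a banded Cholesky
#' factorization, where D2 is the second-difference operator on the index
#' grid. Exposed so the inner solve can be checked against a dense solver.
#'
#' @param y numeric vector
#' @param w non-negative weights, same length
#' @param lam smoothness penalty (> 0)
#' @return the smoothed vector `z`
#' @export
whittaker_smooth <- function(y, w, lam) {
  stopifnot(length(y) == length(w), lam > 0, all(w >= 0))
  cpp_whittaker(as.numeric(y), as.numeric(w), lam)
}

#' Baseline-correct every valid pixel of an image
#'
#' Applies [asls_baseline()] pixelwise and subtracts it. Invalid pixels are
#' left untouched. Negative corrected absorbances are kept; non-negativity
#' is enforced later by MCR-ALS, not by preprocessing.
#'
#' @param image a [spectral_image()] (typically already truncated to the
#'   analysis window)
#' @param params an [asls_params()]
#' @param return_baselines if `TRUE`, attach the per-pixel baselines as
#'   attribute `baselines` (rows x cols x channels)
#' @return corrected [spectral_image()]
#' @export
correct_image <- function(image, params = asls_params(), return_baselines = FALSE) {
  stopifnot(inherits(image, "spectral_image"))
  d <- dim(image$cube)
  mat <- unfold_full(image)
  mat[!as.vector(t(image$mask)), ] <- NA_real_
  Z <- tryCatch(cpp_asls_matrix(mat, params$lam, params$p, params$max_iter),
                error = function(e) stop("AsLS failed: ", conditionMessage(e)))
  corrected <- mat - Z
  out_mat <- unfold_full(image)
  valid <- as.vector(t(image$mask))
  out_mat[valid, ] <- corrected[valid, ]
  meta <- image$meta
  meta$asls <- list(lam = params$lam, p = params$p, max_iter = params$max_iter)
  out <- spectral_image(refold_full(out_mat, d[1], d[2]), image$axis,
                        mask = image$mask, meta = meta)
  if (return_baselines) {
    Zfull <- Z
    Zfull[!valid, ] <- NA_real_
    attr(out, "baselines") <- refold_full(Zfull, d[1], d[2])
  }
  out
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing of an equally spaced spectrum.
#' Interior points use the centered window; the first and last half-windows
#' are smoothed by evaluating the polynomial fitted to the edge-anchored
#' window, so the output has the input's length. Defaults (window 15,
#' degree 2) match common practice for point IR spectra.
#'
#' @param y numeric vector, `length(y) >= window`
#' @param window odd window size (points)
#' @param degree polynomial degree, `< window`
#' @return smoothed vector of the same length
#' @export
savgol_smooth <- function(y, window = 15L, degree = 2L) {
  window <- as.integer(window); degree <- as.integer(degree)
  if (window %% 2L == 0L) stop("window must be odd")
  if (degree >= window) stop("degree must be < window")
  n <- length(y)
  if (n < window) stop("window (", window, ") larger than input length (", n, ")")
  h <- (window - 1L) %/% 2L
  # projection matrix of the centered window: rows = evaluation offsets
  V <- outer(seq(-h, h), 0:degree, `^`)
  P <- V %*% solve(crossprod(V), t(V))
  out <- numeric(n)
  # interior: centered-window coefficient row at offset 0
  w0 <- P[h + 1L, ]
  for (i in seq.int(h + 1L, n - h)) out[i] <- sum(w0 * y[(i - h):(i + h)])
  # edges: evaluate the polynomial fitted on the boundary window
  out[1:h] <- (P %*% y[1:window])[1:h]
  out[(n - h + 1L):n] <- (P %*% y[(n - window + 1L):n])[(window - h + 1L):window]
  out
}
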