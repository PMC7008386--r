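#' Singular values of the augmented multiset
#'
#' Scree input for rank estimation: the singular values (descending) of the
#' preprocessed augmented data matrix.
#'
#' @param multiset a [augment()] result (or a plain numeric matrix)
#' @return numeric vector of singular values, descending
#' @export
svd_scree <- function(multiset) {
  D <- if (inherits(multiset, "multiset")) multiset$data else as.matrix(multiset)
  if (!length(D) || !nrow(D)) stop("empty multiset")
  svd(D, nu = 0, nv = 0)$d
}

#' Choose the number of components from a scree
#'
#' * `gap`: the index `k` maximizing `s_k / s_(k+1)` over the first half of
#'   the scree (restricting to the first half avoids spurious ratios in the
#'   noise tail).
#' * `noise_floor`: the count of singular values above the expected largest
#'   singular value of an i.i.d. noise matrix of the same size,
#'   `noise_sd * (sqrt(m) + sqrt(n))`.
#' * `manual`: passthrough of `k`.
#'
#' @param sv singular values, descending and non-negative
#' @param noise_sd noise standard deviation (required for `noise_floor`)
#' @param method `"gap"`, `"noise_floor"` or `"manual"`
#' @param k the rank for `method = "manual"`
#' @param dims `c(m, n)` of the data matrix for `noise_floor`
#' @return integer rank estimate
#' @export
select_rank <- function(sv, noise_sd = NULL, method = c("gap", "noise_floor", "manual"),
                        k = NULL, dims = NULL) {
  method <- match.arg(method)
  if (is.unsorted(rev(sv)) || any(sv < 0))
    stop("sv must be non-negative and descending")
  switch(method,
    gap = {
      if (length(sv) < 2L) stop("gap method needs at least 2 singular values")
      upto <- min(ceiling(length(sv) / 2), length(sv) - 1L)
      ratios <- sv[seq_len(upto)] / sv[seq_len(upto) + 1L]
      ratios[!is.finite(ratios)] <- Inf
      which.max(ratios)
    },
    noise_floor = {
      if (is.null(noise_sd) || is.null(dims))
        stop("noise_floor needs noise_sd and dims")
      thr <- noise_sd * (sqrt(dims[1]) + sqrt(dims[2]))
      sum(sv > thr)
    },
    manual = {
      if (is.null(k)) stop("manual method needs k")
      as.integer(k)
    })
}

#' SIMPLISMA purest-pixel initial estimates
#'
#' Selects the `k` purest rows (pixel spectra) of the multiset as initial
#' estimates of the pure spectra. Purity of row i is
#' `p_i = sd_i / (mean_i + alpha)` with offset `alpha = alpha_pct/100 *
#' max(mean)`; after each selection, candidate purities are down-weighted by
#' the determinant of the correlation-around-origin dispersion matrix of the
#' already selected rows plus the candidate, which suppresses rows collinear
#' with previous picks. Selected spectra are clipped at 0 and normalized to
#' unit 2-norm.
#'
#' @param multiset a [augment()] result (or a numeric matrix, rows = pixels)
#' @param k number of components (>= 1, <= rows)
#' @param alpha_pct purity offset, percent of the maximum row mean
#' @return matrix `k x channels` with attribute `selected` (row indices)
#' @export
simplisma_init <- function(multiset, k, alpha_pct = 1) {
  D <- if (inherits(multiset, "multiset")) multiset$data else as.matrix(multiset)
  n <- nrow(D)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k exceeds the number of pixels")
  mu <- rowMeans(D)
  sg <- sqrt(rowMeans(D^2) - mu^2)
  sg[sg < 0] <- 0
  alpha <- alpha_pct / 100 * max(mu)
  purity1 <- sg / (mu + alpha)
  # length-scaled rows for the correlation-around-origin dispersion
  lambda <- sqrt(mu^2 + (sg + alpha)^2)
  Z <- D / lambda
  nchan <- ncol(D)
  sel <- integer(0)
  for (step in seq_len(k)) {
    w <- if (!length(sel)) rep(1, n) else {
      Zs <- Z[sel, , drop = FALSE]
      base <- tcrossprod(Zs) / nchan
      zz <- rowSums(Z^2) / nchan
      cross <- Z %*% t(Zs) / nchan
      vapply(seq_len(n), function(i) {
        M <- rbind(c(zz[i], cross[i, ]), cbind(cross[i, ], base))
        det(M)
      }, numeric(1))
    }
    w[w < 0] <- 0
    score <- w * purity1
    score[sel] <- -Inf
    pick <- which.max(score)
    sel <- c(sel, pick)
  }
  sv <- svd(D, nu = 0, nv = 0)$d
  num_rank <- sum(sv > 1e-10 * sv[1])
  if (k > num_rank)
    warning("k (", k, ") exceeds the numerical rank (", num_rank, ") of the data")
  S0 <- D[sel, , drop = FALSE]
  S0[S0 < 0] <- 0
  nrm <- sqrt(rowSums(S0^2))
  if (any(nrm == 0)) stop("a selected pixel spectrum is all zero after clipping")
  S0 <- S0 / nrm
  attr(S0, "selected") <- sel
  S0
}

#' Lack of fit of a bilinear model
#'
#' `100 * sqrt(sum((D - C S_t)^2) / sum(D^2))`, the percent unexplained
#' signal.
#'
#' @param D data matrix
#' @param C concentration matrix (rows x k)
#' @param S_t pure spectra matrix (k x channels)
#' @return percent lack of fit
#' @export
lack_of_fit <- function(D, C, S_t) {
  D <- as.matrix(D)
  ss <- sum(D^2)
  if (ss == 0) stop("lack of fit undefined: D is all zero")
  E <- D - C %*% S_t
  100 * sqrt(sum(E^2) / ss)
}

#' MCR-ALS constraint set
#'
#' @param nonneg_C,nonneg_S enforce elementwise non-negativity (always on in
#'   this implementation's exact-NNLS updates; kept as flags for reporting)
#' @param normalize_S normalize S_t rows to unit 2-norm each iteration,
#'   rescaling C columns compensatingly (product unchanged)
#' @param correspondence optional logical presence matrix (n_images x k);
#'   components marked absent have their concentration block constrained to
#'   exactly zero (the correspondence-of-species constraint)
#' @return object of class `mcr_constraints`
#' @export
mcr_constraints <- function(nonneg_C = TRUE, nonneg_S = TRUE, normalize_S = TRUE,
                            correspondence = NULL) {
  structure(list(nonneg_C = nonneg_C, nonneg_S = nonneg_S,
                 normalize_S = normalize_S, correspondence = correspondence),
            class = "mcr_constraints")
}

#' Non-negative least squares
#'
#' Exact Lawson-Hanson active-set solution of `min ||A x - b||` subject to
#' `x >= 0`.
#' @param A numeric matrix (m x n)
#' @param b numeric vector (length m)
#' @return solution vector x
#' @export
nnls <- function(A, b) {
  cpp_nnls(as.matrix(A), as.numeric(b))
}

#' Fit the constrained MCR-ALS bilinear model to a multiset
#'
#' Alternating exact non-negative least squares: each iteration (i) updates
#' every row of C by NNLS against the current S_t, restricted to the
#' components present in the row's image when a correspondence matrix is
#' given (absent components are exactly zero by construction); (ii) updates
#' every column of S_t by NNLS against C; (iii) normalizes S_t rows to unit
#' 2-norm with a compensating rescale of the C columns; (iv) appends the
#' lack of fit. Because both half-updates are exact constrained minimizers
#' and the normalization leaves C S_t unchanged, the LOF trace is
#' non-increasing. Iteration stops when the relative LOF change drops below
#' `tol` (in percent of the previous LOF) or after `max_iter` iterations.
#'
#' @param multiset a [augment()] result
#' @param S0 initial spectra (k x channels), e.g. from [simplisma_init()]
#' @param constraints an [mcr_constraints()]
#' @param tol relative LOF change stopping threshold, percent (default 0.1)
#' @param max_iter maximum iterations (default 50)
#' @return object of class `mcr_model` with fields `C`, `S_t`, `presence`,
#'   `lof_trace`, `n_iter`, `converged`, plus the multiset bookkeeping
#'   (`blocks`, `index`, `shapes`, `axis`) needed to refold maps
#' @export
mcr_als_fit <- function(multiset, S0, constraints = mcr_constraints(),
                        tol = 0.1, max_iter = 50L) {
  stopifnot(inherits(multiset, "multiset"))
  D <- multiset$data
  S <- as.matrix(S0)
  k <- nrow(S)
  if (k > ncol(D)) stop("k (", k, ") exceeds the number of channels (", ncol(D), ")")
  if (ncol(S) != ncol(D)) stop("S0 channel count does not match the multiset")
  if (any(sqrt(rowSums(S^2)) == 0)) stop("S0 contains an all-zero row")
  n_img <- nrow(multiset$blocks)
  presence <- constraints$correspondence
  if (is.null(presence)) presence <- matrix(TRUE, n_img, k)
  presence <- as.matrix(presence)
  if (!identical(dim(presence), c(n_img, k)))
    stop("correspondence matrix must be n_images x k")
  # 0-based block id per row, for the C++ row updater
  block_of <- integer(nrow(D))
  for (bi in seq_len(n_img))
    block_of[seq.int(multiset$blocks$start[bi], multiset$blocks$end[bi])] <- bi - 1L
  lof_trace <- numeric(0)
  converged <- FALSE
  C <- NULL
  it <- 0L
  pres_l <- matrix(as.logical(presence), n_img, k)
  all_present <- matrix(TRUE, 1L, k)
  zero_block <- integer(ncol(D))
  ss_D <- sum(D^2)
  while (it < max_iter) {
    it <- it + 1L
    # C update: per-row NNLS against S (Gram/projections via BLAS)
    C <- cpp_nnls_batch(tcrossprod(S), D %*% t(S), block_of, pres_l)
    # S update: per-channel NNLS against C
    GC <- crossprod(C)
    DC <- crossprod(D, C)
    S <- t(cpp_nnls_batch(GC, DC, zero_block, all_present))
    # LOF before normalization (the compensated rescale leaves C.S unchanged):
    # ||D - CS||^2 = ||D||^2 - 2 tr(S'C'D) + tr(C'C SS')
    ss_E <- max(0, ss_D - 2 * sum(DC * t(S)) + sum(GC * tcrossprod(S)))
    # the trace identity cancels catastrophically near an exact fit; recompute
    # the residual directly when it claims (near) exactness
    if (ss_E < 1e-8 * ss_D) ss_E <- sum((D - C %*% S)^2)
    lof <- 100 * sqrt(ss_E / ss_D)
    if (constraints$normalize_S) {
      nrm <- sqrt(rowSums(S^2))
      dead <- nrm < 1e-300
      if (any(dead)) {
        warning("component(s) ", paste(which(dead), collapse = ","),
                " collapsed to zero spectrum")
        nrm[dead] <- 1
      }
      S <- S / nrm
      C <- sweep(C, 2, nrm, `*`)
    }
    lof_trace <- c(lof_trace, lof)
    if (lof < 1e-10) { converged <- TRUE; break }
    if (it >= 2L) {
      rel <- abs(lof_trace[it - 1L] - lof) / lof_trace[it - 1L] * 100
      if (rel < tol) { converged <- TRUE; break }
    }
  }
  structure(list(C = C, S_t = S, presence = pres_l, lof_trace = lof_trace,
                 n_iter = it, converged = converged,
                 blocks = multiset$blocks, index = multiset$index,
                 shapes = multiset$shapes, axis = multiset$axis),
            class = "mcr_model")
}

#' @export
print.mcr_model <- function(x, ...) {
  cat(sprintf("<mcr_model: k=%d, %d rows, %d iter, LOF %.4g%%, %s>\n",
              nrow(x$S_t), nrow(x$C), x$n_iter, tail(x$lof_trace, 1),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Estimate per-image component presence from an unconstrained fit
#'
#' Automates the map inspection that identifies components absent from some
#' images: component k is declared present in image i when the mean of its
#' concentration over the image's block reaches `rel_threshold` times the
#' largest such mean across images. Every image keeps at least one present
#' component.
#'
#' @param model an [mcr_als_fit()] result (fitted without correspondence)
#' @param multiset the fitted multiset (unused besides validation; the model
#'   carries the block structure)
#' @param rel_threshold fraction of the per-component maximum block mean
#' @return logical matrix n_images x k
#' @export
estimate_presence <- function(model, multiset = NULL, rel_threshold = 0.01) {
  stopifnot(inherits(model, "mcr_model"))
  n_img <- nrow(model$blocks)
  k <- ncol(model$C)
  means <- matrix(0, n_img, k)
  for (bi in seq_len(n_img)) {
    rows <- seq.int(model$blocks$start[bi], model$blocks$end[bi])
    means[bi, ] <- colMeans(model$C[rows, , drop = FALSE])
  }
  mx <- apply(means, 2, max)
  pres <- sweep(means, 2, pmax(mx, .Machine$double.xmin), `/`) >= rel_threshold
  if (rel_threshold <= 0) pres[] <- TRUE
  for (bi in seq_len(n_img))
    if (!any(pres[bi, ])) pres[bi, which.max(means[bi, ])] <- TRUE
  rownames(pres) <- model$blocks$image_id
  pres
}

#' Match estimated components to ground truth
#'
#' Optimal one-to-one assignment maximizing the total Pearson correlation
#' between estimated and true pure spectra (bitmask dynamic program, exact
#' for the small k used here; ties broken toward the lowest index).
#'
#' @param estimated an [mcr_als_fit()] result or a k x channels matrix
#' @param truth a [ground_truth()] or a k x channels matrix
#' @return list with `perm` (perm[j] = estimated component assigned to true
#'   component j), `correlations` (per matched pair), `corr_matrix`
#' @export
match_components <- function(estimated, truth) {
  Se <- if (inherits(estimated, "mcr_model")) estimated$S_t else as.matrix(estimated)
  St <- if (inherits(truth, "ground_truth")) truth$pure_spectra else as.matrix(truth)
  if (nrow(Se) != nrow(St))
    stop("component count mismatch: ", nrow(Se), " vs ", nrow(St))
  k <- nrow(Se)
  CM <- matrix(0, k, k)  # CM[t, e] = cor(truth t, estimate e)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    a <- St[i, ]; b <- Se[j, ]
    CM[i, j] <- if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
  }
  # DP over subsets of estimated components; truth components in order
  nstates <- bitwShiftL(1L, k)
  best <- rep(-Inf, nstates); best[1] <- 0
  choice <- matrix(NA_integer_, nstates, k)
  prev <- rep(NA_integer_, nstates)
  # forward DP: process truth component t = popcount(state)
  ord <- order(vapply(0:(nstates - 1), function(s) sum(bitwAnd(s, bitwShiftL(1L, 0:(k - 1))) > 0), numeric(1)))
  states <- (0:(nstates - 1))[ord]
  parent <- rep(NA_integer_, nstates); pick <- rep(NA_integer_, nstates)
  for (s in states) {
    if (!is.finite(best[s + 1])) next
    t <- sum(bitwAnd(s, bitwShiftL(1L, 0:(k - 1))) > 0)
    if (t >= k) next
    for (e in seq_len(k)) {
      bit <- bitwShiftL(1L, e - 1L)
      if (bitwAnd(s, bit) > 0) next
      ns <- bitwOr(s, bit)
      val <- best[s + 1] + CM[t + 1, e]
      if (val > best[ns + 1] + 1e-15) {
        best[ns + 1] <- val; parent[ns + 1] <- s; pick[ns + 1] <- e
      }
    }
  }
  perm <- integer(k)
  s <- nstates - 1L
  for (t in k:1) {
    perm[t] <- pick[s + 1]
    s <- parent[s + 1]
  }
  list(perm = perm,
       correlations = CM[cbind(seq_len(k), perm)],
       corr_matrix = CM)
}

#' Full resolution pipeline for an image series
#'
#' Truncate to the analysis window, optionally AsLS-correct, augment into a
#' multiset, estimate the rank from the SVD scree (unless `k` is given),
#' compute SIMPLISMA initial spectra, run a preliminary MCR-ALS under
#' non-negativity and normalization, derive the presence matrix from its
#' maps, and refit under the correspondence-of-species constraint.
#'
#' @param images ordered list of [spectral_image()]
#' @param k number of components; `NULL` to select by the scree gap
#' @param window analysis window `c(lo, hi)` in cm^-1; `NULL` to skip
#' @param asls an [asls_params()] or `NULL` to skip baseline correction
#' @param presence optional known presence matrix; when given, the
#'   preliminary fit and presence estimation are skipped
#' @param rel_threshold threshold for [estimate_presence()]
#' @param tol,max_iter passed to [mcr_als_fit()]
#' @param direction multiset direction label
#' @return list with `model` (constrained fit), `model_unconstrained`
#'   (`NULL` when `presence` was supplied), `presence`, `sv`, `k`,
#'   `multiset`
#' @export
resolve_images <- function(images, k = NULL, window = c(1200, 1750),
                           asls = asls_params(), presence = NULL,
                           rel_threshold = 0.25, tol = 0.1, max_iter = 50L,
                           direction = "cross") {
  if (!is.null(window))
    images <- lapply(images, truncate_range, lo = window[1], hi = window[2])
  if (!is.null(asls))
    images <- lapply(images, correct_image, params = asls)
  mset <- augment(images, direction = direction)
  sv <- svd_scree(mset)
  if (is.null(k)) k <- select_rank(sv, method = "gap")
  S0 <- simplisma_init(mset, k)
  model0 <- NULL
  if (is.null(presence)) {
    # the preliminary unconstrained fit only feeds the presence estimate,
    # so a moderate iteration budget suffices
    model0 <- mcr_als_fit(mset, S0, mcr_constraints(), tol = 0.1,
                          max_iter = min(max_iter, 50L))
    presence <- estimate_presence(model0, mset, rel_threshold = rel_threshold)
  }
  model <- mcr_als_fit(mset, S0, mcr_constraints(correspondence = presence),
                       tol = tol, max_iter = max_iter)
  list(model = model, model_unconstrained = model0, presence = presence,
       sv = sv, k = k, multiset = mset)
}
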