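# Independent oracles used by the test suite. These deliberately use dense
# linear algebra / exhaustive enumeration, not the package's solvers.

# dense AsLS fixed-point iteration (reference for the banded C++ path)
asls_dense <- function(y, lam, p, max_iter = 10) {
  n <- length(y)
  D2 <- diff(diag(n), differences = 2)
  P <- lam * crossprod(D2)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(max_iter)) {
    z <- solve(diag(w) + P, w * y)
    wn <- ifelse(y > z, p, 1 - p)
    if (all(wn == w)) break
    w <- wn
  }
  as.numeric(z)
}

# dense weighted Whittaker solve
whittaker_dense <- function(y, w, lam) {
  n <- length(y)
  D2 <- diff(diag(n), differences = 2)
  as.numeric(solve(diag(w) + lam * crossprod(D2), w * y))
}

# brute-force NNLS: enumerate all supports, keep feasible stationary points
nnls_brute <- function(A, b) {
  n <- ncol(A)
  best <- rep(0, n)
  best_r <- sum(b^2)
  for (m in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    Ai <- A[, idx, drop = FALSE]
    x <- tryCatch(qr.solve(Ai, b), error = function(e) NULL)
    if (is.null(x) || any(x < -1e-10)) next
    r <- sum((Ai %*% x - b)^2)
    if (r < best_r - 1e-12) {
      best_r <- r
      best <- rep(0, n)
      best[idx] <- x
    }
  }
  best
}

# exhaustive SIMPLISMA selection: recompute purity and determinant weights
# naively for every row at every step
simplisma_brute <- function(D, k, alpha_pct = 1) {
  n <- nrow(D)
  mu <- rowMeans(D)
  sg <- sqrt(pmax(rowMeans(D^2) - mu^2, 0))
  alpha <- alpha_pct / 100 * max(mu)
  p1 <- sg / (mu + alpha)
  Z <- D / sqrt(mu^2 + (sg + alpha)^2)
  nchan <- ncol(D)
  sel <- integer(0)
  for (step in seq_len(k)) {
    score <- vapply(seq_len(n), function(i) {
      if (i %in% sel) return(-Inf)
      if (!length(sel)) return(p1[i])
      M <- tcrossprod(Z[c(i, sel), , drop = FALSE]) / nchan
      max(det(M), 0) * p1[i]
    }, numeric(1))
    sel <- c(sel, which.max(score))
  }
  sel
}

# factorial-enumeration component matcher
match_brute <- function(Se, St) {
  k <- nrow(Se)
  CM <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) CM[i, j] <- cor(St[i, ], Se[j, ])
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      rest <- perms(v[-i])
      out <- c(out, lapply(rest, function(r) c(v[i], r)))
    }
    out
  }
  best <- NULL; best_s <- -Inf
  for (p in perms(seq_len(k))) {
    s <- sum(CM[cbind(seq_len(k), p)])
    if (s > best_s + 1e-15) { best_s <- s; best <- p }
  }
  best
}

# unfold a ground_truth's concentration arrays in multiset row order
truth_C <- function(truth) {
  do.call(rbind, lapply(truth$concentrations, function(a) {
    matrix(aperm(a, c(3, 2, 1)), nrow = prod(dim(a)[1:2]), byrow = TRUE)
  }))
}

# wrap a plain matrix (rows x channels) as a single-block multiset
mset_from_matrix <- function(D, axis = seq_len(ncol(D))) {
  cube <- array(0, dim = c(nrow(D), 1, ncol(D)))
  cube[, 1, ] <- D
  augment(list(spectral_image(cube, axis, meta = list(section = "m1"))))
}

# per-component relative map error after optimal scaling
scaled_relerr <- function(c_est, c_true) {
  s <- sum(c_est * c_true) / max(sum(c_est^2), 1e-300)
  sqrt(sum((s * c_est - c_true)^2) / sum(c_true^2))
}

# small default-geometry scene, used across tests
tiny_scene <- function(...) {
  scene_params(n_images = 2, image_shape = c(10, 10),
               axis = seq(1200, 1750, by = 10), noise_sd = 0,
               baseline_amplitude = 0, ...)
}
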