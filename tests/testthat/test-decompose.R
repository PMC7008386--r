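scene_k3 <- function(...) {
  scene_params(n_images = 3, image_shape = c(16, 16),
               profiles = c("cellulose", "lumen_blank", "extractives"),
               noise_sd = 0, baseline_amplitude = 0, ...)
}

test_that("svd_scree exposes the exact rank of noiseless multisets", {
  sim <- simulate_multiset(scene_k3(seed = 5))
  mset <- augment(sim$images)
  sv <- svd_scree(mset)
  expect_equal(sum(sv > 1e-8 * sv[1]), 3)
  # zero data -> all-zero singular values
  expect_true(all(svd_scree(matrix(0, 5, 4)) == 0))
  # appending a duplicated image leaves the numerical rank unchanged
  mset2 <- augment(c(sim$images, sim$images[1]))
  sv2 <- svd_scree(mset2)
  expect_equal(sum(sv2 > 1e-8 * sv2[1]), 3)
  expect_error(svd_scree(matrix(numeric(0), 0, 0)), "empty")
})

test_that("select_rank implements gap, noise_floor and manual rules", {
  expect_equal(select_rank(c(100, 50, 40, 0.1, 0.08), method = "gap"), 3)
  expect_equal(select_rank(c(10, 1), method = "gap"), 1)
  expect_error(select_rank(5, method = "gap"), "at least 2")
  expect_error(select_rank(c(1, 2, 3), method = "gap"), "descending")
  expect_equal(select_rank(c(9, 5, 1), method = "manual", k = 5), 5)
  expect_error(select_rank(c(9, 5, 1), method = "manual"), "needs k")
  # noise floor: strong rank-3 signal + known noise
  set.seed(8)
  m <- 300; n <- 60; sdn <- 0.05
  D <- matrix(runif(m * 3), m) %*% matrix(runif(3 * n), 3) +
    matrix(rnorm(m * n, sd = sdn), m)
  sv <- svd(D, nu = 0, nv = 0)$d
  expect_equal(select_rank(sv, noise_sd = sdn, method = "noise_floor",
                           dims = c(m, n)), 3)
  # the default synthetic scene at low noise yields the designed rank
  sim <- simulate_multiset(scene_params(noise_sd = 1e-3,
                                        baseline_amplitude = 0, seed = 1))
  expect_equal(select_rank(svd_scree(augment(sim$images)), method = "gap"), 5)
})

test_that("SIMPLISMA selects planted pure pixels first and matches the oracle", {
  axis <- seq(1200, 1400, by = 4)
  s1 <- exp(-4 * log(2) * ((axis - 1250) / 20)^2)
  s2 <- exp(-4 * log(2) * ((axis - 1350) / 20)^2)
  set.seed(3)
  mix <- t(sapply(runif(20, 0.25, 0.75), function(a) a * s1 + (1 - a) * s2))
  D <- rbind(mix[1:10, ], 0.9 * s1, mix[11:20, ], 1.1 * s2) +
    matrix(rnorm(22 * length(axis), sd = 1e-4), 22)
  D[D < 0] <- 0
  S0 <- simplisma_init(mset_from_matrix(D, axis), 2)
  sel <- attr(S0, "selected")
  expect_setequal(sel, c(11, 22))
  expect_equal(sel, simplisma_brute(D, 2))
  # k = 1 equals exhaustive purity maximization
  S1 <- simplisma_init(mset_from_matrix(D, axis), 1)
  expect_equal(attr(S1, "selected"), simplisma_brute(D, 1))
  # rows are clipped and unit-normalized
  expect_equal(unname(sqrt(rowSums(S0^2))), c(1, 1), tolerance = 1e-12)
})

test_that("a constant row has finite purity and is never selected early", {
  axis <- seq_len(30)
  set.seed(4)
  D <- rbind(matrix(runif(5 * 30), 5), rep(0.5, 30))
  S0 <- simplisma_init(mset_from_matrix(D, axis), 3)
  expect_false(6 %in% attr(S0, "selected"))
})

test_that("simplisma_init warns when k exceeds the numerical rank", {
  D <- outer(1:8, seq(0.1, 1, length.out = 6))  # rank 1
  expect_warning(simplisma_init(mset_from_matrix(D), 3), "numerical rank")
})

test_that("NNLS equals brute-force support enumeration", {
  set.seed(11)
  for (case in 1:30) {
    n <- sample(2:6, 1)
    m <- n + sample(2:6, 1)
    A <- matrix(rnorm(m * n), m)
    b <- rnorm(m)
    x <- nnls(A, b)
    xb <- nnls_brute(A, b)
    expect_equal(sum((A %*% x - b)^2), sum((A %*% xb - b)^2), tolerance = 1e-8)
    expect_equal(x, xb, tolerance = 1e-6)
    expect_true(all(x >= 0))
  }
})

test_that("lack_of_fit reproduces the worked examples", {
  D <- matrix(c(2, 0, 0, 2), 2)
  C1 <- diag(2)
  expect_equal(lack_of_fit(D, D, diag(2)), 0)                   # E = 0
  expect_equal(lack_of_fit(D, matrix(0, 2, 2), diag(2)), 100)   # zero model
  expect_equal(lack_of_fit(D, C1, diag(2)), 50)                 # sqrt(2/8)
  expect_error(lack_of_fit(matrix(0, 2, 2), C1, diag(2)), "all zero")
})

test_that("MCR-ALS is exact at the truth and recovers a k=3 scene", {
  sim <- simulate_multiset(scene_k3(seed = 1))
  mset <- augment(sim$images)
  # initialized at the true spectra, the first iteration is already exact
  m0 <- mcr_als_fit(mset, sim$truth$pure_spectra, max_iter = 1)
  expect_lt(m0$lof_trace[1], 1e-6)
  # SIMPLISMA initialization converges to the truth
  S0 <- simplisma_init(mset, 3)
  m <- mcr_als_fit(mset, S0, tol = 1e-4, max_iter = 200)
  expect_lt(tail(m$lof_trace, 1), 0.1)
  mt <- match_components(m, sim$truth)
  expect_true(all(mt$correlations > 0.999))
  expect_true(all(m$C >= 0))
  expect_true(all(m$S_t >= 0))
  expect_equal(unname(sqrt(rowSums(m$S_t^2))), rep(1, 3), tolerance = 1e-10)
})

test_that("mcr_als_fit validates its inputs", {
  sim <- simulate_multiset(scene_k3(seed = 2))
  mset <- augment(sim$images)
  S0 <- sim$truth$pure_spectra
  S0bad <- S0; S0bad[2, ] <- 0
  expect_error(mcr_als_fit(mset, S0bad), "all-zero row")
  wide <- matrix(1, ncol(mset$data) + 1, ncol(mset$data))
  expect_error(mcr_als_fit(mset, wide), "exceeds the number of channels")
  expect_error(mcr_als_fit(mset, S0[, -1]), "channel count")
  expect_error(mcr_als_fit(mset, S0,
                           mcr_constraints(correspondence = matrix(TRUE, 2, 3))),
               "n_images x k")
})

test_that("correspondence forces exact zeros that refold to zero maps", {
  sim <- simulate_multiset(scene_k3(seed = 6))
  mset <- augment(sim$images)
  pres <- matrix(TRUE, 3, 3)
  pres[1, 2] <- FALSE   # declare component 2 absent in image 1
  m <- mcr_als_fit(mset, sim$truth$pure_spectra,
                   mcr_constraints(correspondence = pres), max_iter = 5)
  rows1 <- seq.int(m$blocks$start[1], m$blocks$end[1])
  expect_true(all(m$C[rows1, 2] == 0))
  map <- refold(mset, m$C[, 2], 1)
  expect_true(all(map[!is.na(map)] == 0))
  # re-fitting from the fitted spectra never violates the zero blocks
  m2 <- mcr_als_fit(mset, m$S_t, mcr_constraints(correspondence = pres),
                    max_iter = 5)
  expect_true(all(m2$C[rows1, 2] == 0))
})

test_that("the LOF trace is non-increasing on random instances", {
  set.seed(19)
  for (case in 1:20) {
    n <- 30; nch <- 12; k <- 3
    C <- matrix(runif(n * k), n)
    S <- matrix(runif(k * nch), k)
    D <- C %*% S + matrix(rnorm(n * nch, sd = 0.05), n)
    D[D < 0] <- 0
    mset <- mset_from_matrix(D)
    S0 <- matrix(runif(k * nch) + 0.1, k)
    m <- suppressWarnings(mcr_als_fit(mset, S0, tol = 0, max_iter = 30))
    lt <- m$lof_trace
    expect_true(all(diff(lt) <= lt[-length(lt)] * 1e-8 + 1e-12))
  }
})

test_that("estimate_presence flags absent components and keeps one per image", {
  sim <- simulate_multiset(scene_params(seed = 2))
  mset <- augment(sim$images)
  Ct <- truth_C(sim$truth)
  set.seed(9)
  Cn <- pmax(Ct + matrix(rnorm(length(Ct), sd = 0.003), nrow(Ct)), 0)
  fake <- structure(list(C = Cn, blocks = mset$blocks), class = "mcr_model")
  pres <- estimate_presence(fake, rel_threshold = 0.01)
  expect_identical(unname(pres), unname(sim$truth$presence))
  # a uniform component is present everywhere
  expect_true(all(pres[, 1]))
  # degenerate threshold: everything present
  expect_true(all(estimate_presence(fake, rel_threshold = 0)))
  # the guarantee: even with an absurd threshold each image keeps a component
  pres_hi <- estimate_presence(fake, rel_threshold = 1)
  expect_true(all(rowSums(pres_hi) >= 1))
})

test_that("match_components finds the optimal assignment", {
  sim <- simulate_multiset(scene_params(seed = 3))
  St <- sim$truth$pure_spectra
  idm <- match_components(St, St)
  expect_equal(idm$perm, 1:5)
  expect_equal(idm$correlations, rep(1, 5))
  shuf <- c(3, 1, 5, 2, 4)
  sw <- match_components(St[shuf, ], St)
  expect_equal(sw$perm, order(shuf))
  expect_equal(sw$correlations, rep(1, 5))
  # noisy estimates agree with factorial enumeration
  set.seed(10)
  Se <- pmax(St[shuf, ] + matrix(rnorm(length(St), sd = 0.02), 5), 0)
  expect_equal(match_components(Se, St)$perm, match_brute(Se, St))
  expect_error(match_components(St[1:3, ], St), "mismatch")
})
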