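test_that("truncate_range keeps exactly the requested window", {
  nch <- length(seq(800, 4000, by = 2))
  cube <- array(runif(2 * 2 * nch), dim = c(2, 2, nch))
  im <- spectral_image(cube, seq(800, 4000, by = 2))
  tr <- truncate_range(im, 1200, 1750)
  expect_equal(dim(tr$cube)[3], 276)
  expect_equal(range(tr$axis), c(1200, 1750))
  expect_equal(tr$meta$window, c(1200, 1750))
  # identity when the window covers the axis
  full <- truncate_range(im, 700, 4100)
  expect_identical(full$cube, im$cube)
  # idempotent
  tr2 <- truncate_range(tr, 1200, 1750)
  expect_identical(tr2$cube, tr$cube)
  expect_error(truncate_range(im, 2000, 1000), "lo must be")
  expect_error(truncate_range(im, 4500, 5000), "does not overlap")
})

test_that("AsLS returns a constant baseline for constant input", {
  y <- rep(3.7, 40)
  z <- asls_baseline(y, asls_params(p = 0.5))
  expect_equal(as.numeric(z), y, tolerance = 1e-8)
})

test_that("AsLS banded solver agrees with the dense oracle", {
  set.seed(42)
  for (case in 1:6) {
    n <- sample(20:50, 1)
    y <- cumsum(rnorm(n, sd = 0.3)) + 2 * exp(-((seq_len(n) - n / 2)^2) / 8)
    lam <- sample(c(1e2, 1e4, 1e5), 1)
    p <- sample(c(0.001, 0.05, 0.5), 1)
    z <- asls_baseline(y, asls_params(lam = lam, p = p, max_iter = 10))
    expect_equal(as.numeric(z), asls_dense(y, lam, p, 10), tolerance = 1e-8)
  }
})

test_that("AsLS with p = 0.5 equals the symmetric Whittaker smoother", {
  set.seed(1)
  y <- sin(seq(0, 3, length.out = 60)) + rnorm(60, sd = 0.05)
  z <- asls_baseline(y, asls_params(lam = 1e3, p = 0.5))
  expect_equal(as.numeric(z), whittaker_dense(y, rep(0.5, 60), 1e3),
               tolerance = 1e-10)
})

test_that("whittaker_smooth matches a dense solve for arbitrary weights", {
  set.seed(5)
  y <- rnorm(45); w <- runif(45, 0.1, 1)
  expect_equal(whittaker_smooth(y, w, 500), whittaker_dense(y, w, 500),
               tolerance = 1e-8)
})

test_that("slow scatter oscillations are removed to within 5% of amplitude", {
  axis <- seq(1200, 1750, by = 2)
  for (phi in c(0, 1.3, 3.1, 4.7)) {
    y <- 0.5 * (1 + cos(phi + 2 * pi * (axis - 1200) / 4000))
    z <- asls_baseline(y, asls_params())
    expect_lt(max(abs(y - z)), 0.05)
  }
})

test_that("an isolated peak survives AsLS nearly intact", {
  axis <- seq(1200, 1750, by = 2)
  y <- exp(-4 * log(2) * ((axis - 1475) / 30)^2)  # height 1, fwhm 30
  z <- asls_baseline(y, asls_params())
  expect_lt(max(z[abs(axis - 1475) < 30]), 0.05)
  corrected <- y - z
  expect_lt(abs(max(corrected) - 1), 0.05)
})

test_that("baseline fraction above the signal is bounded by the asymmetry", {
  axis <- seq(1200, 1750, by = 2)
  y <- exp(-4 * log(2) * ((axis - 1350) / 25)^2) +
    0.6 * exp(-4 * log(2) * ((axis - 1600) / 25)^2)
  z <- asls_baseline(y, asls_params(p = 0.001))
  # z exceeds y only by spline-tail amounts (<0.1% of peak); meaningful
  # exceedances are bounded by the asymmetry weight
  expect_lt(mean(z > y + 0.005 * max(y)), 0.05)
  expect_lt(max(z - y), 0.001 * max(y))
})

test_that("correct_image recovers generated baselines and is consistent", {
  sc <- scene_params(n_images = 1, image_shape = c(8, 8), noise_sd = 0,
                     baseline_amplitude = 0.02, seed = 14)
  sim <- simulate_multiset(sc)
  out <- correct_image(sim$images[[1]], asls_params(), return_baselines = TRUE)
  zb <- attr(out, "baselines")
  err <- abs(zb - sim$truth$baselines[[1]])
  # AsLS removes the bulk (offset and tilt) of the oscillation; residual
  # curvature mismatch stays well under half the amplitude
  expect_lt(mean(err), 0.5 * sc$baseline_amplitude)
  expect_lt(max(err), 2.5 * sc$baseline_amplitude)
  # single-pixel image equals asls_baseline on that spectrum
  px <- sim$images[[1]]$cube[3, 3, , drop = FALSE]
  one <- spectral_image(array(px, dim = c(1, 1, length(sc$axis))), sc$axis)
  cone <- correct_image(one, asls_params())
  z1 <- asls_baseline(as.numeric(px), asls_params())
  expect_equal(cone$cube[1, 1, ], as.numeric(px) - as.numeric(z1),
               tolerance = 1e-12)
})

test_that("a baseline-free image is nearly unchanged by correction", {
  sc <- scene_params(n_images = 1, image_shape = c(8, 8), noise_sd = 0,
                     baseline_amplitude = 0, seed = 15)
  sim <- simulate_multiset(sc)
  out <- correct_image(sim$images[[1]], asls_params())
  dev <- abs(out$cube - sim$images[[1]]$cube)
  mx <- max(sim$images[[1]]$cube)
  # AsLS hugs the lower envelope, so band-dense pixels lose a small offset;
  # the deviation stays a few percent of the peak absorbance and the median
  # channel is essentially untouched
  expect_lt(max(dev), 0.10 * mx)
  expect_lt(median(dev), 0.02 * mx)
})

test_that("correct_image leaves invalid pixels untouched", {
  sc <- scene_params(n_images = 1, image_shape = c(6, 6), noise_sd = 0,
                     saturation_fraction = 0.2, seed = 16)
  sim <- simulate_multiset(sc)
  im <- sim$images[[1]]
  out <- correct_image(im, asls_params())
  expect_identical(out$mask, im$mask)
  bad <- which(!im$mask, arr.ind = TRUE)
  for (i in seq_len(nrow(bad)))
    expect_identical(out$cube[bad[i, 1], bad[i, 2], ], im$cube[bad[i, 1], bad[i, 2], ])
})

test_that("asls_baseline validates input", {
  expect_error(asls_baseline(c(1, 2, 3), asls_params()), "at least 4")
  expect_error(asls_baseline(c(1, 2, NA, 4, 5), asls_params()), "non-finite")
  expect_error(asls_params(lam = 0), "lam")
  expect_error(asls_params(p = 1), "p must be")
})

test_that("Savitzky-Golay reproduces quadratics and smooths noise", {
  x <- seq_len(60)
  y <- 2 + 0.3 * x - 0.01 * x^2
  s <- savgol_smooth(y, window = 15, degree = 2)
  expect_equal(s[8:53], y[8:53], tolerance = 1e-10)
  # white noise variance strictly decreases (several seeds)
  for (seed in 1:5) {
    set.seed(seed)
    e <- rnorm(200)
    expect_lt(var(savgol_smooth(e, 15, 2)), var(e))
  }
  expect_error(savgol_smooth(rnorm(10), 15, 2), "larger than input")
  expect_error(savgol_smooth(rnorm(30), 14, 2), "odd")
  expect_error(savgol_smooth(rnorm(30), 15, 15), "degree")
})
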