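test_that("band libraries carry the marker bands of each constituent", {
  centers <- function(p) vapply(build_band_library(p), `[[`, numeric(1), "center")
  expect_true(1660 %in% centers("lignin_sw"))
  expect_false(1640 %in% centers("lignin_sw"))
  expect_true(1640 %in% centers("lignin_hw"))
  expect_false(1660 %in% centers("lignin_hw"))
  expect_true(all(c(1317, 1336, 1368, 1423) %in% centers("cellulose")))
  expect_true(all(c(1640, 1660, 1728) %in% centers("extractives")))
  expect_error(build_band_library("pectin"), "cellulose")
})

test_that("render_pure_spectra renders normalized, unimodal-consistent rows", {
  axis <- seq(1200, 1750, by = 1)
  one <- list(list(band_spec(1510, 20, 1)))
  S <- render_pure_spectra(one, axis)
  expect_equal(axis[which.max(S[1, ])], 1510)
  libs <- lapply(c("cellulose", "lignin_sw", "extractives"), build_band_library)
  S2 <- render_pure_spectra(libs, axis)
  expect_equal(unname(sqrt(rowSums(S2^2))), rep(1, 3), tolerance = 1e-12)
  expect_true(all(S2 >= 0))
  # two disjoint equal bands -> two equal local maxima
  twin <- list(list(band_spec(1300, 10, 0.5), band_spec(1600, 10, 0.5)))
  St <- render_pure_spectra(twin, axis)
  expect_equal(St[1, axis == 1300], St[1, axis == 1600], tolerance = 1e-12)
  expect_error(render_pure_spectra(list(), axis), "empty")
  expect_error(render_pure_spectra(one, c(1200, 1190, 1210)), "monotonic")
})

test_that("tissue maps honor presence, lumen confinement and determinism", {
  sc <- scene_params(seed = 11)
  # absent component -> all-zero map (lignin_hw absent in image 1)
  expect_true(all(render_tissue_maps(sc, 5, 1) == 0))
  # lumen_blank nonzero exactly inside lumen holes
  m <- render_tissue_maps(sc, 2, 1)
  masks <- tissue_masks(sc$image_shape, sc$tissue_geometry)
  expect_true(all(m[masks$lumen] > 0))
  expect_true(all(m[!masks$lumen] == 0))
  # determinism
  expect_identical(render_tissue_maps(sc, 1, 3), render_tissue_maps(sc, 1, 3))
  expect_error(render_tissue_maps(sc, 6, 1), "component_index")
  expect_error(render_tissue_maps(sc, 1, 9), "image_index")
})

test_that("zero-noise zero-baseline cubes equal the bilinear product exactly", {
  sc <- tiny_scene(seed = 21)
  sim <- simulate_multiset(sc)
  S <- sim$truth$pure_spectra
  for (i in seq_along(sim$images)) {
    a <- sim$truth$concentrations[[i]]
    Cm <- matrix(aperm(a, c(3, 2, 1)), nrow = prod(dim(a)[1:2]), byrow = TRUE)
    got <- unfold(sim$images[[i]])$data
    expect_equal(got, Cm %*% S, tolerance = 0)
  }
  # and the ground-truth factorization has exactly zero lack of fit
  mset <- augment(sim$images)
  expect_equal(lack_of_fit(mset$data, truth_C(sim$truth), S), 0, tolerance = 1e-12)
})

test_that("default presence places both lignins in the transition ring", {
  sc <- scene_params(seed = 1)
  p <- sim <- simulate_multiset(sc)$truth$presence
  expect_true(p[5, 4] && p[5, 5])        # ring 5: sw and hw both present
  expect_true(all(p[1:4, 4]) && !any(p[6:8, 4]))
  expect_true(all(p[5:8, 5]) && !any(p[1:4, 5]))
  expect_true(all(p[, 1:3]))
  expect_true(all(rowSums(p) >= 1))
})

test_that("saturation masks about the requested fraction of pixels", {
  sc <- scene_params(n_images = 2, image_shape = c(64, 64),
                     saturation_fraction = 0.1, seed = 33)
  sim <- simulate_multiset(sc)
  n_masked <- sum(vapply(sim$images, function(im) sum(!im$mask), numeric(1)))
  n_px <- 2 * 64 * 64
  # binomial(8192, 0.1): allow 5 standard deviations
  expect_lt(abs(n_masked - 0.1 * n_px), 5 * sqrt(n_px * 0.1 * 0.9))
  # masked pixels never reach the multiset
  mset <- augment(sim$images)
  expect_equal(nrow(mset$data), n_px - n_masked)
})

test_that("simulation is seed-deterministic and presence matches zero pattern", {
  a <- simulate_multiset(scene_params(seed = 7))
  b <- simulate_multiset(scene_params(seed = 7))
  d <- simulate_multiset(scene_params(seed = 8))
  expect_identical(a$images[[3]]$cube, b$images[[3]]$cube)
  expect_identical(a$truth$pure_spectra, b$truth$pure_spectra)
  expect_false(identical(a$images[[3]]$cube, d$images[[3]]$cube))
  for (i in seq_along(a$images)) {
    nonzero <- apply(a$truth$concentrations[[i]], 3, function(m) any(m > 0))
    expect_identical(nonzero, unname(a$truth$presence[i, ]))
  }
  expect_true(all(a$truth$pure_spectra >= 0))
  expect_true(all(vapply(a$truth$concentrations, function(x) all(x >= 0), logical(1))))
})

test_that("simulate_multiset validates the axis and scene invariants", {
  sc7 <- scene_params(n_images = 2, image_shape = c(10, 10), noise_sd = 0,
                      baseline_amplitude = 0, axis = seq(1200, 1212, by = 2))
  expect_error(simulate_multiset(sc7), "at least 8 channels")
  expect_error(scene_params(noise_sd = -1), "noise_sd")
  expect_error(scene_params(saturation_fraction = 1), "saturation_fraction")
  # an image with no present component is rejected
  pres <- default_presence(3, c("cellulose", "lignin_sw"), 2)
  pres[3, ] <- FALSE
  expect_error(scene_params(n_images = 3, profiles = c("cellulose", "lignin_sw"),
                            presence = pres), "at least one present")
})

test_that("scene config reader rebuilds scene_params", {
  f <- tempfile(fileext = ".cfg")
  writeLines(c("# demo scene", "n_images: 3", "image_shape: 8, 9",
               "axis: 1200, 1750, 10", "noise_sd: 0", "baseline_amplitude: 0",
               "transition_ring: 2", "seed: 4"), f)
  sc <- read_scene_config(f)
  expect_s3_class(sc, "scene_params")
  expect_equal(sc$n_images, 3L)
  expect_equal(sc$image_shape, c(8L, 9L))
  expect_equal(length(sc$axis), 56)
  sc2 <- read_scene_config(f, seed = 99)
  expect_equal(sc2$seed, 99L)
})

test_that("ground truth serializes to a text container", {
  sim <- simulate_multiset(tiny_scene(seed = 3))
  td <- tempfile()
  save_ground_truth(sim$truth, td)
  S <- as.matrix(read.table(file.path(td, "pure_spectra.tsv"), sep = "\t"))
  dimnames(S) <- NULL
  expect_equal(S, unname(sim$truth$pure_spectra), tolerance = 0)
  pres <- as.matrix(read.table(file.path(td, "presence.tsv"), sep = "\t"))
  expect_equal(unname(pres == 1), unname(sim$truth$presence))
})
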