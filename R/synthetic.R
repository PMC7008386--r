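#' Synthetic scene parameters
#'
#' Describes a simulated annual-ring series of wood-section FTIR images with
#' known ground truth. Defaults emulate the measurement situation the
#' analysis assumes: 8 images (rings, sapwood to heartwood), a
#' 1200-1750 cm^-1 window at 2 cm^-1 spacing (276 channels), five
#' constituents (cellulose, lumen blank, extractives, sapwood lignin,
#' heartwood lignin), sapwood lignin present in rings 1..transition_ring and
#' heartwood lignin from transition_ring onward, a broad Mie-like raised
#' cosine baseline, homoscedastic additive noise, and optional saturated
#' pixels flagged invalid.
#'
#' @param n_images number of ring images
#' @param image_shape c(rows, cols) in pixels; default 32 x 32
#' @param axis ascending wavenumber grid (cm^-1)
#' @param profiles character vector of constituent profiles (see
#'   [build_band_library()]); its length sets the number of components
#' @param presence logical matrix n_images x n_components; default derived
#'   from `transition_ring`
#' @param transition_ring ring at which heartwood lignin appears (and beyond
#'   which sapwood lignin disappears); both are present at the transition
#'   ring itself
#' @param tissue_geometry list: `ray_center`, `ray_width` (px), `wall_period`,
#'   `wall_thickness` (px) for the cell-wall lattice
#' @param baseline_amplitude a.u.; typical amplitude of the baseline
#'   oscillation (per-pixel amplitudes jitter around it)
#' @param baseline_period cm^-1; period of the raised cosine oscillation
#' @param noise_sd a.u.; standard deviation of additive i.i.d. noise
#' @param saturation_fraction proportion of pixels masked invalid
#' @param shape band line shape passed to the spectral renderer
#' @param seed integer master seed; everything the generator draws derives
#'   from it
#' @return object of class `scene_params`
#' @export
scene_params <- function(n_images = 8L,
                         image_shape = c(32L, 32L),
                         axis = seq(1200, 1750, by = 2),
                         profiles = c("cellulose", "lumen_blank", "extractives",
                                      "lignin_sw", "lignin_hw"),
                         presence = NULL,
                         transition_ring = 5L,
                         tissue_geometry = list(),
                         baseline_amplitude = 0.02,
                         baseline_period = 1000,
                         noise_sd = 0.006,
                         saturation_fraction = 0,
                         shape = "gaussian",
                         seed = 1L) {
  n_images <- as.integer(n_images)
  stopifnot(n_images >= 1L, length(image_shape) == 2L, all(image_shape >= 1))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (saturation_fraction < 0 || saturation_fraction >= 1)
    stop("saturation_fraction must be in [0, 1)")
  k <- length(profiles)
  if (is.null(presence))
    presence <- default_presence(n_images, profiles, transition_ring)
  presence <- as.matrix(presence)
  if (!identical(dim(presence), c(n_images, k)))
    stop("presence must be n_images x n_components")
  if (any(rowSums(presence) < 1))
    stop("every image must have at least one present component")
  geo <- utils::modifyList(list(ray_center = ceiling(image_shape[2] / 2),
                                ray_width = 5L, wall_period = 10L,
                                wall_thickness = 2L), tissue_geometry)
  structure(list(n_images = n_images, image_shape = as.integer(image_shape),
                 axis = axis, profiles = profiles, n_components = k,
                 presence = presence, transition_ring = as.integer(transition_ring),
                 tissue_geometry = geo,
                 baseline_amplitude = baseline_amplitude,
                 baseline_period = baseline_period, noise_sd = noise_sd,
                 saturation_fraction = saturation_fraction,
                 shape = shape, seed = as.integer(seed)),
            class = "scene_params")
}

#' @export
print.scene_params <- function(x, ...) {
  cat(sprintf(paste0("<scene: %d images %dx%d px, %d channels, %d components ",
                     "(%s), noise %.3g, baseline %.3g, seed %d>\n"),
              x$n_images, x$image_shape[1], x$image_shape[2], length(x$axis),
              x$n_components, paste(x$profiles, collapse = ","), x$noise_sd,
              x$baseline_amplitude, x$seed))
  invisible(x)
}

#' Default presence matrix for a ring series
#'
#' All components present everywhere, except: `lignin_sw` only in rings
#' `1..transition_ring` and `lignin_hw` only in rings
#' `transition_ring..n_images` (both present at the transition ring, where
#' heartwood formation starts).
#'
#' @param n_images number of ring images
#' @param profiles constituent profile names
#' @param transition_ring the ring where heartwood lignin first appears
#' @return logical matrix `n_images x length(profiles)`
#' @export
default_presence <- function(n_images, profiles, transition_ring = 5L) {
  k <- length(profiles)
  pres <- matrix(TRUE, n_images, k)
  colnames(pres) <- profiles
  ring <- seq_len(n_images)
  if ("lignin_sw" %in% profiles)
    pres[, profiles == "lignin_sw"] <- ring <= transition_ring
  if ("lignin_hw" %in% profiles)
    pres[, profiles == "lignin_hw"] <- ring >= transition_ring
  pres
}

#' Anatomical masks of the synthetic tissue geometry
#'
#' Splits the pixel grid into a vertical ray stripe, a periodic cell-wall
#' lattice with cell-corner pixels, and lumen holes. The ray takes
#' precedence over lattice and lumen in its columns.
#'
#' @param shape c(rows, cols)
#' @param geometry list with `ray_center`, `ray_width`, `wall_period`,
#'   `wall_thickness`
#' @return list of logical matrices `ray`, `wall`, `corner`, `lumen`
#'   (mutually exclusive, covering the grid)
#' @export
tissue_masks <- function(shape, geometry) {
  nr <- shape[1]; nc <- shape[2]
  g <- geometry
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  rows <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  ray <- abs(cols - g$ray_center) <= (g$ray_width - 1) / 2
  on_wall_r <- ((rows - 1L) %% g$wall_period) < g$wall_thickness
  on_wall_c <- ((cols - 1L) %% g$wall_period) < g$wall_thickness
  corner <- on_wall_r & on_wall_c & !ray
  wall <- (on_wall_r | on_wall_c) & !corner & !ray
  lumen <- !ray & !wall & !corner
  list(ray = ray, wall = wall, corner = corner, lumen = lumen)
}

# smooth multiplicative texture field in [1-spread, 1+spread]
texture_field <- function(nr, nc, spread = 0.3) {
  u <- matrix(runif(nr * nc), nr, nc)
  for (pass in 1:2) {
    up <- rbind(u[1, ], u[-nr, ]); dn <- rbind(u[-1, ], u[nr, ])
    lf <- cbind(u[, 1], u[, -nc]); rt <- cbind(u[, -1], u[, nc])
    u <- (u + up + dn + lf + rt) / 5
  }
  rng <- range(u)
  if (diff(rng) < .Machine$double.eps) return(matrix(1, nr, nc))
  1 - spread + 2 * spread * (u - rng[1]) / diff(rng)
}

# mean abundance per tissue class for each constituent profile
.role_weights <- list(
  cellulose   = c(ray = 0.00, wall = 1.00, corner = 0.20, lumen = 0.00),
  lumen_blank = c(ray = 0.00, wall = 0.00, corner = 0.00, lumen = 0.90),
  extractives = c(ray = 1.00, wall = 0.00, corner = 0.00, lumen = 0.00),
  lignin_sw   = c(ray = 0.35, wall = 0.45, corner = 1.20, lumen = 0.00),
  lignin_hw   = c(ray = 0.70, wall = 0.45, corner = 1.20, lumen = 0.00)
)

#' Render one component's concentration map
#'
#' Deterministic given the scene seed: the per-map random texture is drawn
#' from a substream derived from `(seed, image_index, component_index)`.
#' Returns the all-zero map when the component is absent in that image.
#'
#' @param params a [scene_params()]
#' @param component_index component (1-based)
#' @param image_index image (1-based)
#' @return non-negative `rows x cols` matrix
#' @export
render_tissue_maps <- function(params, component_index, image_index) {
  stopifnot(inherits(params, "scene_params"))
  if (component_index < 1 || component_index > params$n_components)
    stop("component_index out of range")
  if (image_index < 1 || image_index > params$n_images)
    stop("image_index out of range")
  nr <- params$image_shape[1]; nc <- params$image_shape[2]
  if (!params$presence[image_index, component_index])
    return(matrix(0, nr, nc))
  profile <- params$profiles[component_index]
  w <- .role_weights[[profile]]
  if (is.null(w)) stop("no tissue role defined for profile ", profile)
  masks <- tissue_masks(params$image_shape, params$tissue_geometry)
  base <- w["ray"] * masks$ray + w["wall"] * masks$wall +
    w["corner"] * masks$corner + w["lumen"] * masks$lumen
  tex <- with_local_seed(derive_seed(params$seed, image_index, component_index),
                         texture_field(nr, nc))
  base * tex
}

#' Ground truth of a simulated multiset
#'
#' Bundle of the generator's true pure spectra (unit 2-norm rows),
#' per-image concentration arrays, per-pixel baselines and the presence
#' matrix, for recovery tests.
#' @param pure_spectra k x channels matrix
#' @param concentrations list of rows x cols x k arrays
#' @param baselines list of rows x cols x channels arrays
#' @param presence logical n_images x k
#' @param axis wavenumber grid
#' @return object of class `ground_truth`
#' @export
ground_truth <- function(pure_spectra, concentrations, baselines, presence, axis) {
  structure(list(pure_spectra = pure_spectra, concentrations = concentrations,
                 baselines = baselines, presence = presence, axis = axis),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth: %d components, %d images, %d channels>\n",
              nrow(x$pure_spectra), length(x$concentrations), length(x$axis)))
  invisible(x)
}

#' Simulate a multiset of wood-section images with ground truth
#'
#' Each pixel spectrum is `sum_k c_k s_k + baseline + noise`: the bilinear
#' absorbance model plus a broad raised-cosine baseline oscillation with
#' random phase and per-pixel amplitude jitter, plus i.i.d. Gaussian noise.
#' A `saturation_fraction` of pixels per image is flagged invalid (their
#' spectra are set to NaN, mimicking detector saturation).
#'
#' @param params a [scene_params()]
#' @return list with elements `images` (list of [spectral_image()]) and
#'   `truth` (a [ground_truth()])
#' @export
#' @examples
#' sc <- scene_params(n_images = 2, image_shape = c(8, 8), noise_sd = 0,
#'                    baseline_amplitude = 0, seed = 42)
#' sim <- simulate_multiset(sc)
#' sim$images[[1]]
simulate_multiset <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  axis <- params$axis
  if (length(axis) < 8L) stop("axis must have at least 8 channels")
  nr <- params$image_shape[1]; nc <- params$image_shape[2]
  k <- params$n_components
  S <- render_pure_spectra(
    lapply(stats::setNames(params$profiles, params$profiles), function(p) {
      bands <- build_band_library(p)
      lapply(bands, function(b) band_spec(b$center, b$width, b$height, params$shape))
    }), axis)
  images <- vector("list", params$n_images)
  concs <- vector("list", params$n_images)
  bases <- vector("list", params$n_images)
  for (i in seq_len(params$n_images)) {
    conc <- array(0, dim = c(nr, nc, k))
    for (j in seq_len(k)) conc[, , j] <- render_tissue_maps(params, j, i)
    Cmat <- matrix(aperm(conc, c(3, 2, 1)), nrow = nr * nc, ncol = k, byrow = TRUE)
    cube_mat <- Cmat %*% S
    base <- with_local_seed(derive_seed(params$seed, i, 0L), {
      if (params$baseline_amplitude > 0) {
        phi <- runif(nr * nc, 0, 2 * pi)
        amp <- params$baseline_amplitude * runif(nr * nc, 0.75, 1.25)
        outer(amp, rep(1, length(axis))) *
          0.5 * (1 + cos(outer(phi, 2 * pi * (axis - axis[1]) / params$baseline_period,
                               `+`)))
      } else {
        matrix(0, nr * nc, length(axis))
      }
    })
    noise <- with_local_seed(derive_seed(params$seed, i, k + 1L), {
      if (params$noise_sd > 0)
        matrix(rnorm(nr * nc * length(axis), sd = params$noise_sd),
               nr * nc, length(axis))
      else matrix(0, nr * nc, length(axis))
    })
    cube_mat <- cube_mat + base + noise
    mask <- matrix(TRUE, nr, nc)
    if (params$saturation_fraction > 0) {
      sat <- with_local_seed(derive_seed(params$seed, i, k + 2L),
        which(runif(nr * nc) < params$saturation_fraction))
      if (length(sat)) {
        # row-major linear index -> (row, col)
        r_i <- (sat - 1L) %/% nc + 1L
        c_i <- (sat - 1L) %% nc + 1L
        mask[cbind(r_i, c_i)] <- FALSE
        cube_mat[sat, ] <- NaN
      }
    }
    cube <- refold_full(cube_mat, nr, nc)
    images[[i]] <- spectral_image(cube, axis, mask = mask,
                                  meta = list(section = sprintf("DX%d", i),
                                              direction = "cross", ring = i))
    concs[[i]] <- conc
    bases[[i]] <- refold_full(base, nr, nc)
  }
  names(images) <- vapply(images, function(im) im$meta$section, character(1))
  list(images = images,
       truth = ground_truth(S, concs, bases, params$presence, axis))
}

#' Write a simulated scene's ground truth to a text container
#'
#' Directory with `pure_spectra.tsv`, `presence.tsv`, `axis.tsv` and one
#' `concentration_<image>.tsv` (unfolded row-major pixels x components) per
#' image, plus `manifest.json`.
#' @param truth a [ground_truth()]
#' @param out_dir output directory
#' @return `out_dir`, invisibly
#' @export
save_ground_truth <- function(truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_matrix(truth$pure_spectra, file.path(out_dir, "pure_spectra.tsv"))
  utils::write.table(truth$presence * 1L, file.path(out_dir, "presence.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(wavenumber = fmt_num(truth$axis)),
                     file.path(out_dir, "axis.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (i in seq_along(truth$concentrations)) {
    a <- truth$concentrations[[i]]
    m <- matrix(aperm(a, c(3, 2, 1)), nrow = dim(a)[1] * dim(a)[2],
                ncol = dim(a)[3], byrow = TRUE)
    write_tsv_matrix(m, file.path(out_dir, sprintf("concentration_%02d.tsv", i)))
  }
  jsonlite::write_json(list(n_images = length(truth$concentrations),
                            n_components = nrow(truth$pure_spectra),
                            dims = dim(truth$concentrations[[1]])),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read a flat `key: value` scene configuration file
#'
#' Minimal YAML-like reader for scene configs: one `key: value` pair per
#' line, `#` comments, numeric scalars parsed, comma-separated values become
#' vectors. Recognized keys are the arguments of [scene_params()].
#' @param path config file
#' @param seed optional seed overriding the file's
#' @return a [scene_params()]
#' @export
read_scene_config <- function(path, seed = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, ":", fixed = TRUE)
  args <- list()
  for (p in kv) {
    if (length(p) < 2) next
    key <- trimws(p[1])
    val <- trimws(paste(p[-1], collapse = ":"))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    args[[key]] <- if (!any(is.na(num))) num else parts
  }
  if (!is.null(args$axis) && length(args$axis) == 3)
    args$axis <- seq(args$axis[1], args$axis[2], by = args$axis[3])
  if (!is.null(seed)) args$seed <- seed
  do.call(scene_params, args)
}
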