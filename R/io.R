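#' Hyperspectral absorbance image
#'
#' Container for one section's absorbance cube: a `rows x cols x channels`
#' array, a strictly ascending wavenumber axis, a per-pixel validity mask and
#' free-form metadata (section id, direction, ring number). Pixels whose
#' spectra are entirely non-finite are masked invalid. Invalid pixels never
#' enter a multiset.
#'
#' @param cube numeric array `rows x cols x channels` (absorbance, a.u.)
#' @param axis numeric wavenumber vector (cm^-1), strictly monotonic; stored
#'   ascending (cube is reversed along channels if needed)
#' @param mask logical `rows x cols` validity matrix; default marks all-NaN
#'   pixels invalid
#' @param meta named list of metadata (e.g. `section`, `direction`, `ring`)
#' @return object of class `spectral_image`
#' @export
spectral_image <- function(cube, axis, mask = NULL, meta = list()) {
  if (!is.array(cube) || length(dim(cube)) != 3L)
    stop("cube must be a rows x cols x channels array")
  if (dim(cube)[3] != length(axis))
    stop("channel count mismatch: cube has ", dim(cube)[3],
         " channels but axis has ", length(axis))
  dup <- axis[duplicated(axis)]
  if (length(dup)) stop("duplicated wavenumber in axis: ", dup[1])
  d <- diff(axis)
  if (length(axis) >= 2 && !(all(d > 0) || all(d < 0)))
    stop("axis is not strictly monotonic")
  reversed <- length(axis) >= 2 && d[1] < 0
  if (reversed) {
    axis <- rev(axis)
    cube <- cube[, , rev(seq_along(axis)), drop = FALSE]
    meta$axis_reversed <- TRUE
  }
  if (is.null(mask)) {
    mask <- apply(cube, c(1, 2), function(v) any(is.finite(v)))
  }
  if (!is.logical(mask) || !identical(dim(mask), dim(cube)[1:2]))
    stop("mask shape must equal the spatial dimensions of the cube")
  ok <- which(mask, arr.ind = TRUE)
  if (nrow(ok)) {
    vals <- cube[cbind(ok[rep(seq_len(nrow(ok)), each = length(axis)), , drop = FALSE],
                       rep(seq_along(axis), times = nrow(ok)))]
    if (any(!is.finite(vals)))
      stop("non-finite absorbance on a pixel marked valid")
  }
  structure(list(cube = cube, axis = axis, mask = mask, meta = meta),
            class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf("<spectral_image %dx%d px, %d channels [%g..%g cm-1], %d valid px>\n",
              d[1], d[2], d[3], min(x$axis), max(x$axis), sum(x$mask)))
  invisible(x)
}

#' @export
dim.spectral_image <- function(x) dim(x$cube)

.io_dialects <- c("envi", "tsv", "csv_long")

#' Write a hyperspectral cube
#'
#' Dialects:
#' * `envi` - ENVI-style text header (`<path>.hdr`) plus a band-interleaved-
#'   by-pixel binary cube of doubles (`<path>.raw`); invalid pixels stored as
#'   NaN.
#' * `tsv` - a directory container holding `manifest.json`, `axis.tsv`,
#'   `data.tsv` (row-major pixel rows x channels, NA for invalid pixels) and
#'   `mask.tsv`; used in place of HDF5, which is not available in this
#'   toolchain.
#' * `csv_long` - long-format text with columns `row,col,wavenumber,absorbance`.
#'
#' @param image a [spectral_image()]
#' @param path output path (a file stem for `envi`/`csv_long`, a directory
#'   for `tsv`)
#' @param dialect one of `"envi"`, `"tsv"`, `"csv_long"`
#' @return `path`, invisibly
#' @export
save_image <- function(image, path, dialect = c("envi", "tsv", "csv_long")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(image, "spectral_image"))
  d <- dim(image$cube)
  switch(dialect,
    envi = {
      hdr <- c("ENVI",
               paste0("samples = ", d[2]),
               paste0("lines = ", d[1]),
               paste0("bands = ", d[3]),
               "data type = 5",
               "interleave = bip",
               "byte order = 0",
               paste0("wavelength = { ",
                      paste(fmt_num(image$axis), collapse = ", "), " }"))
      writeLines(hdr, paste0(path, ".hdr"))
      cube <- image$cube
      for (r in seq_len(d[1])) for (cc in seq_len(d[2]))
        if (!image$mask[r, cc]) cube[r, cc, ] <- NaN
      # BIP: all bands of pixel (0,0), then (0,1), ... row-major
      vec <- aperm(cube, c(3, 2, 1))
      con <- file(paste0(path, ".raw"), "wb")
      on.exit(close(con), add = TRUE)
      writeBin(as.numeric(vec), con, size = 8, endian = "little")
    },
    tsv = {
      dir.create(path, showWarnings = FALSE, recursive = TRUE)
      mat <- unfold_full(image)
      mat[!as.vector(t(image$mask)), ] <- NA_real_
      write_tsv_matrix(mat, file.path(path, "data.tsv"))
      utils::write.table(data.frame(wavenumber = fmt_num(image$axis)),
                         file.path(path, "axis.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      utils::write.table(image$mask * 1L, file.path(path, "mask.tsv"), sep = "\t",
                         row.names = FALSE, col.names = FALSE)
      manifest <- list(rows = d[1], cols = d[2], channels = d[3],
                       meta = image$meta)
      jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    },
    csv_long = {
      idx <- expand.grid(col = seq_len(d[2]), row = seq_len(d[1]))
      long <- do.call(rbind, lapply(seq_len(nrow(idx)), function(i) {
        r <- idx$row[i]; cc <- idx$col[i]
        if (!image$mask[r, cc]) return(NULL)
        data.frame(row = r, col = cc, wavenumber = image$axis,
                   absorbance = image$cube[r, cc, ])
      }))
      long$wavenumber <- fmt_num(long$wavenumber)
      long$absorbance <- fmt_num(long$absorbance)
      utils::write.table(long, paste0(path, ".csv"), sep = ",",
                         row.names = FALSE, quote = FALSE)
    })
  invisible(path)
}

#' Read a hyperspectral cube
#'
#' Counterpart of [save_image()]. The axis is normalized to ascending order
#' regardless of stored order (a reversal is recorded in `meta$axis_reversed`);
#' all-NaN pixels become invalid in the mask.
#'
#' @param path path as produced by [save_image()]
#' @param dialect one of `"envi"`, `"tsv"`, `"csv_long"`
#' @return a [spectral_image()]
#' @export
load_image <- function(path, dialect = c("envi", "tsv", "csv_long")) {
  dialect <- match.arg(dialect)
  switch(dialect,
    envi = {
      hfile <- paste0(path, ".hdr")
      if (!file.exists(hfile)) stop("no ENVI header at ", hfile)
      hdr <- readLines(hfile, warn = FALSE)
      getnum <- function(key) {
        ln <- grep(paste0("^", key, "\\s*="), hdr, value = TRUE)
        if (!length(ln)) stop("ENVI header missing '", key, "'")
        as.numeric(sub(".*=\\s*", "", ln[1]))
      }
      ns <- getnum("samples"); nl <- getnum("lines"); nb <- getnum("bands")
      wl_line <- paste(hdr[grep("wavelength", hdr)[1]:length(hdr)], collapse = " ")
      wl <- as.numeric(strsplit(gsub(".*\\{|\\}.*", "", wl_line), ",")[[1]])
      if (length(wl) != nb)
        stop("channel-count mismatch: header declares ", nb,
             " bands but lists ", length(wl), " wavelengths")
      rawf <- paste0(path, ".raw")
      n_expected <- ns * nl * nb
      vec <- readBin(rawf, "numeric", n = n_expected + 1, size = 8, endian = "little")
      if (length(vec) != n_expected)
        stop("channel-count mismatch: file holds ", length(vec),
             " values, header implies ", n_expected)
      cube <- aperm(array(vec, dim = c(nb, ns, nl)), c(3, 2, 1))
      spectral_image(cube, wl)
    },
    tsv = {
      manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                      simplifyVector = TRUE)
      axis <- as.numeric(utils::read.table(file.path(path, "axis.tsv"),
                                           header = TRUE, sep = "\t")$wavenumber)
      mat <- as.matrix(utils::read.table(file.path(path, "data.tsv"), sep = "\t"))
      if (ncol(mat) != length(axis))
        stop("channel-count mismatch: data.tsv has ", ncol(mat),
             " columns, axis.tsv has ", length(axis), " wavenumbers")
      cube <- refold_full(mat, manifest$rows, manifest$cols)
      meta <- manifest$meta
      if (is.null(meta)) meta <- list()
      spectral_image(cube, axis, meta = as.list(meta))
    },
    csv_long = {
      long <- utils::read.table(paste0(path, ".csv"), header = TRUE, sep = ",")
      need <- c("row", "col", "wavenumber", "absorbance")
      if (!all(need %in% names(long)))
        stop("csv_long requires columns ", paste(need, collapse = ", "))
      dup <- duplicated(long[c("row", "col", "wavenumber")])
      if (any(dup))
        stop("duplicated wavenumber row: ", long$wavenumber[which(dup)[1]],
             " cm-1 at pixel (", long$row[which(dup)[1]], ",",
             long$col[which(dup)[1]], ")")
      axis <- as.numeric(sort(unique(long$wavenumber)))
      counts <- table(paste(long$row, long$col))
      if (any(counts != length(axis)))
        stop("channel-count mismatch: not every pixel has every wavenumber")
      nr <- max(long$row); nc <- max(long$col)
      cube <- array(NaN, dim = c(nr, nc, length(axis)))
      ch <- match(long$wavenumber, axis)
      cube[cbind(long$row, long$col, ch)] <- as.numeric(long$absorbance)
      spectral_image(cube, axis)
    })
}

# format doubles so text roundtrips are bit-exact (17 significant digits)
fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  out
}

# write a numeric matrix as TSV preserving full double precision
write_tsv_matrix <- function(m, path) {
  ch <- matrix(fmt_num(m), nrow = nrow(m))
  utils::write.table(ch, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
}

# row-major unfold including invalid pixels (io helper)
unfold_full <- function(image) {
  d <- dim(image$cube)
  m <- matrix(aperm(image$cube, c(3, 2, 1)), nrow = d[1] * d[2],
              ncol = d[3], byrow = TRUE)
  m
}

refold_full <- function(mat, rows, cols) {
  aperm(array(t(mat), dim = c(ncol(mat), cols, rows)), c(3, 2, 1))
}

#' Save distribution maps with a manifest
#'
#' Writes one TSV per (image, component) map plus `manifest.json` listing
#' image ids, component ids and each map's value range.
#'
#' @param model_maps list (one entry per image) of `rows x cols x k` arrays,
#'   or of lists of `rows x cols` matrices; names are used as image ids
#' @param out_dir output directory (created if needed)
#' @return character vector of files written, invisibly
#' @export
save_maps <- function(model_maps, out_dir) {
  stopifnot(is.list(model_maps), length(model_maps) >= 1)
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  as_list3 <- function(m) {
    if (is.array(m) && length(dim(m)) == 3L)
      lapply(seq_len(dim(m)[3]), function(j) m[, , j]) else m
  }
  maps <- lapply(model_maps, as_list3)
  kk <- unique(vapply(maps, length, integer(1)))
  if (length(kk) != 1L) stop("maps do not share a component count")
  ids <- names(maps)
  if (is.null(ids)) ids <- sprintf("image%02d", seq_along(maps))
  files <- character(0); entries <- list()
  for (i in seq_along(maps)) for (j in seq_len(kk)) {
    f <- file.path(out_dir, sprintf("map_%s_comp%02d.tsv", ids[i], j))
    write_tsv_matrix(maps[[i]][[j]], f)
    v <- maps[[i]][[j]]
    entries[[length(entries) + 1L]] <- list(
      image = ids[i], component = j, file = basename(f),
      range = c(min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
    files <- c(files, f)
  }
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(list(images = ids, n_components = kk, maps = entries),
                       mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, mf))
}

#' Read one map written by [save_maps()]
#' @param path path to a `map_*.tsv` file
#' @return numeric matrix
#' @export
load_map <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t"))
}
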