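#' Unfold an image to a pixel-by-channel matrix
#'
#' One row per valid pixel, in row-major scan order ((1,1), (1,2), ...,
#' (2,1), ...). Masked pixels are omitted and absent from the provenance
#' index.
#'
#' @param image a [spectral_image()]
#' @return list with `data` (valid_pixels x channels matrix) and `index`
#'   (data.frame with columns `image_id`, `row`, `col`)
#' @export
unfold <- function(image) {
  stopifnot(inherits(image, "spectral_image"))
  d <- dim(image$cube)
  valid <- as.vector(t(image$mask))
  if (!any(valid)) stop("image has zero valid pixels")
  mat <- unfold_full(image)[valid, , drop = FALSE]
  idx <- expand.grid(col = seq_len(d[2]), row = seq_len(d[1]))[valid, ]
  id <- image$meta$section
  if (is.null(id)) id <- "image"
  index <- data.frame(image_id = id, row = idx$row, col = idx$col,
                      stringsAsFactors = FALSE)
  rownames(index) <- NULL
  list(data = mat, index = index)
}

#' Build the augmented multiset from an ordered image list
#'
#' Row-wise concatenation of the unfolded images (the column-wise augmented
#' matrix D of the bilinear model), with per-image block ranges and pixel
#' provenance recorded so concentration columns can be refolded into maps.
#' Images with zero valid pixels are dropped with a warning, mirroring the
#' exclusion of oversaturated sections from the measured multisets.
#'
#' @param images ordered list of [spectral_image()] sharing an identical axis
#' @param direction `"cross"` or `"tangential"` (bookkeeping only)
#' @return object of class `multiset` with fields `data`, `axis`, `index`,
#'   `blocks` (data.frame image_id/start/end), `shapes`, `masks`, `direction`
#' @export
augment <- function(images, direction = "cross") {
  stopifnot(is.list(images), length(images) >= 1)
  ids <- vapply(seq_along(images), function(i) {
    id <- images[[i]]$meta$section
    if (is.null(id)) id <- names(images)[i]
    if (is.null(id) || !nzchar(id)) id <- sprintf("image%02d", i)
    id
  }, character(1))
  axis <- images[[1]]$axis
  for (i in seq_along(images)) {
    if (!isTRUE(all.equal(images[[i]]$axis, axis)))
      stop("axis mismatch between images '", ids[1], "' and '", ids[i], "'")
  }
  keep <- vapply(images, function(im) any(im$mask), logical(1))
  if (any(!keep)) {
    warning("excluding image(s) with zero valid pixels: ",
            paste(ids[!keep], collapse = ", "))
    images <- images[keep]; ids <- ids[keep]
    if (!length(images)) stop("all images excluded")
  }
  parts <- lapply(seq_along(images), function(i) {
    u <- unfold(images[[i]])
    u$index$image_id <- ids[i]
    u
  })
  data <- do.call(rbind, lapply(parts, `[[`, "data"))
  index <- do.call(rbind, lapply(parts, `[[`, "index"))
  n_rows <- vapply(parts, function(p) nrow(p$data), integer(1))
  end <- cumsum(n_rows)
  blocks <- data.frame(image_id = ids, start = c(1L, head(end, -1) + 1L),
                       end = end, stringsAsFactors = FALSE)
  structure(list(data = data, axis = axis, index = index, blocks = blocks,
                 shapes = lapply(images, function(im) dim(im$cube)[1:2]),
                 masks = lapply(images, `[[`, "mask"),
                 direction = direction),
            class = "multiset")
}

#' @export
print.multiset <- function(x, ...) {
  cat(sprintf("<multiset: %d rows x %d channels, %d blocks (%s), %s>\n",
              nrow(x$data), ncol(x$data), nrow(x$blocks),
              paste(x$blocks$image_id, collapse = ","), x$direction))
  invisible(x)
}

#' Refold a per-row vector into one image's spatial map
#'
#' Fills a `rows x cols` matrix from the rows of `values` belonging to
#' `image_id`'s block, using the recorded pixel provenance. Masked pixels
#' receive `missing`.
#'
#' @param multiset a [augment()] result
#' @param values numeric vector, one value per multiset row (e.g. a column
#'   of the concentration matrix)
#' @param image_id an id from `multiset$blocks$image_id` (or its 1-based
#'   position)
#' @param missing fill value for invalid pixels (default `NA`)
#' @return numeric `rows x cols` matrix
#' @export
refold <- function(multiset, values, image_id, missing = NA_real_) {
  stopifnot(inherits(multiset, "multiset"))
  if (length(values) != nrow(multiset$data))
    stop("values length (", length(values), ") != multiset row count (",
         nrow(multiset$data), ")")
  if (is.numeric(image_id)) {
    bi <- as.integer(image_id)
    if (bi < 1 || bi > nrow(multiset$blocks)) stop("unknown image_id: ", image_id)
  } else {
    bi <- match(image_id, multiset$blocks$image_id)
    if (is.na(bi)) stop("unknown image_id: ", image_id)
  }
  b <- multiset$blocks[bi, ]
  shape <- multiset$shapes[[bi]]
  map <- matrix(missing, shape[1], shape[2])
  rows <- seq.int(b$start, b$end)
  map[cbind(multiset$index$row[rows], multiset$index$col[rows])] <- values[rows]
  map
}

#' Refold every component column of a concentration matrix
#'
#' @param multiset a [augment()] result
#' @param C concentration matrix (rows x k)
#' @return named list (per image) of `rows x cols x k` arrays
#' @export
refold_all <- function(multiset, C) {
  k <- ncol(C)
  out <- lapply(seq_len(nrow(multiset$blocks)), function(bi) {
    shape <- multiset$shapes[[bi]]
    arr <- array(NA_real_, dim = c(shape[1], shape[2], k))
    for (j in seq_len(k)) arr[, , j] <- refold(multiset, C[, j], bi)
    arr
  })
  names(out) <- multiset$blocks$image_id
  out
}

#' Serialize a multiset to a text container directory
#' @param multiset a [augment()] result
#' @param out_dir output directory
#' @return `out_dir`, invisibly
#' @export
save_multiset <- function(multiset, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_matrix(multiset$data, file.path(out_dir, "data.tsv"))
  utils::write.table(data.frame(wavenumber = fmt_num(multiset$axis)),
                     file.path(out_dir, "axis.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(multiset$index, file.path(out_dir, "index.tsv"), sep = "\t",
                     row.names = FALSE)
  utils::write.table(multiset$blocks, file.path(out_dir, "blocks.tsv"), sep = "\t",
                     row.names = FALSE)
  jsonlite::write_json(list(direction = multiset$direction,
                            shapes = multiset$shapes),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read a multiset written by [save_multiset()]
#' @param path container directory
#' @return a `multiset`
#' @export
load_multiset <- function(path) {
  data <- as.matrix(utils::read.table(file.path(path, "data.tsv"), sep = "\t"))
  dimnames(data) <- NULL
  axis <- as.numeric(utils::read.table(file.path(path, "axis.tsv"),
                                       header = TRUE, sep = "\t")$wavenumber)
  index <- utils::read.table(file.path(path, "index.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  blocks <- utils::read.table(file.path(path, "blocks.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  shapes <- lapply(seq_len(nrow(blocks)), function(bi) {
    as.integer(manifest$shapes[[bi]])
  })
  masks <- lapply(seq_len(nrow(blocks)), function(bi) {
    m <- matrix(FALSE, shapes[[bi]][1], shapes[[bi]][2])
    rows <- seq.int(blocks$start[bi], blocks$end[bi])
    m[cbind(index$row[rows], index$col[rows])] <- TRUE
    m
  })
  structure(list(data = data, axis = axis, index = index, blocks = blocks,
                 shapes = shapes, masks = masks,
                 direction = manifest$direction),
            class = "multiset")
}
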