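# Minimal baseline TIFF support (no R TIFF package exists in the target
# environment). Scope: uncompressed grayscale, 8- or 16-bit unsigned, one
# sample per pixel, multi-page, little- or big-endian on read,
# little-endian single-strip on write. That covers the label masks and
# intensity pages this package emits and the equivalent output of common
# scientific writers; anything else is rejected with a clear error.

.tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

#' Write a multi-page grayscale TIFF
#'
#' Pages are written uncompressed, one strip per page, little-endian, with
#' unsigned integer samples. Values are rounded and clamped to the sample
#' range (\[0, 255\] or \[0, 65535\]).
#'
#' @param x numeric matrix (one page), 3-D array `rows x cols x pages`, or
#'   list of equally-sized matrices.
#' @param path output file path.
#' @param bits bits per sample: 8 or 16 (default).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(x, path, bits = 16L) {
  if (!bits %in% c(8L, 16L)) stop_param("bits must be 8 or 16")
  pages <- if (is.list(x)) {
    x
  } else if (is.matrix(x)) {
    list(x)
  } else if (is.array(x) && length(dim(x)) == 3L) {
    lapply(seq_len(dim(x)[3]), function(i) x[, , i])
  } else {
    stop_input("x must be a matrix, 3-D array or list of matrices")
  }
  if (!length(pages)) stop_input("no pages to write")
  dims <- dim(pages[[1]])
  if (!all(vapply(pages, function(p) identical(dim(p), dims), logical(1)))) {
    stop_input("all pages must share the same dimensions")
  }

  bytes_pp <- bits / 8L
  page_bytes <- prod(dims) * bytes_pp
  n <- length(pages)
  data_off <- 8L + (seq_len(n) - 1L) * page_bytes
  ifd_size <- 2L + 9L * 12L + 4L
  ifd_off <- 8L + n * page_bytes + (seq_len(n) - 1L) * ifd_size

  con <- file(path, "wb")
  on.exit(close(con))
  wle <- function(v, size) writeBin(as.integer(v), con, size = size,
                                    endian = "little")
  writeChar("II", con, 2, eos = NULL)
  wle(42L, 2)
  wle(ifd_off[1], 4)

  maxv <- 2^bits - 1
  for (p in pages) {
    v <- round(as.numeric(t(p)))  # TIFF is row-major
    v[v < 0] <- 0
    v[v > maxv] <- maxv
    wle(v, bytes_pp)
  }

  entry <- function(tag, type, value) {
    wle(tag, 2)
    wle(type, 2)
    wle(1L, 4)
    if (type == 3L) {        # SHORT: left-justified in the 4-byte slot
      wle(value, 2)
      wle(0L, 2)
    } else {
      wle(value, 4)
    }
  }
  for (i in seq_len(n)) {
    wle(9L, 2)
    entry(256L, 4L, dims[2])          # ImageWidth
    entry(257L, 4L, dims[1])          # ImageLength
    entry(258L, 3L, bits)             # BitsPerSample
    entry(259L, 3L, 1L)               # Compression: none
    entry(262L, 3L, 1L)               # Photometric: BlackIsZero
    entry(273L, 4L, data_off[i])      # StripOffsets
    entry(278L, 4L, dims[1])          # RowsPerStrip
    entry(279L, 4L, page_bytes)       # StripByteCounts
    entry(339L, 3L, 1L)               # SampleFormat: unsigned
    wle(if (i < n) ifd_off[i + 1] else 0L, 4)
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF
#'
#' Counterpart of [write_tiff()]; additionally accepts big-endian files and
#' multi-strip layouts, but only uncompressed unsigned 8/16-bit grayscale.
#'
#' @param path TIFF file path.
#' @return 3-D numeric array `rows x cols x pages`.
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  byte_order <- rawToChar(raw[1:2])
  if (!byte_order %in% c("II", "MM")) stop_input("not a TIFF file: %s", path)
  en <- if (byte_order == "II") "little" else "big"
  rd <- function(off, size, n = 1L) {
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            signed = size == 4L, endian = en)
  }
  if (rd(2, 2) != 42L) stop_input("bad TIFF magic in %s", path)

  pages <- list()
  ifd_off <- rd(4, 4)
  while (ifd_off != 0L) {
    n_entries <- rd(ifd_off, 2)
    tags <- list()
    for (e in seq_len(n_entries)) {
      base <- ifd_off + 2L + (e - 1L) * 12L
      tag <- rd(base, 2)
      type <- rd(base + 2L, 2)
      count <- rd(base + 4L, 4)
      tsize <- .tiff_type_size[as.character(type)]
      vals <- if (!is.na(tsize) && type %in% c(3L, 4L)) {
        voff <- if (tsize * count <= 4L) base + 8L else rd(base + 8L, 4)
        rd(voff, tsize, count)
      } else {
        NULL
      }
      tags[[as.character(tag)]] <- vals
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop_input("TIFF tag %d missing in %s", tag, path)
        default
      } else {
        v
      }
    }
    width <- need(256L)
    height <- need(257L)
    bits <- need(258L, 1L)
    if (need(259L, 1L) != 1L) stop_input("compressed TIFF not supported: %s", path)
    if (need(277L, 1L) != 1L) stop_input("multi-sample TIFF not supported: %s", path)
    if (need(339L, 1L) != 1L) stop_input("non-unsigned TIFF not supported: %s", path)
    if (!bits %in% c(8L, 16L)) stop_input("unsupported bit depth %d in %s", bits, path)
    offsets <- need(273L)
    counts <- need(279L)
    bpp <- bits / 8L
    vals <- unlist(lapply(seq_along(offsets), function(i) {
      readBin(raw[(offsets[i] + 1):(offsets[i] + counts[i])], "integer",
              n = counts[i] / bpp, size = bpp, signed = FALSE, endian = en)
    }))
    if (length(vals) != width * height) {
      stop_input("strip data does not match image size in %s", path)
    }
    pages[[length(pages) + 1L]] <- t(matrix(vals, nrow = width, ncol = height))
    ifd_off <- rd(ifd_off + 2L + n_entries * 12L, 4)
  }
  if (!length(pages)) stop_input("no pages found in %s", path)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' Export / import a rendered scene as TIFF + CSV
#'
#' Writes `<prefix>_image.tif` (one 16-bit page per channel, intensities
#' rounded), `<prefix>_mask.tif` (16-bit label mask), `<prefix>_truth.csv`
#' and a `<prefix>_channels.json` sidecar recording the channel order.
#'
#' @param scene a [render_scene()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named character vector of the written paths, invisibly.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  if (!inherits(scene, "synthetic_scene")) stop_input("scene must be a synthetic_scene")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    image = file.path(dir, paste0(prefix, "_image.tif")),
    mask = file.path(dir, paste0(prefix, "_mask.tif")),
    truth = file.path(dir, paste0(prefix, "_truth.csv")),
    channels = file.path(dir, paste0(prefix, "_channels.json"))
  )
  write_tiff(scene$image, paths[["image"]], bits = 16L)
  write_tiff(scene$mask, paths[["mask"]], bits = 16L)
  write_cells_csv(scene$truth, paths[["truth"]])
  jsonlite::write_json(list(channels = dimnames(scene$image)[[3]]),
                       paths[["channels"]], auto_unbox = FALSE, pretty = TRUE)
  invisible(paths)
}

#' @param dir directory holding the exported scene.
#' @rdname write_scene
#' @export
read_scene <- function(dir, prefix = "scene") {
  chans <- jsonlite::read_json(
    file.path(dir, paste0(prefix, "_channels.json")), simplifyVector = TRUE
  )$channels
  image <- read_tiff(file.path(dir, paste0(prefix, "_image.tif")))
  dimnames(image) <- list(NULL, NULL, chans)
  mask <- read_tiff(file.path(dir, paste0(prefix, "_mask.tif")))[, , 1]
  storage.mode(mask) <- "integer"
  truth <- read_cells_csv(file.path(dir, paste0(prefix, "_truth.csv")),
                          required = "cell_id")
  structure(list(image = image, mask = mask, truth = truth),
            class = "synthetic_scene")
}
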