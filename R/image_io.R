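#' Multichannel microscopy image container
#'
#' An `mc_image` holds registered 2-D intensity planes, one per named color
#' channel, on the native integer scale of the source file (no rescaling,
#' gamma or denoising is ever applied). Matrices are indexed `[row, col]`,
#' 1-based, row 1 at the top of the image.
#'
#' @param channels named list of numeric matrices of identical dimensions;
#'   names are channel names such as `"blue"`, `"green"`, `"red"`.
#' @param bit_depth integer, 8 or 16; all intensities must lie in
#'   `[0, 2^bit_depth - 1]`.
#' @param source_id opaque identifier for the source image.
#'
#' @return An object of class `mc_image` with fields `channels`, `height`,
#'   `width`, `bit_depth`, `source_id`.
#' @export
mc_image <- function(channels, bit_depth = 8L, source_id = "image") {
  if (!length(channels) || is.null(names(channels)) || any(names(channels) == ""))
    stop("'channels' must be a non-empty named list of matrices")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 2L))
    stop("every channel must be a 2-D matrix")
  d0 <- dims[[1L]]
  if (!all(vapply(dims, function(d) all(d == d0), TRUE)))
    stop("channel planes differ in shape")
  maxv <- 2^bit_depth - 1
  for (nm in names(channels)) {
    v <- channels[[nm]]
    if (any(v < 0) || any(v > maxv))
      stop(sprintf("channel '%s' has values outside [0, %d]", nm, maxv))
  }
  structure(list(channels = channels, height = d0[1L], width = d0[2L],
                 bit_depth = as.integer(bit_depth), source_id = source_id),
            class = "mc_image")
}

#' @export
print.mc_image <- function(x, ...) {
  cat(sprintf("<mc_image '%s': %d x %d px, %d-bit, channels: %s>\n",
              x$source_id, x$height, x$width, x$bit_depth,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Load a microscopy image and split it into named channels
#'
#' Reads either one RGB raster (TIFF or PNG) that is split plane-by-plane, or
#' several single-channel grayscale files given as a named vector of paths
#' (`c(blue = "dapi.tif", green = "marker.tif")`). Pixel values are passed
#' through unmodified on the native integer scale of the file.
#'
#' @param path a single file path to an RGB image, or a named character
#'   vector mapping channel names to grayscale files.
#' @param channel_order channel names assigned to the color planes of an RGB
#'   file, in plane order. Microscopes exporting BGR can pass
#'   `c("blue", "green", "red")`.
#' @param source_id identifier stored in the result; defaults to the file
#'   name (without directory) of the first path.
#'
#' @return An [mc_image]. Loading fails unless both a `"blue"` and a
#'   `"green"` channel are present afterwards.
#' @export
load_image <- function(path, channel_order = c("red", "green", "blue"),
                       source_id = NULL) {
  if (is.null(source_id)) source_id <- basename(path[[1L]])
  if (length(path) > 1L || !is.null(names(path))) {
    if (is.null(names(path)) || any(names(path) == ""))
      stop("multi-file mode requires a fully named vector of channel paths")
    planes <- lapply(path, read_raster)
    bd <- unique(vapply(planes, function(p) p$bit_depth, 1L))
    if (length(bd) != 1L)
      stop("channel files disagree on bit depth")
    chans <- lapply(planes, function(p) {
      if (length(dim(p$data)) != 2L)
        stop("per-channel files must be single-plane grayscale rasters")
      p$data
    })
    dims <- lapply(chans, dim)
    if (!all(vapply(dims, function(d) all(d == dims[[1L]]), TRUE)))
      stop("channel files differ in shape")
    img <- mc_image(chans, bit_depth = bd, source_id = source_id)
  } else {
    r <- read_raster(path)
    if (length(dim(r$data)) == 2L)
      stop("single grayscale file cannot provide both 'blue' and 'green' ",
           "channels; use the named multi-file form")
    k <- dim(r$data)[3L]
    if (k < length(channel_order))
      stop(sprintf("file has %d planes but channel_order names %d", k,
                   length(channel_order)))
    chans <- stats::setNames(
      lapply(seq_along(channel_order), function(i) r$data[, , i]),
      channel_order)
    img <- mc_image(chans, bit_depth = r$bit_depth, source_id = source_id)
  }
  if (!all(c("blue", "green") %in% names(img$channels)))
    stop("configuration error: loaded image lacks a 'blue' or 'green' channel")
  img
}

# Decode a TIFF or PNG file to integer intensities on the native scale.
# Returns list(data = h x w [x k] array, bit_depth).
read_raster <- function(path) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    read_tiff(path)
  } else if (ext == "png") {
    x <- png::readPNG(path, info = TRUE)
    info <- attr(x, "info")
    bd <- if (!is.null(info) && !is.null(info$bit.depth)) info$bit.depth else 8L
    maxv <- 2^bd - 1
    d <- round(x * maxv)
    attributes(d) <- attributes(x)[c("dim")]
    if (length(dim(d)) == 3L && dim(d)[3L] == 4L) d <- d[, , 1:3] # drop alpha
    list(data = d, bit_depth = as.integer(bd))
  } else {
    stop("unsupported image format: ", path)
  }
}

## ---- minimal baseline TIFF codec (uncompressed, 8/16-bit, gray or RGB) ----
## No TIFF package is available in this toolchain, so the subset of baseline
## TIFF actually produced by microscope exports (uncompressed, chunky,
## single-plane) is read and written directly.

#' Read an uncompressed baseline TIFF
#'
#' Supports 8- and 16-bit grayscale and interleaved RGB, both byte orders,
#' any strip layout; compressed or tiled files are rejected.
#'
#' @param path file path.
#' @return list with `data` (h x w matrix or h x w x 3 array of integers on
#'   the native scale) and `bit_depth`.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  endian <- if (raw[1L] == as.raw(0x49)) "little" else "big"
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = endian)
  u32 <- function(off) {
    v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = endian)
    if (v < 0) stop("TIFF offset overflow")
    v
  }
  if (u16(2) != 42L) stop("not a TIFF file: ", path)
  ifd <- u32(4)
  nent <- u16(ifd)
  tags <- list()
  for (i in seq_len(nent)) {
    base <- ifd + 2 + (i - 1) * 12
    tag <- u16(base); type <- u16(base + 2); count <- u32(base + 4)
    size <- c(1, 1, 2, 4, 8)[type]
    if (is.na(size)) next
    total <- size * count
    voff <- if (total <= 4) base + 8 else u32(base + 8)
    vals <- switch(as.character(type),
      "3" = vapply(seq_len(count), function(k) u16(voff + (k - 1) * 2), 1),
      "4" = vapply(seq_len(count), function(k) u32(voff + (k - 1) * 4), 1),
      "1" = as.integer(raw[(voff + 1):(voff + count)]),
      NULL)
    if (!is.null(vals)) tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", tag, " missing in ", path)
      default
    } else v
  }
  w <- need(256); h <- need(257)
  bits <- unique(need(258, 8L))
  if (length(bits) != 1L || !(bits %in% c(8L, 16L)))
    stop("unsupported TIFF bit depth in ", path)
  if (need(259, 1L) != 1L) stop("compressed TIFF not supported: ", path)
  spp <- need(277, 1L)
  if (!(spp %in% c(1L, 3L))) stop("unsupported samples per pixel in ", path)
  if (need(284, 1L) != 1L) stop("planar TIFF not supported: ", path)
  offs <- need(273); counts <- need(279)
  rps <- need(278, h)
  buf <- raw(0)
  for (k in seq_along(offs))
    buf <- c(buf, raw[(offs[k] + 1):(offs[k] + counts[k])])
  npx <- as.numeric(w) * h * spp
  vals <- if (bits == 8L) as.integer(buf[seq_len(npx)])
  else readBin(buf, "integer", n = npx, size = 2, signed = FALSE,
               endian = endian)
  if (spp == 1L) {
    data <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  } else {
    data <- array(0, dim = c(h, w, 3L))
    for (s in 1:3)
      data[, , s] <- matrix(vals[seq(s, npx, by = 3L)], nrow = h, ncol = w,
                            byrow = TRUE)
  }
  invisible(rps) # strip layout already honored via offsets/counts
  list(data = data, bit_depth = as.integer(bits))
}

#' Write an uncompressed baseline TIFF
#'
#' @param data h x w matrix (grayscale) or h x w x 3 array (RGB) of integers
#'   on the native scale.
#' @param path output file path.
#' @param bit_depth 8 or 16.
#' @export
write_tiff <- function(data, path, bit_depth = 8L) {
  dm <- dim(data)
  spp <- if (length(dm) == 3L) dm[3L] else 1L
  if (!(spp %in% c(1L, 3L))) stop("data must be grayscale or RGB")
  h <- dm[1L]; w <- dm[2L]
  maxv <- 2^bit_depth - 1
  if (any(data < 0) || any(data > maxv))
    stop("values outside the representable range for bit_depth ", bit_depth)
  # interleave samples in row-major pixel order
  vals <- if (spp == 1L) as.vector(t(data))
  else as.vector(aperm(data, c(3L, 2L, 1L)))
  vals <- as.integer(round(vals))
  nbytes <- length(vals) * (bit_depth / 8L)

  entries <- list(
    c(256L, 3L, 1L, w), c(257L, 3L, 1L, h),
    NULL, # 258 BitsPerSample, filled below
    c(259L, 3L, 1L, 1L),
    c(262L, 3L, 1L, if (spp == 3L) 2L else 1L),
    NULL, # 273 StripOffsets, filled below
    c(277L, 3L, 1L, spp), c(278L, 3L, 1L, h),
    c(279L, 4L, 1L, nbytes), c(284L, 3L, 1L, 1L))
  n <- length(entries)
  ifd_off <- 8L
  extra_off <- ifd_off + 2L + 12L * n + 4L   # out-of-line values area
  extra <- raw(0)
  if (spp == 3L) {
    bps_entry <- c(258L, 3L, 3L, extra_off + length(extra))
    extra <- c(extra, writeBin(rep(as.integer(bit_depth), 3L), raw(),
                               size = 2, endian = "little"))
  } else {
    bps_entry <- c(258L, 3L, 1L, as.integer(bit_depth))
  }
  data_off_pos <- extra_off + length(extra)
  entries[[3L]] <- bps_entry
  entries[[6L]] <- c(273L, 4L, 1L, data_off_pos)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x49), as.raw(0x49)), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off, con, size = 4, endian = "little")
  writeBin(n, con, size = 2, endian = "little")
  ord <- order(vapply(entries, function(e) as.integer(e[1L]), 0L))
  for (e in entries[ord]) {
    e <- as.integer(e)
    writeBin(e[1L], con, size = 2, endian = "little")
    writeBin(e[2L], con, size = 2, endian = "little")
    writeBin(e[3L], con, size = 4, endian = "little")
    if (e[2L] == 3L && e[3L] == 1L) {
      writeBin(e[4L], con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(e[4L], con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little") # next IFD
  if (length(extra)) writeBin(extra, con)
  writeBin(vals, con, size = bit_depth / 8L, endian = "little")
  invisible(path)
}

#' Write an mc_image to disk
#'
#' Writes the red/green/blue channels (missing channels are zero-filled) as
#' an interleaved RGB TIFF or PNG, preserving native intensities.
#'
#' @param img an [mc_image].
#' @param path output path; format chosen by extension (.tif/.tiff/.png).
#' @export
write_image <- function(img, path) {
  arr <- array(0, dim = c(img$height, img$width, 3L))
  for (i in seq_along(c("red", "green", "blue"))) {
    nm <- c("red", "green", "blue")[i]
    if (!is.null(img$channels[[nm]])) arr[, , i] <- img$channels[[nm]]
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    write_tiff(arr, path, bit_depth = img$bit_depth)
  } else if (ext == "png") {
    png::writePNG(arr / (2^img$bit_depth - 1), path)
  } else stop("unsupported output format: ", path)
  invisible(path)
}

#' Write a results table as RFC-4180 CSV
#'
#' @param records a data.frame of per-image (or per-nucleus) result rows.
#' @param path output CSV path.
#' @export
write_results_table <- function(records, path) {
  if (!is.data.frame(records)) stop("'records' must be a data.frame")
  con <- file(path, "wb") # binary connection: byte-identical across platforms
  on.exit(close(con))
  write.csv(records, con, row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read back a results table written by [write_results_table]
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_results_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
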