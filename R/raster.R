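# Raster containers and plain-text/PNG image I/O.
#
# Convention (shared with all downstream modules): image row 1 is the TOP of
# the physical scene; physical y increases upward; the centre of pixel
# (row r, col c), 1-based, is at x = (c - 0.5)*pixel_size,
# y = (H - r + 0.5)*pixel_size. All physical coordinates are metres.

#' Raster image with a physical pixel size
#'
#' A thin container for an RGB raster: an `H x W x 3` array of intensities in
#' `[0, 255]` plus the physical size of one pixel in metres.
#'
#' @param pixels numeric `H x W x 3` array, values in `[0, 255]`.
#' @param pixel_size metres per pixel (scalar, > 0).
#' @return object of class `raster_image`.
#' @export
raster_image <- function(pixels, pixel_size) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_format("raster_image: `pixels` must be an H x W x 3 array (RGB)")
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop_validation("raster_image: empty image")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop_validation("raster_image: pixel_size must be a positive scalar")
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size)),
            class = "raster_image")
}

#' Binary vessel mask
#'
#' @param values logical `H x W` matrix; `TRUE` marks vessel lumen.
#' @param pixel_size metres per pixel.
#' @return object of class `vessel_mask`.
#' @export
vessel_mask <- function(values, pixel_size) {
  if (!is.matrix(values)) stop_format("vessel_mask: `values` must be a matrix")
  if (!is.logical(values)) {
    storage.mode(values) <- "logical"
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop_validation("vessel_mask: pixel_size must be a positive scalar")
  structure(list(values = values, pixel_size = as.numeric(pixel_size)),
            class = "vessel_mask")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image> %d x %d px, %.3g m/px (%.2f x %.2f mm)\n",
              d[1], d[2], x$pixel_size,
              d[2] * x$pixel_size * 1e3, d[1] * x$pixel_size * 1e3))
  invisible(x)
}

#' @export
print.vessel_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<vessel_mask> %d x %d px, %.3g m/px, %.1f%% foreground\n",
              d[1], d[2], x$pixel_size, 100 * mean(x$values)))
  invisible(x)
}

# pixel <-> physical coordinate helpers (1-based row/col)
px_to_xy <- function(row, col, H, pixel_size) {
  cbind(x = (col - 0.5) * pixel_size, y = (H - row + 0.5) * pixel_size)
}

# I/O -----------------------------------------------------------------------

#' Read an RGB image (PNG or ASCII PPM) as a raster_image
#'
#' @param path file path; format chosen by extension (`.png`, `.ppm`).
#' @param pixel_size metres per pixel of the scene depicted.
#' @return a [raster_image].
#' @export
read_image <- function(path, pixel_size) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2L) stop_format("read_image: greyscale PNG; RGB required")
    px <- a[, , 1:3, drop = FALSE] * 255
  } else if (ext == "ppm") {
    px <- read_ppm(path)
  } else {
    stop_format("read_image: unsupported extension '", ext, "'")
  }
  raster_image(px, pixel_size)
}

#' Write a binary mask as PNG (0/255) or ASCII PGM
#'
#' @param mask a [vessel_mask].
#' @param path output path (`.png` or `.pgm`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "vessel_mask"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(mask$values * 1.0, path)
  } else if (ext == "pgm") {
    v <- ifelse(t(mask$values), 255L, 0L)  # row-major for PNM
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(mask$values), nrow(mask$values)), "255"), con)
    writeLines(paste(as.integer(v), collapse = "\n"), con)
  } else {
    stop_format("write_mask: unsupported extension '", ext, "'")
  }
  invisible(path)
}

#' Write an RGB raster as PNG or ASCII PPM
#' @param image a [raster_image].
#' @param path output path (`.png` or `.ppm`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "raster_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image$pixels / 255, path)
  } else if (ext == "ppm") {
    px <- image$pixels
    H <- dim(px)[1]; W <- dim(px)[2]
    # interleave RGB per pixel, row-major
    flat <- as.integer(round(aperm(px, c(3, 2, 1))))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P3", paste(W, H), "255"), con)
    writeLines(paste(flat, collapse = " "), con)
  } else {
    stop_format("write_image: unsupported extension '", ext, "'")
  }
  invisible(path)
}

# ASCII PPM (P3) reader; minimal NetPBM subset sufficient for round-tripping
# the package's own output (no installed package reads PNM).
read_ppm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P3") stop_format("read_ppm: only ASCII P3 supported")
  W <- as.integer(toks[2]); H <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != 3 * W * H) stop_format("read_ppm: truncated pixel data")
  a <- aperm(array(vals, dim = c(3, W, H)), c(3, 2, 1))
  a
}
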