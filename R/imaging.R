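# Vessel segmentation: green channel -> CLAHE -> threshold -> despeckle.

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-based histogram equalization with clipped histograms and bilinear
#' interpolation of the per-tile intensity mappings, applied to a single
#' channel scaled to `[0, 1]`.
#'
#' @param channel numeric matrix with values in `[0, 1]`.
#' @param clip_limit clip limit as a fraction of the tile pixel count per
#'   histogram bin multiplied by the bin count; i.e. the conventional
#'   normalized clip limit (default 0.01).
#' @param tiles integer pair `(rows, cols)` of tile grid (default `c(8, 8)`).
#' @param n_bins number of histogram bins (default 256).
#' @return matrix of equalized values in `[0, 1]`.
#' @export
clahe <- function(channel, clip_limit = 0.01, tiles = c(8L, 8L), n_bins = 256L) {
  stopifnot(is.matrix(channel))
  if (clip_limit <= 0) stop_validation("clahe: clip_limit must be > 0")
  H <- nrow(channel); W <- ncol(channel)
  tr <- max(1L, min(as.integer(tiles[1]), H))
  tc <- max(1L, min(as.integer(tiles[2]), W))
  bin <- pmin(pmax(floor(channel * n_bins) + 1L, 1L), n_bins)

  # tile index of each pixel and fractional position for interpolation
  th <- H / tr; tw <- W / tc
  row_t <- (seq_len(H) - 0.5) / th  # in tile units, centres at k - 0.5
  col_t <- (seq_len(W) - 0.5) / tw

  # per-tile clipped CDF mapping: M[tile, bin] in [0,1]
  tile_of_row <- pmin(pmax(ceiling(row_t), 1L), tr)
  tile_of_col <- pmin(pmax(ceiling(col_t), 1L), tc)
  M <- array(0, dim = c(tr, tc, n_bins))
  for (a in seq_len(tr)) {
    for (b in seq_len(tc)) {
      sel <- bin[tile_of_row == a, tile_of_col == b]
      n_px <- length(sel)
      h <- tabulate(sel, nbins = n_bins)
      clip <- max(1, clip_limit * n_px)
      excess <- sum(pmax(h - clip, 0))
      h <- pmin(h, clip) + excess / n_bins
      M[a, b, ] <- cumsum(h) / sum(h)
    }
  }

  # bilinear interpolation between the four surrounding tile mappings
  a0 <- pmin(pmax(floor(row_t - 0.5) + 1L, 1L), tr)   # tile whose centre is above
  a1 <- pmin(a0 + 1L, tr)
  fa <- pmin(pmax(row_t - (a0 - 0.5), 0), 1)
  b0 <- pmin(pmax(floor(col_t - 0.5) + 1L, 1L), tc)
  b1 <- pmin(b0 + 1L, tc)
  fb <- pmin(pmax(col_t - (b0 - 0.5), 0), 1)

  A0 <- matrix(a0, H, W); A1 <- matrix(a1, H, W)
  FA <- matrix(fa, H, W)
  B0 <- matrix(b0, H, W, byrow = TRUE); B1 <- matrix(b1, H, W, byrow = TRUE)
  FB <- matrix(fb, H, W, byrow = TRUE)

  g <- function(A, B) M[cbind(as.vector(A), as.vector(B), as.vector(bin))]
  out <- (1 - FA) * (1 - FB) * g(A0, B0) + (1 - FA) * FB * g(A0, B1) +
    FA * (1 - FB) * g(A1, B0) + FA * FB * g(A1, B1)
  matrix(pmin(pmax(out, 0), 1), H, W)
}

#' Remove small connected components from a logical matrix
#'
#' @param values logical matrix.
#' @param min_px minimum component size in pixels; smaller components are
#'   removed.
#' @param connectivity 4 or 8 (default 8).
#' @return logical matrix.
#' @export
remove_small_components <- function(values, min_px, connectivity = 8L) {
  if (min_px <= 1L || !any(values)) return(values)
  lab <- .cpp_label_components(values, as.integer(connectivity))
  sz <- tabulate(lab[lab > 0L])
  keep <- which(sz >= min_px)
  values & matrix(lab %in% keep, nrow(values), ncol(values))
}

#' Segment capillaries from a colour micrograph
#'
#' Extracts the green channel (highest vessel/background contrast), applies
#' CLAHE, thresholds the enhanced channel on the `[0, 1]` scale, and removes
#' speckle components below `min_component_px` pixels. The threshold is a
#' required input: in practice it is picked by trial and error per image, so
#' no silent default is applied. Set `threshold = "otsu"` for automatic
#' Otsu thresholding (an extension beyond the trial-and-error procedure).
#'
#' @param image a [raster_image] (RGB).
#' @param threshold scalar in `[0, 1]`, or the string `"otsu"`.
#' @param clahe_clip CLAHE normalized clip limit (default 0.01).
#' @param clahe_tiles CLAHE tile grid, integer pair (default `c(8, 8)`).
#' @param min_component_px remove foreground components smaller than this
#'   (default 1 = keep everything).
#' @return a [vessel_mask] of the same dimensions.
#' @export
extract_vessel_mask <- function(image, threshold, clahe_clip = 0.01,
                                clahe_tiles = c(8L, 8L),
                                min_component_px = 1L) {
  if (!inherits(image, "raster_image"))
    stop_format("extract_vessel_mask: input must be a raster_image (RGB)")
  otsu <- identical(threshold, "otsu")
  if (!otsu) {
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        threshold < 0 || threshold > 1)
      stop_validation("extract_vessel_mask: threshold must be in [0, 1]")
  }
  green <- image$pixels[, , 2] / 255
  enh <- clahe(green, clip_limit = clahe_clip, tiles = clahe_tiles)
  thr <- if (otsu) otsu_threshold(enh) else threshold
  mask <- enh > thr
  mask <- remove_small_components(mask, as.integer(min_component_px))
  vessel_mask(mask, image$pixel_size)
}

# Otsu's method on a [0,1] channel (optional extension).
otsu_threshold <- function(channel, n_bins = 256L) {
  h <- tabulate(pmin(pmax(floor(channel * n_bins) + 1L, 1L), n_bins),
                nbins = n_bins)
  p <- h / sum(h)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Dice similarity coefficient of two masks
#' @param a,b logical matrices or [vessel_mask] objects of equal size.
#' @return scalar in `[0, 1]`; 1 for two empty masks.
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "vessel_mask")) a <- a$values
  if (inherits(b, "vessel_mask")) b <- b$values
  stopifnot(all(dim(a) == dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Trace capillary wall contours
#'
#' Extracts closed polygons along the boundaries of the foreground components
#' (holes included) by marching squares at level 0.5 on the padded mask. A
#' 3x3 box pre-blur gives subpixel boundary localization (it removes the
#' staircase perimeter bias of a hard indicator while moving the contour by
#' less than half a pixel). Coordinates are physical metres.
#'
#' @param mask a [vessel_mask].
#' @return list of closed polygons; each a data.frame with columns `x`, `y`
#'   (first vertex not repeated).
#' @export
trace_contours <- function(mask) {
  stopifnot(inherits(mask, "vessel_mask"))
  v <- mask$values
  if (!any(v)) return(list())
  H <- nrow(v); W <- ncol(v); ps <- mask$pixel_size
  # pad with background so boundary-touching components close
  z <- matrix(0, H + 2, W + 2)
  z[2:(H + 1), 2:(W + 1)] <- v
  zp <- rbind(0, cbind(0, z, 0), 0)
  zb <- matrix(0, H + 2, W + 2)
  for (dr in 0:2) for (dc in 0:2)
    zb <- zb + zp[dr + seq_len(H + 2), dc + seq_len(W + 2)]
  z <- zb / 9
  # contourLines(x, y, z): x along rows of z. Use x = physical x -> rows of z
  # must index x; transpose and flip so z'[i, j] has x_i increasing, y_j up.
  zz <- t(z[rev(seq_len(H + 2)), ])            # (W+2) x (H+2)
  xs <- (seq_len(W + 2) - 1.5) * ps            # padded col c centre
  ys <- (seq_len(H + 2) - 1.5) * ps
  cl <- contourLines(x = xs, y = ys, z = zz, levels = 0.5)
  lapply(cl, function(p) {
    n <- length(p$x)
    # contourLines repeats the first point for closed curves; drop it
    if (n > 1 && p$x[1] == p$x[n] && p$y[1] == p$y[n]) {
      data.frame(x = p$x[-n], y = p$y[-n])
    } else {
      data.frame(x = p$x, y = p$y)
    }
  })
}

#' Signed area of a closed polygon (shoelace)
#' @param poly data.frame with `x`, `y` columns (closed implicitly).
#' @return signed area in m^2 (positive if counter-clockwise).
#' @export
polygon_area <- function(poly) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

#' Perimeter of a closed polygon
#' @param poly data.frame with `x`, `y` columns.
#' @return perimeter in metres.
#' @export
polygon_perimeter <- function(poly) {
  x <- poly$x; y <- poly$y
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

#' Write contours to CSV
#' @param contours list of polygons from [trace_contours].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contours_csv <- function(contours, path) {
  rows <- do.call(rbind, lapply(seq_along(contours), function(i) {
    data.frame(polygon_id = i,
               vertex_index = seq_len(nrow(contours[[i]])),
               x_m = contours[[i]]$x, y_m = contours[[i]]$y)
  }))
  if (is.null(rows))
    rows <- data.frame(polygon_id = integer(), vertex_index = integer(),
                       x_m = numeric(), y_m = numeric())
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
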