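# vessel segmentation, contour tracing, skeletonization

make_rgb <- function(green, ps = 1e-5) {
  px <- array(0, dim = c(nrow(green), ncol(green), 3))
  px[, , 2] <- green
  raster_image(px, ps)
}

test_that("extraction handles trivial inputs and bad arguments", {
  black <- make_rgb(matrix(0, 32, 32))
  expect_equal(sum(extract_vessel_mask(black, 0.5)$values), 0)

  # binary bar is its own segmentation at mid threshold
  g <- matrix(0, 40, 40); g[15:20, 5:35] <- 255
  m <- extract_vessel_mask(make_rgb(g), 0.5)
  expect_identical(m$values, g == 255)

  expect_error(extract_vessel_mask(make_rgb(g), 1.5),
               class = "petflow_validation_error")
  expect_error(extract_vessel_mask(list(pixels = g), 0.5),
               class = "petflow_format_error")
})

test_that("noise-free rendered images segment exactly (Dice = 1)", {
  m <- rect_mask(50, 60, 10, 20, 15, 45)
  img <- render_image(m, noise_sigma = 0, background_level = 0)
  got <- extract_vessel_mask(img, 0.5)
  expect_equal(dice_coefficient(m, got), 1)
})

test_that("noisy rendered network recovers with Dice >= 0.9", {
  mask <- suppressWarnings(rasterize_graph(small_graph(), 2e-5, 0.00672,
                                           0.00609))
  img <- render_image(mask, noise_sigma = 10, background_level = 40, seed = 3)
  got <- extract_vessel_mask(img, 0.5, min_component_px = 30)
  expect_gte(dice_coefficient(mask, got), 0.9)
  # otsu extension stays in the plausible range on the same image
  otsu <- extract_vessel_mask(img, "otsu", min_component_px = 30)
  expect_gte(dice_coefficient(mask, otsu), 0.8)
})

test_that("contours enclose component areas and perimeters", {
  expect_identical(trace_contours(vessel_mask(matrix(FALSE, 5, 5), 1e-5)),
                   list())

  ps <- 1e-5
  m <- rect_mask(60, 80, 20, 39, 30, 59, ps)   # 20 x 30 px rectangle
  cs <- trace_contours(m)
  expect_length(cs, 1L)
  area_px <- abs(polygon_area(cs[[1]])) / ps^2
  # marching squares at 0.5 runs mid-pixel: area within one perimeter band
  expect_lt(abs(area_px - 20 * 30), 2 * (20 + 30) + 4)

  d <- disc_mask(128, 128, 50, ps)
  cs <- trace_contours(d)
  expect_length(cs, 1L)
  per <- polygon_perimeter(cs[[1]])
  expect_lt(abs(per - 2 * pi * 50 * ps) / (2 * pi * 50 * ps), 0.05)
})

test_that("contours lie within a pixel of every boundary pixel", {
  m <- disc_mask(64, 64, 20, 1e-5)
  cs <- trace_contours(m)
  v <- m$values
  H <- nrow(v); W <- ncol(v)
  inner <- v[2:(H - 1), 2:(W - 1)] &
    !(v[1:(H - 2), 2:(W - 1)] & v[3:H, 2:(W - 1)] &
        v[2:(H - 1), 1:(W - 2)] & v[2:(H - 1), 3:W])
  bidx <- which(inner, arr.ind = TRUE) + 1L
  pts <- do.call(rbind, lapply(cs, as.matrix))
  ps <- m$pixel_size
  for (k in seq_len(nrow(bidx))) {
    x <- (bidx[k, 2] - 0.5) * ps; y <- (H - bidx[k, 1] + 0.5) * ps
    dmin <- sqrt(min((pts[, 1] - x)^2 + (pts[, 2] - y)^2))
    expect_lt(dmin, 1.5 * ps)
  }
})

test_that("skeletonization recovers bar geometry and Y topology", {
  expect_equal(nrow(skeletonize_to_graph(
    vessel_mask(matrix(FALSE, 8, 8), 1e-5))$nodes), 0L)

  ps <- 1e-5
  m <- rect_mask(20, 110, 8, 13, 5, 104, ps)   # width 6, length 100 px
  g <- skeletonize_to_graph(m)
  expect_equal(nrow(g$edges), 1L)
  expect_lt(abs(g$edges$length - 100 * ps), 2.5 * ps)
  expect_lt(abs(g$edges$radius - 3 * ps), 0.75 * ps)

  # Y shape: three bars meeting at a point -> exactly one degree-3 node
  v <- matrix(FALSE, 60, 60)
  v[30, 10:30] <- TRUE
  for (k in 0:20) {
    v[30 - k, 30 + k] <- TRUE; v[30 + k, 30 + k] <- TRUE
  }
  for (d in -1:1) {  # thicken to width 3
    vv <- v
    v[pmin(pmax(row(v) + d, 1), 60) + (col(v) - 1) * 60] <-
      v[pmin(pmax(row(v) + d, 1), 60) + (col(v) - 1) * 60] | vv
  }
  g <- skeletonize_to_graph(vessel_mask(v, ps))
  degree <- table(factor(c(g$edges$from, g$edges$to),
                         levels = g$nodes$id))
  expect_equal(sum(degree == 3), 1)
})

test_that("skeleton total length is rotation-invariant within 2%", {
  mask <- suppressWarnings(rasterize_graph(small_graph(), 2e-5, 0.00672,
                                           0.00609))
  g0 <- skeletonize_to_graph(mask)
  rot <- vessel_mask(t(mask$values)[ncol(mask$values):1, ], mask$pixel_size)
  g90 <- skeletonize_to_graph(rot)
  expect_lt(abs(graph_total_length(g0) - graph_total_length(g90)) /
              graph_total_length(g0), 0.02)
})
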