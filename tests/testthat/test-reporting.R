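# region statistics, probes, normalized maps, I/O round trips

fabricate_traj <- function(states, flow) {
  structure(list(times = vapply(states, `[[`, numeric(1), "t"),
                 states = states, flow = flow, params = flow$params,
                 config = sim_config(), budget = NULL),
            class = "trajectory")
}

test_that("region_stats: uniform fields, identities, validation", {
  dom <- small_domain(h = 5e-4)
  fl <- uniform_flow_field(dom, default_params())
  g <- fl$grid
  mk <- function(v) matrix(v, g$nx, g$ny)
  st <- conc_state(60, mk(2), mk(3), mk(5))
  traj <- fabricate_traj(list(st), fl)
  rs <- region_stats(traj)
  expect_equal(rs$median_Ci, c(2, 2))
  expect_equal(rs$mean_Ctotal, c(10, 10))
  expect_equal(rs$median_Ctotal, rs$median_Ci + rs$median_Ce + rs$median_Cm)
  expect_error(region_stats(traj, regions = "stroma"),
               class = "petflow_validation_error")
  expect_error(region_stats(traj, times = 999),
               class = "petflow_validation_error")
  # reference table row self-consistency (tumor @ 60 s):
  expect_equal(23.1867 + 0.2301 + 1051.0168, 1074.4336)
})

test_that("region median is permutation-invariant and plain", {
  expect_equal(median(c(1, 3)), 2)   # two-cell region -> midpoint
  dom <- small_domain(h = 5e-4)
  fl <- uniform_flow_field(dom, default_params())
  g <- fl$grid
  set.seed(1)
  Ci <- matrix(runif(g$nx * g$ny), g$nx, g$ny)
  st <- conc_state(0, Ci, Ci * 0, Ci * 0)
  rs <- region_stats(fabricate_traj(list(st), fl))
  sel <- g$region == 2L
  expect_equal(rs$median_Ci[rs$region == "tumor"], median(Ci[sel]))
  expect_equal(rs$median_Ci[rs$region == "tumor"],
               median(sample(Ci[sel])))
})

test_that("probe_tac: exact at nodes, constant on uniform cutlines, bounds", {
  dom <- small_domain(h = 5e-4)
  fl <- uniform_flow_field(dom, default_params())
  g <- fl$grid
  Ci <- outer(seq_len(g$nx), seq_len(g$ny), function(i, j) i + 0.1 * j)
  st <- conc_state(0, Ci, Ci * 0, Ci * 0 + 4)
  traj <- fabricate_traj(list(st), fl)
  pr <- probe_spec(points = data.frame(label = "p1", x = g$xc[3], y = g$yc[5]),
                   cutlines = list(list(start = c(g$xc[2], g$yc[2]),
                                        end = c(g$xc[2], g$yc[8]), n = 13)))
  tac <- probe_tac(traj, pr)
  expect_equal(tac$C_i[tac$probe == "p1"], Ci[3, 5])
  expect_equal(tac$C_m[tac$kind == "cutline"], 4)
  bad <- probe_spec(points = data.frame(label = "x", x = -1, y = 0))
  expect_error(probe_tac(traj, bad), class = "petflow_validation_error")
})

test_that("probes rank by microvascular density on the default fixture", {
  traj <- small_trajectory()
  pr <- default_probes(traj$flow)
  tac <- probe_tac(traj, pr)
  last <- tac[tac$time_s == max(tac$time_s), ]
  expect_gt(last$C_total[last$probe == "tumor_high_mvd"],
            last$C_total[last$probe == "tumor_low_mvd"])
  expect_gt(last$C_total[last$probe == "tumor_high_mvd"],
            last$C_total[last$probe == "distant_low_mvd"])
})

test_that("normalized maps scale to the global C_total maximum", {
  dom <- small_domain(h = 5e-4)
  fl <- uniform_flow_field(dom, default_params())
  g <- fl$grid
  z <- matrix(0, g$nx, g$ny)
  one <- z; one[4, 7] <- 11
  st <- conc_state(0, one, z, z)
  nm <- normalized_maps(fabricate_traj(list(st), fl))
  expect_equal(nm[[1]]$C_total[4, 7], 1)
  expect_equal(sum(nm[[1]]$C_total > 0), 1)
  # scale invariance
  st2 <- conc_state(0, 2 * one, z, z)
  nm2 <- normalized_maps(fabricate_traj(list(st2), fl))
  expect_equal(nm2[[1]]$C_i, nm[[1]]$C_i)
  expect_lte(max(nm[[1]]$C_i), 1)
  # all-zero trajectory is rejected
  expect_error(normalized_maps(fabricate_traj(list(conc_state(0, z, z, z)),
                                              fl)),
               class = "petflow_validation_error")
})

test_that("mesh_convergence validates factors and computes relative changes", {
  expect_error(mesh_convergence(list(), c(2, 1)),
               class = "petflow_validation_error")
})

test_that("CSV outputs round-trip exactly", {
  g <- small_graph()
  stem <- file.path(tempdir(), "rt")
  write_graph_csv(g, stem)
  ed <- read.csv(paste0(stem, "_edges.csv"))
  expect_equal(ed$radius_m, g$edges$radius)
  expect_equal(ed$length_m, g$edges$length)
  nd <- read.csv(paste0(stem, "_nodes.csv"))
  expect_equal(nd$x, g$nodes$x)

  cs <- trace_contours(rect_mask(20, 20, 5, 10, 5, 10))
  p <- tempfile(fileext = ".csv")
  write_contours_csv(cs, p)
  back <- read.csv(p)
  expect_equal(back$x_m, cs[[1]]$x)
  expect_equal(back$y_m, cs[[1]]$y)
})

test_that("raster and graph file formats round-trip", {
  m <- rect_mask(12, 16, 3, 6, 4, 9, 2e-5)
  img <- render_image(m, noise_sigma = 5, seed = 2)
  pp <- tempfile(fileext = ".ppm")
  write_image(img, pp)
  back <- read_image(pp, img$pixel_size)
  expect_equal(back$pixels, round(img$pixels))

  pn <- tempfile(fileext = ".png")
  write_image(img, pn)
  back2 <- read_image(pn, img$pixel_size)
  expect_equal(back2$pixels, round(img$pixels), tolerance = 0.51)

  mp <- tempfile(fileext = ".png")
  write_mask(m, mp)
  rb <- png::readPNG(mp)
  expect_equal(rb == 1, m$values)

  gml <- tempfile(fileext = ".graphml")
  write_graphml(small_graph(), gml)
  gg <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(gg), nrow(small_graph()$nodes))
  expect_equal(igraph::gsize(gg), nrow(small_graph()$edges))
})

test_that("VTK export writes a parseable structured-points file", {
  dom <- small_domain(h = 5e-4)
  fl <- uniform_flow_field(dom, default_params())
  p <- tempfile(fileext = ".vtk")
  write_vtk_grid(p, fl$grid, list(P_i = fl$P_i + 3))
  lines <- readLines(p)
  expect_true(any(grepl("STRUCTURED_POINTS", lines)))
  expect_true(any(grepl(sprintf("DIMENSIONS %d %d 1", fl$grid$nx, fl$grid$ny),
                        lines)))
  vals <- as.numeric(lines[(which(lines == "LOOKUP_TABLE default") + 1):
                             length(lines)])
  expect_equal(vals, rep(3, fl$grid$nx * fl$grid$ny))
})
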