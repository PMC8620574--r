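# intravascular Poiseuille solve, Starling exchange, IFP Poisson solve,
# Darcy velocity, coupled fixed point

test_that("straight tube: linear pressure drop and Poiseuille flow", {
  L <- 1e-3; r <- 1e-5; mu <- 3e-3
  vp <- solve_vessel_pressure(straight_tube(L, r, 3333, 0), viscosity = mu)
  expect_equal(unname(vp$pressure[2]), 1666.5)
  q_expect <- pi * r^4 * 3333 / (8 * mu * L)
  expect_equal(unname(vp$edge_flow[1]), q_expect, tolerance = 1e-12)
  expect_lt(vp$residual, 1e-10)
})

test_that("symmetric Y splits flow equally", {
  L <- 1e-3; r <- 8e-6
  g <- vessel_graph(
    nodes = data.frame(id = 1:4, x = c(0, L, 2 * L, 2 * L),
                       y = c(0, 0, L, -L)),
    edges = data.frame(from = c(1, 2, 2), to = c(2, 3, 4), radius = r,
                       length = c(L, L * sqrt(2), L * sqrt(2))),
    boundary = data.frame(node = c(1, 3, 4), pressure = c(2000, 0, 0)))
  vp <- solve_vessel_pressure(g)
  expect_equal(vp$edge_flow[2], vp$edge_flow[3], tolerance = 1e-12)
  expect_equal(vp$edge_flow[1], vp$edge_flow[2] + vp$edge_flow[3],
               tolerance = 1e-12)
})

test_that("random network conserves mass to 1e-10 and floating parts error", {
  set.seed(99)
  n <- 40
  nodes <- data.frame(id = 1:n, x = runif(n), y = runif(n))
  # random spanning tree + extra chords = 50 edges
  from <- 2:n; to <- vapply(2:n, function(k) sample.int(k - 1, 1), 1L)
  extra <- cbind(sample.int(n, 11), sample.int(n, 11))
  extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
  edges <- data.frame(from = c(from, extra[, 1]), to = c(to, extra[, 2]),
                      radius = runif(n - 1 + nrow(extra), 5e-6, 2e-5),
                      length = NA_real_)
  g <- vessel_graph(nodes, edges,
                    data.frame(node = c(1, n), pressure = c(1500, 0)))
  vp <- solve_vessel_pressure(g)
  imbalance <- abs(sum(vp$boundary_flow$flow)) / max(abs(vp$edge_flow))
  expect_lt(imbalance, 1e-10)

  # disconnected component without boundary pressure -> configuration error
  g2 <- vessel_graph(rbind(nodes, data.frame(id = n + 1:2, x = 2, y = 2:3)),
                     rbind(edges, data.frame(from = n + 1, to = n + 2,
                                             radius = 1e-5, length = NA)),
                     data.frame(node = 1, pressure = 100))
  expect_error(solve_vessel_pressure(g2), class = "petflow_solver_error")
})

test_that("Starling exchange: equilibrium, tumor lymph, hand value", {
  dom <- small_domain(h = 3e-4)
  grid <- domain_grid(dom)
  pars <- default_params()
  w <- matrix(pars$normal$S_over_V, grid$nx, grid$ny)

  # P_b - P_i = sigma_s (pi_b - pi_i) -> phi_b = 0 (per region)
  sig_dpi <- matrix(0, grid$nx, grid$ny)
  sig_dpi[grid$region == 1L] <- 0.91 * mmHg_to_Pa(10)
  sig_dpi[grid$region == 2L] <- 0.82 * mmHg_to_Pa(5)
  ex <- starling_exchange(sig_dpi, matrix(0, grid$nx, grid$ny), grid, pars, w)
  expect_equal(max(abs(ex$phi_b)), 0, tolerance = 1e-18)

  # tumor has no lymphatics under defaults, normal does
  ex2 <- starling_exchange(matrix(mmHg_to_Pa(25), grid$nx, grid$ny),
                           matrix(100, grid$nx, grid$ny), grid, pars, w)
  expect_true(all(ex2$phi_L[grid$region == 2L] == 0))
  expect_true(all(ex2$phi_L[grid$region == 1L] > 0))

  # hand evaluation (independent arithmetic): normal tissue, P_b = 25 mmHg,
  # P_i = 0, S/V = 2e4; L_p = 0.36e-7 cm/(mmHg s)
  phi_hand <- (0.36e-7 * 1e-2 / 133.322) * 2e4 *
    (25 * 133.322 - 0 - 0.91 * (20 - 10) * 133.322)
  expect_equal(phi_hand, 1.14e-4, tolerance = 0.01)   # spec-quoted value
  ex3 <- starling_exchange(matrix(mmHg_to_Pa(25), grid$nx, grid$ny),
                           matrix(0, grid$nx, grid$ny), grid, pars, w)
  expect_equal(ex3$phi_b[1, 1], phi_hand, tolerance = 1e-12)
})

test_that("IFP solve: zero source, Bessel-disc oracle, maximum principle", {
  dom <- small_domain(h = 1e-4)
  grid <- domain_grid(dom)
  pars <- default_params()
  z <- matrix(0, grid$nx, grid$ny)
  sol <- solve_ifp(grid, pars0 <- local({
    p <- pars; p$normal$L_pL_SV <- 0; p
  }), Lambda = z, P_src = z, boundary_pressure = 0)
  expect_equal(max(abs(sol$P_i)), 0)

  # uniform-source disc vs modified-Bessel profile, alpha = 4; P(R) = 0 is
  # imposed by a stiff sink outside the disc, antialiased with subcell
  # coverage fractions so the effective boundary sits on the true circle
  l2_err <- function(n, aa = 4L) {
    L <- 0.04; R <- 0.0115
    dom <- domain_spec(width = L, height = L, tumor_diameter = 2 * R,
                       grid_spacing = L / n)
    grid <- domain_grid(dom)
    kappa <- 3e-14
    alpha <- 4
    Lam <- alpha^2 * kappa / R^2
    Pe_src <- 2000
    pars <- default_params()
    pars$normal$kappa <- pars$tumor$kappa <- kappa
    pars$normal$L_pL_SV <- pars$tumor$L_pL_SV <- 0
    f_in <- matrix(0, grid$nx, grid$ny)
    off <- (seq_len(aa) - 0.5) / aa - 0.5
    for (ox in off) for (oy in off) {
      dx <- outer(grid$xc + ox * grid$hx - L / 2, rep(1, grid$ny))
      dy <- outer(rep(1, grid$nx), grid$yc + oy * grid$hy - L / 2)
      f_in <- f_in + ((dx^2 + dy^2) <= R^2)
    }
    f_in <- f_in / aa^2
    Lambda <- Lam * f_in + 1e5 * Lam * (1 - f_in)
    P_src <- Pe_src * Lam * f_in / Lambda
    P <- solve_ifp(grid, pars, Lambda, P_src, 0)$P_i
    dx <- outer(grid$xc - L / 2, rep(1, grid$ny))
    dy <- outer(rep(1, grid$nx), grid$yc - L / 2)
    rr <- sqrt(dx^2 + dy^2)
    sel <- rr < R - 1.5 * grid$hx
    ana <- radial_ifp_analytic(R, Pe_src, alpha, pmin(rr[sel], R))
    sqrt(sum((P[sel] - ana)^2) / sum(ana^2))
  }
  e_coarse <- l2_err(80)
  e_fine <- l2_err(160)
  expect_lt(e_fine, 0.02)
  expect_lt(e_fine, e_coarse)

  # maximum principle on the coupled fixture
  fl <- small_flow()
  pars <- fl$params
  cap <- max(
    effective_filtration_pressure(max(fl$P_b), pars$normal),
    effective_filtration_pressure(max(fl$P_b), pars$tumor))
  expect_lte(max(fl$P_i), cap + 1e-9)
})

test_that("Darcy velocity: uniform and linear pressure fields", {
  dom <- small_domain(h = 2e-4)
  grid <- domain_grid(dom)
  kap <- 5e-15
  v0 <- darcy_velocity(matrix(7, grid$nx, grid$ny), grid, kap)
  expect_equal(max(abs(v0$speed)), 0)

  dP <- 100
  Pl <- outer(grid$xc, rep(1, grid$ny)) * dP / (grid$nx * grid$hx)
  v1 <- darcy_velocity(Pl, grid, kap)
  expect_equal(max(abs(v1$vx[2:(grid$nx - 1), ] +
                         kap * dP / (grid$nx * grid$hx))), 0,
               tolerance = 1e-20)
  expect_equal(max(abs(v1$vy)), 0, tolerance = 1e-20)
})

test_that("coupled flow: decoupled limit, convergence, balance, ordering", {
  dom <- small_domain()
  g <- small_graph()

  # zero L_p decouples: vessel pressures = no-leak solve, P_i = boundary value
  pars0 <- default_params()
  pars0$normal$L_p <- pars0$tumor$L_p <- 0
  pars0$normal$L_pL_SV <- 0
  fl0 <- couple_flow(g, dom, pars0)
  expect_equal(max(abs(fl0$P_i)), 0, tolerance = 1e-12)
  vp_ref <- solve_vessel_pressure(g)
  expect_equal(unname(fl0$vessel$pressure), unname(vp_ref$pressure),
               tolerance = 1e-10)

  fl <- small_flow()
  # successive-iterate residual non-increasing after iteration 2
  h <- fl$history
  if (length(h) > 2) expect_true(all(diff(h[-1]) <= 1e-12))
  # global fluid mass balance within 1%
  bal <- fl$balance
  expect_lt(abs(bal$filtration - bal$drainage - bal$boundary_outflow) /
              bal$filtration, 0.01)
  # phi_b localized to vasculature; phi_L absent in tumor
  expect_true(all(fl$phi_b[fl$vessel_weight == 0] == 0))
  expect_true(all(fl$phi_L[fl$grid$region == 2L] == 0))
  # discrete Darcy identity v = -kappa grad P at an interior point
  kapn <- fl$params$normal$kappa
  i <- 5; j <- 10
  gxp <- (fl$P_i[i + 1, j] - fl$P_i[i - 1, j]) / (2 * fl$grid$hx)
  expect_equal(fl$vx[i, j], -kapn * gxp, tolerance = 1e-12)

  # tumor params raise IFP over an equally vascularized all-normal tissue
  pars_n <- default_params()
  pars_n$tumor <- pars_n$normal
  fl_n <- couple_flow(g, dom, pars_n)
  expect_gt(max(fl$P_i[fl$grid$tumor]), max(fl_n$P_i[fl_n$grid$tumor]))

  # monotonicity: higher tumor L_p weakly raises max tumor IFP
  pars_hi <- default_params()
  pars_hi$tumor$L_p <- pars_hi$tumor$L_p * 2
  fl_hi <- couple_flow(g, dom, pars_hi)
  expect_gte(max(fl_hi$P_i[fl_hi$grid$tumor]) + 1e-9,
             max(fl$P_i[fl$grid$tumor]))
})
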