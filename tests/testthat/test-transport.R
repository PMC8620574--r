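# transvascular exchange algebra and the CDR time integrator

test_that("Peclet number: trivial, hand value, proportionality, errors", {
  expect_equal(peclet_number(0, 0.9, 3.75e-7, 2e4), 0)
  # hand evaluation: phi_b = 1.14e-4, sigma_f = 0.9, P S/V = 7.5e-3 1/s
  expect_equal(peclet_number(1.14e-4, 0.9, 3.75e-7, 2e4),
               1.14e-4 * 0.1 / (3.75e-7 * 2e4), tolerance = 1e-12)
  expect_equal(peclet_number(1.14e-4, 0.9, 3.75e-7, 2e4), 1.52e-3,
               tolerance = 0.01)
  expect_equal(peclet_number(1e-4, 0.9, 2 * 3.75e-7, 2e4),
               peclet_number(1e-4, 0.9, 3.75e-7, 2e4) / 2)
  expect_error(peclet_number(1e-4, 0.9, 0, 2e4),
               class = "petflow_validation_error")
})

test_that("Patlak flux: diffusion limit and brute-force formula", {
  z <- matrix(0, 2, 2)
  PSV <- z + 7.5e-3
  # phi_b = 0 -> pure diffusion limit
  expect_equal(transvascular_solute_flux(100, z + 20, z, 0.9, PSV),
               PSV * 80, tolerance = 1e-14)
  # C_p = C_i, phi_b = 0 -> zero
  expect_equal(max(abs(transvascular_solute_flux(50, z + 50, z, 0.9, PSV))),
               0)
  # independent brute-force evaluation of the formula
  phi_b <- 1.14e-4; sf <- 0.9; psv <- 7.5e-3; Cp <- 100; Ci <- 0
  Pe <- phi_b * (1 - sf) / psv
  expected <- phi_b * (1 - sf) * Cp + psv * (Cp - Ci) * Pe / (exp(Pe) - 1)
  got <- transvascular_solute_flux(Cp, z + Ci, z + phi_b, sf, z + psv)
  expect_equal(got[1, 1], expected, tolerance = 1e-12)
  # off-vessel cells carry no flux
  got2 <- transvascular_solute_flux(Cp, z, z, sf, z)
  expect_equal(max(abs(got2)), 0)
})

test_that("lymphatic drain is an elementwise product", {
  z <- matrix(0, 3, 3)
  expect_equal(max(abs(lymphatic_solute_drain(z + 50, z))), 0)
  expect_equal(max(abs(lymphatic_solute_drain(z, z + 1e-4))), 0)
  expect_equal(lymphatic_solute_drain(z + 50, z + 1e-4)[1, 1], 5e-3)
})

zeroed_params <- function() {
  p <- default_params()
  for (r in c("normal", "tumor"))
    for (f in c("L3", "L4", "L5", "L_pL_SV", "D_eff"))
      p[[r]][[f]] <- 0
  p
}

test_that("advance: frozen dynamics leave the state unchanged", {
  pars <- zeroed_params()
  dom <- small_domain(h = 5e-4)
  fl <- uniform_flow_field(dom, pars, phi_b = 0)
  fl$vessel_weight[] <- 0   # no exchange at all
  op <- transport_operator(fl, pars, sim_config(dt = 1))
  g <- fl$grid
  Ci <- matrix(runif(g$nx * g$ny), g$nx, g$ny)
  st <- conc_state(0, Ci, Ci * 0, Ci * 0)
  st2 <- advance(st, op, aif_biexponential())
  expect_equal(st2$C_i, Ci, tolerance = 1e-12)
  expect_equal(max(st2$C_e), 0)
  expect_equal(max(st2$C_m), 0)
})

test_that("advance: kinetic cascade keeps C_m at zero when L3 = 0", {
  pars <- zeroed_params()   # L3 = L5 = 0
  dom <- small_domain(h = 5e-4)
  fl <- uniform_flow_field(dom, pars, phi_b = 1e-4)
  op <- transport_operator(fl, pars, sim_config(dt = 1))
  g <- fl$grid
  st <- conc_state(0, matrix(5, g$nx, g$ny), matrix(0, g$nx, g$ny),
                   matrix(0, g$nx, g$ny))
  for (k in 1:20) st <- advance(st, op, aif_biexponential())
  expect_equal(max(st$C_m), 0)
  expect_equal(max(st$C_e), 0)
})

test_that("uniform configuration matches the well-mixed oracle to 1e-3", {
  dom <- domain_spec(width = 0.004, height = 0.0035,
                     tumor_diameter = 0.0012, grid_spacing = 5e-4)
  pars <- default_params()
  pars$tumor <- pars$normal
  phi_b <- 1.14e-4; phi_L <- 1e-5
  fl <- uniform_flow_field(dom, pars, phi_b = phi_b, phi_L = phi_L)
  aif <- aif_biexponential()
  traj <- run_simulation(fl, aif,
                         config = sim_config(dt = 1, t_end = 3600,
                                             output_times = 3600))
  st <- traj$states[[1]]
  wm <- wellmixed_params(pars$normal$L3, pars$normal$L4, pars$normal$L5,
                         pars$normal$sigma_f,
                         PSV = pars$normal$P_perm * pars$normal$S_over_V,
                         phi_b = phi_b, phi_L = phi_L)
  ana <- wellmixed_solution(wm, aif, 3600)
  for (f in c("C_i", "C_e", "C_m")) {
    num <- st[[f]][3, 3]
    expect_lt(abs(num - ana[[f]]) / abs(ana[[f]]), 1e-3)
  }
})

test_that("zero AIF keeps every compartment at zero", {
  aif0 <- aif_table(c(0, 4000), c(0, 0))
  traj <- run_simulation(small_flow(), aif0,
                         config = sim_config(dt = 2, t_end = 60,
                                             output_times = 60))
  st <- traj$states[[1]]
  expect_equal(max(total_concentration(st)), 0)
})

test_that("default fixture: nonnegative, monotone C_m, tumor > normal, C_i early", {
  traj <- small_trajectory()
  grid <- traj$flow$grid
  prev_Cm <- NULL
  for (k in seq_along(traj$times)) {
    st <- traj$states[[k]]
    expect_gte(min(st$C_i), 0)
    expect_gte(min(st$C_e), 0)
    expect_gte(min(st$C_m), 0)
    tot <- total_concentration(st)
    expect_gt(mean(tot[grid$tumor]), mean(tot[!grid$tumor]))
    if (!is.null(prev_Cm)) expect_gte(min(st$C_m - prev_Cm), 0)
    prev_Cm <- st$C_m
  }
  # early times: free extracellular tracer dominates at the tumor centre
  ic <- round(grid$nx / 2); jc <- round(grid$ny / 2)
  for (t in c(60, 120, 180)) {
    st <- traj$states[[match(t, traj$times)]]
    expect_gt(st$C_i[ic, jc], st$C_e[ic, jc])
  }
})

test_that("closed-domain diffusion-convection conserves total C_i to 0.1%", {
  pars <- zeroed_params()
  pars$normal$D_eff <- pars$tumor$D_eff <- 1e-9
  dom <- small_domain(h = 2e-4)
  fl <- uniform_flow_field(dom, pars, phi_b = 0)
  fl$vessel_weight[] <- 0
  # gentle rotational-ish velocity field, zero at the boundary
  g <- fl$grid
  xs <- outer(g$xc / max(g$xc), rep(1, g$ny)); ys <- outer(rep(1, g$nx), g$yc / max(g$yc))
  fl$vx <- 1e-7 * sin(pi * xs) * sin(pi * ys)
  fl$vy <- 1e-7 * sin(pi * ys) * sin(pi * xs)
  op <- transport_operator(fl, pars,
                           sim_config(dt = 1, conservative = TRUE,
                                      closed_domain = TRUE))
  Ci <- exp(-((xs - 0.5)^2 + (ys - 0.5)^2) / 0.02)
  st <- conc_state(0, Ci, Ci * 0, Ci * 0)
  m0 <- sum(st$C_i)
  for (k in 1:100) st <- advance(st, op, aif_biexponential())
  expect_lt(abs(sum(st$C_i) - m0) / m0, 0.001)
})

test_that("per-step solute balance closes within 1%", {
  traj <- run_simulation(small_flow(), aif_biexponential(),
                         config = sim_config(dt = 1, t_end = 300,
                                             output_times = 300,
                                             conservative = TRUE,
                                             track_balance = TRUE))
  b <- traj$budget
  resid <- abs(b$d_mass - (b$exchange_gain - b$boundary_adv_out))
  expect_lt(max(resid / pmax(abs(b$exchange_gain), abs(b$d_mass))), 0.01)
})

test_that("CFL violation is caught", {
  fl <- small_flow()
  fl$vx <- fl$vx + 1e-3   # absurd interstitial speed
  expect_error(transport_operator(fl, fl$params, sim_config(dt = 1)),
               class = "petflow_solver_error")
})

test_that("AIF containers evaluate consistently", {
  a <- aif_biexponential(A = 100, tau_rise = 30, tau_wash = 1800)
  expect_equal(aif_eval(a, 0), 0)
  expect_true(all(aif_eval(a, c(10, 100, 1000)) > 0))
  tt <- seq(0, 100, by = 5)
  tab <- aif_table(tt, aif_eval(a, tt))
  expect_equal(aif_eval(tab, 37.5),
               mean(aif_eval(a, c(35, 40))), tolerance = 1e-10)
  p <- tempfile(fileext = ".csv")
  write.csv(data.frame(t_s = tt, Cp_mol_per_m3 = aif_eval(a, tt)), p,
            row.names = FALSE)
  expect_equal(aif_eval(read_aif_csv(p), 50), aif_eval(tab, 50))
})
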