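# Transient tracer transport: three tissue compartments on the steady flow
# field. C_i (free extracellular) obeys a convection-diffusion-reaction
# equation fed transvascularly from plasma (Patlak flux), C_e (free
# intracellular) and C_m (phosphorylated, trapped) are local kinetic pools:
#
#   dC_i/dt = div(D_eff grad C_i) - v.grad(C_i) - L3 C_i + L4 C_e
#             + Phi_bt - Phi_Lt
#   dC_e/dt = L3 C_i - (L4 + L5) C_e
#   dC_m/dt = L5 C_e
#
#   Phi_bt = phi_b (1 - sigma_f) C_p + (P S/V)(C_p - C_i) Pe/(e^Pe - 1)
#   Pe     = phi_b (1 - sigma_f) / (P S/V)
#   Phi_Lt = phi_L C_i
#
# Scheme: operator splitting per step - vectorized RK4 for the pointwise
# kinetics/exchange, explicit first-order upwind convection (CFL-checked),
# implicit (backward Euler) diffusion with a cached sparse Cholesky factor.

# --- arterial input function ----------------------------------------------

#' Parametric arterial input function (bolus plus washout)
#'
#' `C_p(t) = A (exp(-t/tau_wash) - exp(-t/tau_rise))`, zero at `t = 0`,
#' peaking after roughly `tau_rise log(tau_wash/tau_rise)` seconds.
#'
#' @param A amplitude (mol/m^3), default 100.
#' @param tau_rise bolus rise time constant (s), default 30.
#' @param tau_wash washout time constant (s), default 1800.
#' @return object of class `aif`.
#' @export
aif_biexponential <- function(A = 100, tau_rise = 30, tau_wash = 1800) {
  stopifnot(A >= 0, tau_rise > 0, tau_wash > tau_rise)
  structure(list(kind = "biexp", A = A, k1 = 1 / tau_rise, k2 = 1 / tau_wash),
            class = "aif")
}

#' Tabulated arterial input function
#'
#' Linear interpolation between samples; constant extrapolation beyond the
#' last sample, zero before the first.
#'
#' @param t sample times (s), increasing.
#' @param C_p plasma concentrations (mol/m^3), non-negative.
#' @return object of class `aif`.
#' @export
aif_table <- function(t, C_p) {
  stopifnot(length(t) == length(C_p), !is.unsorted(t), all(C_p >= 0))
  structure(list(kind = "table", t = as.numeric(t), C_p = as.numeric(C_p)),
            class = "aif")
}

#' Read a tabulated AIF from CSV (columns t_s, Cp_mol_per_m3)
#' @param path CSV file path.
#' @return object of class `aif`.
#' @export
read_aif_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("t_s", "Cp_mol_per_m3") %in% names(d)))
    stop_format("read_aif_csv: need columns t_s, Cp_mol_per_m3")
  aif_table(d$t_s, d$Cp_mol_per_m3)
}

#' Evaluate an AIF at times `t`
#' @param aif an `aif` object.
#' @param t times (s).
#' @return plasma concentration(s), mol/m^3.
#' @export
aif_eval <- function(aif, t) {
  stopifnot(inherits(aif, "aif"))
  if (aif$kind == "biexp") {
    pmax(aif$A * (exp(-aif$k2 * pmax(t, 0)) - exp(-aif$k1 * pmax(t, 0))), 0)
  } else {
    out <- approx(aif$t, aif$C_p, xout = t, rule = 2)$y
    out[t < aif$t[1]] <- 0
    pmax(out, 0)
  }
}

# --- pointwise exchange algebra -------------------------------------------

#' Transvascular Peclet number
#'
#' `Pe = phi_b (1 - sigma_f) / (P S/V)`: the ratio of convective to
#' diffusive transvascular solute transport. Elementwise on grids.
#'
#' @param phi_b filtration rate (1/s).
#' @param sigma_f filtration reflection coefficient.
#' @param P_perm vascular permeability (m/s).
#' @param S_over_V vessel surface per tissue volume (1/m).
#' @return Peclet number, same shape as `phi_b`.
#' @export
peclet_number <- function(phi_b, sigma_f, P_perm, S_over_V) {
  denom <- P_perm * S_over_V
  if (any(denom <= 0))
    stop_validation("peclet_number: P_perm * S_over_V must be > 0")
  phi_b * (1 - sigma_f) / denom
}

# Pe / (exp(Pe) - 1), stable at Pe -> 0 (limit 1)
pe_factor <- function(Pe) {
  out <- Pe
  small <- abs(Pe) < 1e-6
  out[small] <- 1 - Pe[small] / 2 + Pe[small]^2 / 12
  out[!small] <- Pe[!small] / expm1(Pe[!small])
  out
}

#' Transvascular solute flux (Patlak model)
#'
#' `Phi_bt = phi_b (1 - sigma_f) C_p + (P S/V)(C_p - C_i) Pe/(e^Pe - 1)`,
#' evaluated elementwise with a series expansion of `Pe/(e^Pe - 1)` near
#' `Pe = 0`. Where `PSV = 0` (no vasculature) the flux is zero.
#'
#' @param C_p plasma concentration (scalar or grid, mol/m^3).
#' @param C_i free extracellular concentration (grid).
#' @param phi_b filtration rate field (1/s).
#' @param sigma_f filtration reflection coefficient (scalar or grid).
#' @param PSV permeability-surface product `P * S/V` (1/s), localized to the
#'   vasculature (zero off-vessel).
#' @return flux field, mol/(m^3 s).
#' @export
transvascular_solute_flux <- function(C_p, C_i, phi_b, sigma_f, PSV) {
  conv <- phi_b * (1 - sigma_f)
  Pe <- matrix(0, nrow(as.matrix(phi_b)), ncol(as.matrix(phi_b)))
  on <- PSV > 0
  Pe[on] <- conv[on] / PSV[on]
  out <- conv * C_p + PSV * (C_p - C_i) * pe_factor(Pe)
  out[!on & conv == 0] <- 0
  out
}

#' Lymphatic solute drain
#'
#' `Phi_Lt = phi_L C_i`; zero wherever lymphatics are absent (tumor, under
#' default parameters).
#'
#' @param C_i free extracellular concentration (grid).
#' @param phi_L lymphatic drainage rate field (1/s).
#' @return drain field, mol/(m^3 s).
#' @export
lymphatic_solute_drain <- function(C_i, phi_L) phi_L * C_i

# --- state and configuration ----------------------------------------------

#' Concentration state at one time point
#' @param t time (s).
#' @param C_i,C_e,C_m compartment grids (mol/m^3), non-negative.
#' @return object of class `conc_state`; `C_total` is available via
#'   [total_concentration].
#' @export
conc_state <- function(t, C_i, C_e, C_m) {
  structure(list(t = t, C_i = C_i, C_e = C_e, C_m = C_m),
            class = "conc_state")
}

#' Total tracer concentration `C_i + C_e + C_m`
#' @param state a [conc_state].
#' @return matrix, mol/m^3.
#' @export
total_concentration <- function(state) state$C_i + state$C_e + state$C_m

#' Simulation controls
#' @param dt time step (s), default 1.
#' @param t_end final time (s), default 3600.
#' @param output_times times at which states are emitted (s); default the
#'   reporting times 60, 120, 180, 600, 1800, 3600.
#' @param n_substeps RK4 substeps for the kinetics within one `dt`.
#' @param conservative use flux-form (conservative) upwind convection
#'   instead of the default advective form `v . grad C`.
#' @param closed_domain suppress boundary advective outflow (used by
#'   conservation tests).
#' @param track_balance record a per-step mass budget.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(dt = 1, t_end = 3600,
                       output_times = c(60, 120, 180, 600, 1800, 3600),
                       n_substeps = 4L, conservative = FALSE,
                       closed_domain = FALSE, track_balance = FALSE) {
  if (dt <= 0) stop_validation("sim_config: dt must be > 0")
  output_times <- sort(unique(output_times))
  if (any(output_times < 0 | output_times > t_end + 1e-9))
    stop_validation("sim_config: output_times must lie in [0, t_end]")
  structure(list(dt = dt, t_end = t_end, output_times = output_times,
                 n_substeps = as.integer(n_substeps),
                 conservative = conservative, closed_domain = closed_domain,
                 track_balance = track_balance),
            class = "sim_config")
}

#' Precompute the transport operator for a steady flow field
#'
#' Builds the per-cell kinetic/exchange coefficient fields and the cached
#' sparse Cholesky factorization of the implicit diffusion system
#' `(I/dt + L_D) C = C_prev/dt` (zero-flux outer boundary, harmonic
#' region-dependent diffusivity at faces, flux-conservative across the tumor
#' interface). Verifies the convection CFL condition for `dt`.
#'
#' @param flow a `flow_field` from [couple_flow].
#' @param params parameter list (default: the flow field's).
#' @param config a [sim_config].
#' @return opaque list used by [advance] / [run_simulation].
#' @export
transport_operator <- function(flow, params = flow$params,
                               config = sim_config()) {
  grid <- flow$grid
  dt <- config$dt
  cfl <- dt * max(max(abs(flow$vx)) / grid$hx, max(abs(flow$vy)) / grid$hy)
  if (cfl > 1)
    stop_solver(sprintf(
      "transport_operator: convection CFL %.3g > 1; reduce dt", cfl))

  sigma_f <- param_field(grid, params, "sigma_f")
  PSV <- param_field(grid, params, "P_perm") * flow$vessel_weight
  conv <- flow$phi_b * (1 - sigma_f)
  Pe <- matrix(0, grid$nx, grid$ny)
  on <- PSV > 0
  Pe[on] <- conv[on] / PSV[on]
  k_ex <- PSV * pe_factor(Pe)       # diffusive exchange conductance, 1/s
  a1 <- conv + k_ex                 # multiplies C_p in dC_i/dt
  phi_L_pos <- pmax(flow$phi_L, 0)
  a2 <- param_field(grid, params, "L3") + k_ex + phi_L_pos  # decay of C_i

  # implicit diffusion: FV operator over internal faces only (natural
  # zero-flux boundary); SPD system factorized once
  nx <- grid$nx; ny <- grid$ny; hx <- grid$hx; hy <- grid$hy
  n <- nx * ny
  D <- blend_field(grid, params, "D_eff")
  idx <- function(i, j) i + (j - 1L) * nx
  kW <- D[1:(nx - 1), , drop = FALSE]; kE <- D[2:nx, , drop = FALSE]
  Tx <- as.vector(harm(kW, kE) * hy / hx)
  iw <- as.vector(outer(1:(nx - 1), 1:ny, idx))
  ie <- as.vector(outer(2:nx, 1:ny, idx))
  kS <- D[, 1:(ny - 1), drop = FALSE]; kN <- D[, 2:ny, drop = FALSE]
  Ty <- as.vector(harm(kS, kN) * hx / hy)
  is_ <- as.vector(outer(1:nx, 1:(ny - 1), idx))
  in_ <- as.vector(outer(1:nx, 2:ny, idx))
  dd <- numeric(n)
  dd[iw] <- dd[iw] + Tx; dd[ie] <- dd[ie] + Tx
  dd[is_] <- dd[is_] + Ty; dd[in_] <- dd[in_] + Ty
  area <- hx * hy
  A <- Matrix::sparseMatrix(
    i = c(iw, ie, is_, in_, 1:n), j = c(ie, iw, in_, is_, 1:n),
    x = c(-Tx, -Tx, -Ty, -Ty, dd + area / dt), dims = c(n, n))
  factor <- Matrix::Cholesky(Matrix::forceSymmetric(A))

  list(grid = grid, dt = dt, config = config, params = params,
       a1 = a1, a2 = a2,
       L3 = param_field(grid, params, "L3"),
       L4 = param_field(grid, params, "L4"),
       L5 = param_field(grid, params, "L5"),
       vx = flow$vx, vy = flow$vy, factor = factor, area = area,
       k_ex = k_ex, conv = conv, phi_L = phi_L_pos,
       phi_net = flow$phi_b - flow$phi_L)
}

# explicit upwind convection increment for C (advective form v.grad C);
# boundary cells use one-sided interior differences (open boundary)
upwind_advect <- function(C, op) {
  vx <- op$vx; vy <- op$vy
  nx <- op$grid$nx; ny <- op$grid$ny
  hx <- op$grid$hx; hy <- op$grid$hy
  gxm <- matrix(0, nx, ny); gxp <- matrix(0, nx, ny)
  gxm[2:nx, ] <- (C[2:nx, ] - C[1:(nx - 1), ]) / hx   # backward
  gxp[1:(nx - 1), ] <- (C[2:nx, ] - C[1:(nx - 1), ]) / hx  # forward
  gym <- matrix(0, nx, ny); gyp <- matrix(0, nx, ny)
  gym[, 2:ny] <- (C[, 2:ny] - C[, 1:(ny - 1)]) / hy
  gyp[, 1:(ny - 1)] <- (C[, 2:ny] - C[, 1:(ny - 1)]) / hy
  adv <- pmax(vx, 0) * gxm + pmin(vx, 0) * gxp +
    pmax(vy, 0) * gym + pmin(vy, 0) * gyp
  -adv
}

# conservative (flux-form) upwind convection increment -div(vC); boundary
# faces: outflow upwinds the interior value, inflow carries zero from outside
# unless closed_domain. Returns list(rate, boundary_outflux_mass_rate).
flux_advect <- function(C, op) {
  vx <- op$vx; vy <- op$vy
  nx <- op$grid$nx; ny <- op$grid$ny
  hx <- op$grid$hx; hy <- op$grid$hy
  closed <- op$config$closed_domain
  # x faces (internal): velocity = mean of adjacent cells
  vfx <- (vx[1:(nx - 1), ] + vx[2:nx, ]) / 2
  Fx <- pmax(vfx, 0) * C[1:(nx - 1), ] + pmin(vfx, 0) * C[2:nx, ]  # per unit length
  vfy <- (vy[, 1:(ny - 1)] + vy[, 2:ny]) / 2
  Fy <- pmax(vfy, 0) * C[, 1:(ny - 1)] + pmin(vfy, 0) * C[, 2:ny]
  rate <- matrix(0, nx, ny)
  rate[1:(nx - 1), ] <- rate[1:(nx - 1), ] - Fx / hx
  rate[2:nx, ] <- rate[2:nx, ] + Fx / hx
  rate[, 1:(ny - 1)] <- rate[, 1:(ny - 1)] - Fy / hy
  rate[, 2:ny] <- rate[, 2:ny] + Fy / hy
  out_mass <- 0
  if (!closed) {
    # boundary faces: outflow only (inflow concentration 0)
    fL <- pmin(vx[1, ], 0) * C[1, ];  rate[1, ] <- rate[1, ] + fL / hx
    fR <- pmax(vx[nx, ], 0) * C[nx, ]; rate[nx, ] <- rate[nx, ] - fR / hx
    fB <- pmin(vy[, 1], 0) * C[, 1];  rate[, 1] <- rate[, 1] + fB / hy
    fT <- pmax(vy[, ny], 0) * C[, ny]; rate[, ny] <- rate[, ny] - fT / hy
    out_mass <- (sum(-fL) + sum(fR)) * hy + (sum(-fB) + sum(fT)) * hx
  }
  list(rate = rate, boundary_outflux = out_mass)
}

#' Advance the tracer state by one time step
#'
#' Operator splitting: RK4 kinetics/exchange (with the AIF sampled at the
#' substep times), explicit upwind convection of `C_i`, implicit diffusion
#' of `C_i`. Negative concentrations beyond a roundoff tolerance raise a
#' scheme error (the step size is too large); roundoff-level negatives are
#' clipped to zero.
#'
#' @param state a [conc_state].
#' @param op operator from [transport_operator].
#' @param aif an `aif`.
#' @return the advanced [conc_state]; attribute `budget` carries the step
#'   mass bookkeeping when `track_balance` was requested.
#' @export
advance <- function(state, op, aif) {
  dt <- op$dt
  t0 <- state$t
  Ci <- state$C_i; Ce <- state$C_e; Cm <- state$C_m
  grid <- op$grid
  track <- op$config$track_balance
  mass0 <- if (track) sum(Ci + Ce + Cm) * op$area else NA_real_

  # 1) kinetics + transvascular exchange, RK4 substeps
  h <- dt / op$config$n_substeps
  gain <- 0
  for (s in seq_len(op$config$n_substeps)) {
    ts <- t0 + (s - 1) * h
    cp0 <- aif_eval(aif, ts); cph <- aif_eval(aif, ts + h / 2)
    cp1 <- aif_eval(aif, ts + h)
    f <- function(ci, ce, cp) {
      list(ci = op$a1 * cp - op$a2 * ci + op$L4 * ce,
           ce = op$L3 * ci - (op$L4 + op$L5) * ce)
    }
    k1 <- f(Ci, Ce, cp0)
    k2 <- f(Ci + h / 2 * k1$ci, Ce + h / 2 * k1$ce, cph)
    k3 <- f(Ci + h / 2 * k2$ci, Ce + h / 2 * k2$ce, cph)
    k4 <- f(Ci + h * k3$ci, Ce + h * k3$ce, cp1)
    dCi <- h / 6 * (k1$ci + 2 * k2$ci + 2 * k3$ci + k4$ci)
    dCe <- h / 6 * (k1$ce + 2 * k2$ce + 2 * k3$ce + k4$ce)
    # C_m via the same quadrature of L5 Ce along the stages
    dCm <- h / 6 * op$L5 * (Ce + 2 * (Ce + h / 2 * k1$ce) +
                              2 * (Ce + h / 2 * k2$ce) + (Ce + h * k3$ce))
    if (track) gain <- gain + sum(dCi + dCe + dCm) * op$area
    Ci <- Ci + dCi; Ce <- Ce + dCe; Cm <- Cm + dCm
  }

  # 2) convection of C_i
  bnd_out <- 0; comp_gain <- 0
  if (op$config$conservative) {
    fa <- flux_advect(Ci, op)
    Ci <- Ci + dt * fa$rate
    bnd_out <- dt * fa$boundary_outflux
  } else {
    # advective (non-conservative) form: the compressibility term
    # C div(v) = C (phi_b - phi_L) is deliberately absent from the PDE;
    # record it so the mass budget closes
    if (track) comp_gain <- dt * sum(Ci * op$phi_net) * op$area
    Ci <- Ci + dt * upwind_advect(Ci, op)
  }

  # 3) implicit diffusion of C_i
  Ci <- matrix(as.numeric(Matrix::solve(op$factor,
                                        as.vector(Ci) * op$area / dt)),
               grid$nx, grid$ny)

  floor_tol <- -1e-9 * max(max(Ci), max(Ce), max(Cm), 1e-300)
  if (min(Ci) < floor_tol * 1e3)
    stop_solver("advance: negative concentration beyond tolerance; dt too large")
  Ci[Ci < 0] <- 0; Ce[Ce < 0] <- 0; Cm[Cm < 0] <- 0

  out <- conc_state(t0 + dt, Ci, Ce, Cm)
  if (track) {
    mass1 <- sum(Ci + Ce + Cm) * op$area
    attr(out, "budget") <- data.frame(
      t = t0 + dt, mass = mass1, d_mass = mass1 - mass0,
      exchange_gain = gain, boundary_adv_out = bnd_out,
      compressibility_gain = comp_gain)
  }
  out
}

#' Run the transient tracer simulation
#'
#' Starts from `C_i = C_e = C_m = 0`, marches with [advance], and emits the
#' state at each requested output time (snapped to the nearest step).
#'
#' @param flow a `flow_field`.
#' @param aif an `aif`.
#' @param params parameter list (default: the flow field's).
#' @param config a [sim_config].
#' @return object of class `trajectory`: `times`, `states` (list of
#'   [conc_state]), `flow`, `config`, and (if tracked) `budget`.
#' @export
run_simulation <- function(flow, aif, params = flow$params,
                           config = sim_config()) {
  op <- transport_operator(flow, params, config)
  grid <- flow$grid
  z <- matrix(0, grid$nx, grid$ny)
  state <- conc_state(0, z, z, z)
  n_steps <- ceiling(config$t_end / config$dt - 1e-9)
  out_steps <- unique(pmin(pmax(round(config$output_times / config$dt), 0L),
                           n_steps))
  states <- list(); times <- numeric(0)
  budget <- if (config$track_balance) vector("list", n_steps) else NULL
  if (0L %in% out_steps) {
    states[[length(states) + 1L]] <- state; times <- c(times, 0)
  }
  for (k in seq_len(n_steps)) {
    state <- advance(state, op, aif)
    if (config$track_balance) budget[[k]] <- attr(state, "budget")
    if (k %in% out_steps) {
      states[[length(states) + 1L]] <- state
      times <- c(times, state$t)
    }
  }
  structure(list(times = times, states = states, flow = flow,
                 params = params, config = config,
                 budget = if (config$track_balance)
                   do.call(rbind, budget) else NULL),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d states at t = %s s (%d x %d grid)\n",
              length(x$states), paste(signif(x$times, 4), collapse = ", "),
              x$flow$grid$nx, x$flow$grid$ny))
  invisible(x)
}
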