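# Closed-form reference solutions used as independent test oracles for the
# flow and transport solvers. Deliberately built on different machinery than
# the production code paths (matrix exponential / Bessel functions vs sparse
# FV solves and RK4 splitting).

#' Well-mixed (zero-dimensional) kinetic parameters
#'
#' The scalar parameter subset describing one homogeneous tissue point:
#' exchange with plasma, lymphatic loss, and the cellular kinetic cascade.
#'
#' @param L3,L4 cell uptake / release rates (1/s).
#' @param L5 phosphorylation rate (1/s).
#' @param sigma_f filtration reflection coefficient.
#' @param PSV permeability-surface product `P S/V` (1/s).
#' @param phi_b filtration rate (1/s).
#' @param phi_L lymphatic drainage rate (1/s).
#' @return object of class `wellmixed_params`.
#' @export
wellmixed_params <- function(L3, L4, L5, sigma_f = 0.9, PSV, phi_b = 0,
                             phi_L = 0) {
  for (v in c(L3, L4, L5, PSV, phi_L))
    if (v < 0) stop_validation("wellmixed_params: rates must be >= 0")
  structure(list(L3 = L3, L4 = L4, L5 = L5, sigma_f = sigma_f, PSV = PSV,
                 phi_b = phi_b, phi_L = phi_L),
            class = "wellmixed_params")
}

wm_coeffs <- function(p) {
  conv <- p$phi_b * (1 - p$sigma_f)
  k_ex <- if (p$PSV > 0) p$PSV * pe_factor(conv / p$PSV) else 0
  list(a1 = conv + k_ex, a2 = p$L3 + k_ex + p$phi_L)
}

#' Well-mixed compartmental solution (matrix-exponential oracle)
#'
#' Solves the spatially uniform limit of the tracer system,
#' `dx/dt = A x + b(t)` with
#' `x = (C_i, C_e, C_m)`, exactly: the AIF forcing is absorbed into an
#' augmented constant-coefficient system (exponential terms for the
#' parametric AIF; a linear-in-time augmentation per segment for tabulated
#' AIFs), which is then propagated by `Matrix::expm`. Accuracy is limited
#' only by the matrix exponential itself (~1e-13 relative).
#'
#' @param params a [wellmixed_params].
#' @param aif an `aif`.
#' @param times output times (s), non-negative.
#' @return data.frame with columns `t`, `C_i`, `C_e`, `C_m`.
#' @export
wellmixed_solution <- function(params, aif, times) {
  stopifnot(inherits(params, "wellmixed_params"), inherits(aif, "aif"))
  times <- sort(unique(as.numeric(times)))
  if (any(times < 0)) stop_validation("wellmixed_solution: times must be >= 0")
  co <- wm_coeffs(params)
  A <- matrix(c(-co$a2, params$L3, 0,
                params$L4, -(params$L4 + params$L5), params$L5,
                0, 0, 0), 3, 3)
  out <- matrix(0, length(times), 3)

  if (aif$kind == "biexp") {
    # augment with u1 = exp(-k1 t), u2 = exp(-k2 t); b(t) = a1 A_amp (u2 - u1)
    M <- matrix(0, 5, 5)
    M[1:3, 1:3] <- A
    M[1, 4] <- -co$a1 * aif$A
    M[1, 5] <- +co$a1 * aif$A
    M[4, 4] <- -aif$k1
    M[5, 5] <- -aif$k2
    z <- c(0, 0, 0, 1, 1)
    t_prev <- 0
    for (k in seq_along(times)) {
      h <- times[k] - t_prev
      if (h > 0) z <- as.numeric(Matrix::expm(Matrix::Matrix(M * h)) %*% z)
      out[k, ] <- z[1:3]
      t_prev <- times[k]
    }
  } else {
    # piecewise-linear forcing: per segment b(t0 + s) = c0 + c1 s, exact via
    # z = (x, s, 1) augmentation
    brk <- sort(unique(c(0, aif$t, times)))
    brk <- brk[brk >= 0 & brk <= max(times)]
    x <- c(0, 0, 0)
    t_prev <- 0
    res <- list(`0` = x)
    for (tb in brk[brk > 0]) {
      h <- tb - t_prev
      cp0 <- aif_eval(aif, t_prev); cp1 <- aif_eval(aif, tb)
      c0 <- c(co$a1 * cp0, 0, 0)
      c1 <- c(co$a1 * (cp1 - cp0) / h, 0, 0)
      M <- matrix(0, 5, 5)
      M[1:3, 1:3] <- A
      M[1:3, 4] <- c1
      M[1:3, 5] <- c0
      M[4, 5] <- 1
      z <- c(x, 0, 1)
      z <- as.numeric(Matrix::expm(Matrix::Matrix(M * h)) %*% z)
      x <- z[1:3]
      res[[as.character(tb)]] <- x
      t_prev <- tb
    }
    for (k in seq_along(times))
      out[k, ] <- res[[as.character(times[k])]]
  }
  data.frame(t = times, C_i = out[, 1], C_e = out[, 2], C_m = out[, 3])
}

#' Radial interstitial pressure profile (modified-Bessel oracle)
#'
#' Axisymmetric solution of the uniform-coefficient pressure equation
#' `-kappa Lap(P) + L_p (S/V) (P - P_e) = 0` on a disc of radius `R` with
#' `P(R) = 0`:
#' `P(r) = P_e (1 - I0(alpha r / R) / I0(alpha))`,
#' `alpha = R sqrt(L_p (S/V) / kappa)`. Evaluated with exponentially scaled
#' Bessel functions so large `alpha` does not overflow.
#'
#' @param R disc radius (m).
#' @param P_e effective filtration pressure (Pa),
#'   `P_b - sigma_s (pi_b - pi_i)`.
#' @param alpha dimensionless leakiness `R sqrt(L_p (S/V) / kappa)`.
#' @param r radii at which to evaluate, `0 <= r <= R`.
#' @return pressure values (Pa), monotone decreasing in `r`.
#' @export
radial_ifp_analytic <- function(R, P_e, alpha, r) {
  if (alpha < 0) stop_validation("radial_ifp_analytic: alpha must be >= 0")
  if (any(r < 0 | r > R + 1e-12))
    stop_validation("radial_ifp_analytic: r must lie in [0, R]")
  if (alpha == 0) return(rep(0, length(r)))
  x <- alpha * r / R
  ratio <- besselI(x, 0, expon.scaled = TRUE) /
    besselI(alpha, 0, expon.scaled = TRUE) * exp(x - alpha)
  P_e * (1 - ratio)
}
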