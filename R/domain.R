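# Computational domain (rectangle + centred tumor disc), structured grid, and
# per-region physical parameters. All quantities SI: Pa, m, s, mol/m^3.

#' Domain geometry: rectangular tissue with a circular tumor
#'
#' Defaults reproduce the reference geometry: a 6.72 cm x 6.09 cm tissue
#' rectangle with a 2.3 cm diameter tumor disc at its centre.
#'
#' @param width,height rectangle extent (m).
#' @param tumor_center `(x, y)` of the tumor centre (m); default domain centre.
#' @param tumor_diameter tumor disc diameter (m).
#' @param grid_spacing target cell size (m) for the structured grid.
#' @return object of class `domain_spec`.
#' @export
domain_spec <- function(width = 0.0672, height = 0.0609,
                        tumor_center = NULL, tumor_diameter = 0.023,
                        grid_spacing = 2e-4) {
  if (is.null(tumor_center)) tumor_center <- c(width / 2, height / 2)
  if (grid_spacing <= 0) stop_validation("domain_spec: grid_spacing must be > 0")
  r <- tumor_diameter / 2
  if (tumor_center[1] - r <= 0 || tumor_center[1] + r >= width ||
      tumor_center[2] - r <= 0 || tumor_center[2] + r >= height)
    stop_validation("domain_spec: tumor disc must lie strictly inside the rectangle")
  structure(list(width = width, height = height,
                 tumor_center = as.numeric(tumor_center),
                 tumor_diameter = tumor_diameter,
                 grid_spacing = grid_spacing),
            class = "domain_spec")
}

#' @export
print.domain_spec <- function(x, ...) {
  cat(sprintf(
    "<domain_spec> %.3g x %.3g cm, tumor d = %.3g cm at (%.3g, %.3g) cm, h = %.3g mm\n",
    x$width * 100, x$height * 100, x$tumor_diameter * 100,
    x$tumor_center[1] * 100, x$tumor_center[2] * 100, x$grid_spacing * 1e3))
  invisible(x)
}

#' Build the structured grid for a domain
#'
#' Cell-centred grid with `nx x ny` cells; fields are stored as `nx x ny`
#' matrices with `[i, j]` at `x = (i - 0.5) hx`, `y = (j - 0.5) hy` (y up).
#' `region` is 1 in normal tissue and 2 inside the tumor disc.
#'
#' @param domain a [domain_spec].
#' @return object of class `domain_grid` with elements `nx`, `ny`, `hx`, `hy`,
#'   `xc`, `yc`, `region`, `tumor` (logical matrix), and the originating
#'   `domain`.
#' @export
domain_grid <- function(domain) {
  stopifnot(inherits(domain, "domain_spec"))
  nx <- max(4L, round(domain$width / domain$grid_spacing))
  ny <- max(4L, round(domain$height / domain$grid_spacing))
  hx <- domain$width / nx
  hy <- domain$height / ny
  xc <- (seq_len(nx) - 0.5) * hx
  yc <- (seq_len(ny) - 0.5) * hy
  dx <- outer(xc - domain$tumor_center[1], rep(1, ny))
  dy <- outer(rep(1, nx), yc - domain$tumor_center[2])
  R2 <- (domain$tumor_diameter / 2)^2
  tumor <- (dx^2 + dy^2) <= R2
  # subcell tumor coverage (4x4 supersampling): used to antialias material
  # coefficients at the circular interface, the structured-grid analogue of
  # a body-fitted mesh (a hard staircase has corner singularities that keep
  # pointwise velocity maxima from converging under refinement)
  frac <- matrix(0, nx, ny)
  off <- ((1:4) - 0.5) / 4 - 0.5
  for (ox in off) for (oy in off) {
    frac <- frac + (((dx + ox * hx)^2 + (dy + oy * hy)^2) <= R2)
  }
  frac <- frac / 16
  structure(list(nx = nx, ny = ny, hx = hx, hy = hy, xc = xc, yc = yc,
                 region = ifelse(tumor, 2L, 1L), tumor = tumor,
                 tumor_frac = frac, domain = domain),
            class = "domain_grid")
}

# harmonic blend of a per-region coefficient by subcell tumor coverage;
# appropriate for flux-carrying coefficients (kappa, D_eff). A zero
# coefficient on a side with nonzero coverage blocks the cell (blend 0).
blend_field <- function(grid, params, name) {
  vn <- params$normal[[name]]; vt <- params$tumor[[name]]
  f <- grid$tumor_frac
  tn <- ifelse(f < 1, (1 - f) / vn, 0)   # Inf where vn = 0 and weight > 0
  tt <- ifelse(f > 0, f / vt, 0)
  out <- 1 / (tn + tt)
  out[!is.finite(out)] <- 0
  out
}

#' Physical parameters for one tissue region
#'
#' All values SI. See [default_params] for the literature defaults.
#'
#' @param L_p vascular hydraulic conductivity, m/(Pa s).
#' @param S_over_V vessel surface area per tissue volume, 1/m.
#' @param sigma_s osmotic (Staverman) reflection coefficient, in `[0, 1]`.
#' @param pi_b,pi_i blood / interstitial osmotic pressure, Pa.
#' @param kappa interstitial hydraulic conductivity, m^2/(Pa s).
#' @param L_pL_SV lymphatic filtration coefficient, 1/(Pa s).
#' @param P_L lymphatic hydrostatic pressure, Pa.
#' @param D_eff tracer effective diffusivity, m^2/s.
#' @param P_perm vascular solute permeability, m/s.
#' @param sigma_f filtration (solvent-drag) reflection coefficient, `[0, 1]`.
#' @param L3,L4 cell membrane transport rates (in / out), 1/s.
#' @param L5 phosphorylation (trapping) rate, 1/s.
#' @return a `region_params` list.
#' @export
region_params <- function(L_p, S_over_V, sigma_s, pi_b, pi_i, kappa,
                          L_pL_SV, P_L, D_eff, P_perm, sigma_f, L3, L4, L5) {
  p <- list(L_p = L_p, S_over_V = S_over_V, sigma_s = sigma_s, pi_b = pi_b,
            pi_i = pi_i, kappa = kappa, L_pL_SV = L_pL_SV, P_L = P_L,
            D_eff = D_eff, P_perm = P_perm, sigma_f = sigma_f,
            L3 = L3, L4 = L4, L5 = L5)
  nonneg <- c("L_p", "S_over_V", "kappa", "L_pL_SV", "D_eff", "P_perm",
              "L3", "L4", "L5")
  for (f in nonneg)
    if (p[[f]] < 0) stop_validation("region_params: ", f, " must be >= 0")
  for (f in c("sigma_s", "sigma_f"))
    if (p[[f]] < 0 || p[[f]] > 1)
      stop_validation("region_params: ", f, " must be in [0, 1]")
  structure(p, class = "region_params")
}

#' Default tissue parameters (normal and tumor)
#'
#' Literature values for interstitial flow and FDG transport. Quantities the
#' source tables leave out (S/V, tumor cell-uptake rates) follow stated
#' package conventions: S/V = 2.0e4 1/m in both regions; tumor L3/L4 are 10x
#' the normal-tissue values. Tumor lymphatics are absent (L_pL_SV = 0).
#'
#' @param tumor_kinetics_factor multiplier applied to normal L3/L4 for the
#'   tumor region (default 10; convention, not a measured value).
#' @return list with elements `normal` and `tumor`, each a [region_params].
#' @export
default_params <- function(tumor_kinetics_factor = 10) {
  L3n <- per_min_to_per_s(8.2e-4)
  L4n <- per_min_to_per_s(6.7e-4)
  L5 <- per_min_to_per_s(5.3e-4)
  normal <- region_params(
    L_p = cm_per_mmHg_s_to_SI(0.36e-7),
    S_over_V = 2.0e4,
    sigma_s = 0.91,
    pi_b = mmHg_to_Pa(20), pi_i = mmHg_to_Pa(10),
    kappa = 6.41e-15,
    L_pL_SV = 1.33e-5 / 133.322, P_L = 0,
    D_eff = 3.7e-10,
    P_perm = 3.75e-7, sigma_f = 0.9,
    L3 = L3n, L4 = L4n, L5 = L5)
  tumor <- region_params(
    L_p = cm_per_mmHg_s_to_SI(2.8e-7),
    S_over_V = 2.0e4,
    sigma_s = 0.82,
    pi_b = mmHg_to_Pa(20), pi_i = mmHg_to_Pa(15),
    kappa = 30.0e-15,
    L_pL_SV = 0, P_L = 0,
    D_eff = 2.5e-9,
    P_perm = 3.0e-6, sigma_f = 0.9,
    L3 = L3n * tumor_kinetics_factor, L4 = L4n * tumor_kinetics_factor,
    L5 = L5)
  list(normal = normal, tumor = tumor)
}

# nx x ny matrix of a parameter, picked per region (1 = normal, 2 = tumor)
param_field <- function(grid, params, name) {
  vals <- c(params$normal[[name]], params$tumor[[name]])
  matrix(vals[grid$region], grid$nx, grid$ny)
}

#' Effective filtration pressure per region
#'
#' `P_e = P_b - sigma_s (pi_b - pi_i)`: the vascular pressure corrected for
#' the reflected osmotic gradient. It is the plateau interstitial pressure in
#' leaky, lymph-free tissue and an upper bound on the interstitial pressure
#' field (maximum principle).
#'
#' @param P_b blood pressure, Pa (scalar or grid).
#' @param params a [region_params].
#' @return same shape as `P_b`, Pa.
#' @export
effective_filtration_pressure <- function(P_b, params) {
  P_b - params$sigma_s * (params$pi_b - params$pi_i)
}
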