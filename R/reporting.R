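# Reporting surfaces: region statistics, probe time-activity curves, cutline
# profiles, normalized maps, and the grid-independence study.

#' Probe specification: labelled points and cutlines
#'
#' @param points data.frame with columns `label`, `x`, `y` (m).
#' @param cutlines list of cutlines, each `list(start = c(x, y),
#'   end = c(x, y), n = samples)`.
#' @return object of class `probe_spec`.
#' @export
probe_spec <- function(points = data.frame(label = character(),
                                           x = numeric(), y = numeric()),
                       cutlines = list()) {
  stopifnot(all(c("label", "x", "y") %in% names(points)))
  structure(list(points = points, cutlines = cutlines), class = "probe_spec")
}

# bilinear interpolation of a cell-centred field at physical (x, y)
interp_field <- function(field, grid, x, y) {
  fx <- x / grid$hx + 0.5; fy <- y / grid$hy + 0.5
  i0 <- pmin(pmax(floor(fx), 1L), grid$nx - 1L)
  j0 <- pmin(pmax(floor(fy), 1L), grid$ny - 1L)
  wx <- pmin(pmax(fx - i0, 0), 1); wy <- pmin(pmax(fy - j0, 0), 1)
  f00 <- field[cbind(i0, j0)]; f10 <- field[cbind(i0 + 1L, j0)]
  f01 <- field[cbind(i0, j0 + 1L)]; f11 <- field[cbind(i0 + 1L, j0 + 1L)]
  (1 - wx) * (1 - wy) * f00 + wx * (1 - wy) * f10 +
    (1 - wx) * wy * f01 + wx * wy * f11
}

#' Region summary statistics of a trajectory
#'
#' Median and mean of each compartment (and of the total) over the grid
#' cells of each region, at the requested output times. `C_total` is always
#' computed as the sum of the three compartments, so the table satisfies the
#' row identity `C_total = C_i + C_e + C_m` for the means (medians of sums
#' are reported from the summed field, not the sum of medians).
#'
#' @param trajectory a `trajectory` from [run_simulation].
#' @param regions character subset of `c("normal", "tumor")`.
#' @param times times to report (default: all trajectory output times).
#' @return data.frame, one row per (time, region).
#' @export
region_stats <- function(trajectory, regions = c("tumor", "normal"),
                         times = trajectory$times) {
  if (!all(regions %in% c("tumor", "normal")))
    stop_validation("region_stats: unknown region label")
  if (!all(times %in% trajectory$times))
    stop_validation("region_stats: times must be trajectory output times")
  grid <- trajectory$flow$grid
  rows <- list()
  for (t in times) {
    st <- trajectory$states[[match(t, trajectory$times)]]
    tot <- total_concentration(st)
    for (reg in regions) {
      sel <- grid$region == (if (reg == "tumor") 2L else 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        time_s = t, region = reg,
        median_Ci = median(st$C_i[sel]), median_Ce = median(st$C_e[sel]),
        median_Cm = median(st$C_m[sel]), median_Ctotal = median(tot[sel]),
        mean_Ci = mean(st$C_i[sel]), mean_Ce = mean(st$C_e[sel]),
        mean_Cm = mean(st$C_m[sel]), mean_Ctotal = mean(tot[sel]))
    }
  }
  do.call(rbind, rows)
}

#' Probe time-activity curves
#'
#' Bilinear interpolation of every compartment at each labelled point, and
#' the arithmetic mean along each cutline's samples, for every output time.
#'
#' @param trajectory a `trajectory`.
#' @param probes a [probe_spec]; all probes must lie inside the domain.
#' @return data.frame with columns `probe`, `kind`, `time_s`, `C_i`, `C_e`,
#'   `C_m`, `C_total`.
#' @export
probe_tac <- function(trajectory, probes) {
  stopifnot(inherits(probes, "probe_spec"))
  grid <- trajectory$flow$grid
  W <- grid$nx * grid$hx; H <- grid$ny * grid$hy
  chk <- function(x, y) {
    if (any(x < 0 | x > W | y < 0 | y > H))
      stop_validation("probe_tac: probe outside domain")
  }
  rows <- list()
  sample_at <- function(st, x, y) {
    c(C_i = mean(interp_field(st$C_i, grid, x, y)),
      C_e = mean(interp_field(st$C_e, grid, x, y)),
      C_m = mean(interp_field(st$C_m, grid, x, y)))
  }
  for (k in seq_along(trajectory$times)) {
    st <- trajectory$states[[k]]
    if (nrow(probes$points)) {
      chk(probes$points$x, probes$points$y)
      for (p in seq_len(nrow(probes$points))) {
        v <- sample_at(st, probes$points$x[p], probes$points$y[p])
        rows[[length(rows) + 1L]] <- data.frame(
          probe = probes$points$label[p], kind = "point",
          time_s = trajectory$times[k], C_i = v[1], C_e = v[2], C_m = v[3],
          C_total = sum(v))
      }
    }
    for (ci in seq_along(probes$cutlines)) {
      cl <- probes$cutlines[[ci]]
      tt <- seq(0, 1, length.out = cl$n)
      xs <- cl$start[1] + tt * (cl$end[1] - cl$start[1])
      ys <- cl$start[2] + tt * (cl$end[2] - cl$start[2])
      chk(xs, ys)
      v <- sample_at(st, xs, ys)
      rows[[length(rows) + 1L]] <- data.frame(
        probe = if (!is.null(cl$label)) cl$label else paste0("cutline_", ci),
        kind = "cutline", time_s = trajectory$times[k],
        C_i = v[1], C_e = v[2], C_m = v[3], C_total = sum(v))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Concentration maps normalized by the global maximum total concentration
#'
#' All compartments at all output times are divided by the single global
#' maximum of `C_total` over the trajectory, so maps are mutually comparable
#' and lie in `[0, 1]` with the maximizing cell at exactly 1.
#'
#' @param trajectory a `trajectory`.
#' @return list (per output time) of lists of matrices `C_i`, `C_e`, `C_m`,
#'   `C_total`; attribute `scale` is the normalizing maximum.
#' @export
normalized_maps <- function(trajectory) {
  if (!length(trajectory$states))
    stop_validation("normalized_maps: empty trajectory")
  gmax <- max(vapply(trajectory$states,
                     function(s) max(total_concentration(s)), numeric(1)))
  if (gmax <= 0)
    stop_validation("normalized_maps: all concentrations are zero")
  out <- lapply(trajectory$states, function(s)
    list(C_i = s$C_i / gmax, C_e = s$C_e / gmax, C_m = s$C_m / gmax,
         C_total = total_concentration(s) / gmax))
  names(out) <- paste0("t", trajectory$times)
  attr(out, "scale") <- gmax
  out
}

# k x k box blur (moving average) via cumulative sums; used for local MVD
box_blur <- function(m, k) {
  if (k <= 1L) return(m)
  nx <- nrow(m); ny <- ncol(m)
  pad <- function(v, n) pmin(pmax(v, 1L), n)
  cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed double cumsum
  cs <- t(cs)
  S <- matrix(0, nx + 1L, ny + 1L)
  S[2:(nx + 1), 2:(ny + 1)] <- cs
  h <- k %/% 2L
  i0 <- pad(seq_len(nx) - h, nx + 1L) ; i1 <- pad(seq_len(nx) + h + 1L, nx + 1L)
  j0 <- pad(seq_len(ny) - h, ny + 1L) ; j1 <- pad(seq_len(ny) + h + 1L, ny + 1L)
  i0 <- pmax(i0, 1L); j0 <- pmax(j0, 1L)
  A <- S[i1, j1] - S[i0, j1] - S[i1, j0] + S[i0, j0]
  cnt <- outer(i1 - i0, j1 - j0)
  A / cnt
}

#' Automatic probe layout by local microvascular density
#'
#' Mirrors the reference layout qualitatively: two tumor points (highest and
#' lowest local vessel density), two peritumoral points just outside the
#' tumor rim, and two distant normal-tissue points, each pair split by local
#' MVD ranking. Local MVD is the box-blurred vessel indicator.
#'
#' @param flow a `flow_field`.
#' @param blur_mm blur window (mm) defining "local" density (default 2).
#' @return a [probe_spec] with points `tumor_high_mvd`, `tumor_low_mvd`,
#'   `peritumoral_high_mvd`, `peritumoral_low_mvd`, `distant_high_mvd`,
#'   `distant_low_mvd`.
#' @export
default_probes <- function(flow, blur_mm = 2) {
  grid <- flow$grid
  k <- max(3L, round(blur_mm * 1e-3 / grid$hx))
  mvd <- box_blur(flow$vessel_mask * 1, k)
  dom <- grid$domain
  dx <- outer(grid$xc - dom$tumor_center[1], rep(1, grid$ny))
  dy <- outer(rep(1, grid$nx), grid$yc - dom$tumor_center[2])
  rr <- sqrt(dx^2 + dy^2)
  R <- dom$tumor_diameter / 2
  zone <- list(
    tumor = rr < 0.8 * R,
    peritumoral = rr > 1.1 * R & rr < 1.6 * R,
    distant = rr > 2.2 * R)
  pts <- list()
  for (z in names(zone)) {
    sel <- which(zone[[z]])
    hi <- sel[which.max(mvd[sel])]
    lo <- sel[which.min(mvd[sel])]
    for (p in list(c("high", hi), c("low", lo))) {
      idx <- as.integer(p[2])
      i <- (idx - 1L) %% grid$nx + 1L
      j <- (idx - 1L) %/% grid$nx + 1L
      pts[[length(pts) + 1L]] <- data.frame(
        label = paste0(z, "_", p[1], "_mvd"),
        x = grid$xc[i], y = grid$yc[j])
    }
  }
  probe_spec(points = do.call(rbind, pts))
}

#' Grid-independence (mesh convergence) study
#'
#' Re-runs the coupled flow + transport pipeline at successively refined
#' grids (the same vessel network throughout) and reports the relative
#' change of max tumor IFP, max |IFV|, and tumor-median total concentration
#' at the final output time between consecutive refinements.
#'
#' @param base_config list with elements `domain` ([domain_spec], whose
#'   `grid_spacing` is the coarsest level), `graph` ([vessel_graph]),
#'   `params`, `aif`, and `sim` ([sim_config]).
#' @param refinement_factors increasing integer factors (default `c(1, 2, 4)`)
#'   applied to the cell count per axis.
#' @param threshold acceptance threshold on the relative change between the
#'   two finest levels (default 0.025).
#' @return object of class `mesh_convergence`: `metrics` (one row per
#'   level), `changes` (one row per consecutive pair), and `converged`
#'   (logical: all finest-pair changes below `threshold`).
#' @export
mesh_convergence <- function(base_config, refinement_factors = c(1, 2, 4),
                             threshold = 0.025) {
  if (is.unsorted(refinement_factors, strictly = TRUE))
    stop_validation("mesh_convergence: factors must be increasing")
  cfg <- base_config
  metrics <- list()
  for (f in refinement_factors) {
    dom <- cfg$domain
    dom$grid_spacing <- cfg$domain$grid_spacing / f
    flow <- couple_flow(cfg$graph, dom, cfg$params)
    traj <- run_simulation(flow, cfg$aif, cfg$params, cfg$sim)
    t_last <- max(traj$times)
    st <- traj$states[[match(t_last, traj$times)]]
    sel <- flow$grid$tumor
    metrics[[length(metrics) + 1L]] <- data.frame(
      factor = f, nx = flow$grid$nx, ny = flow$grid$ny,
      max_tumor_IFP_Pa = max(flow$P_i[sel]),
      max_IFV_m_s = max(flow$speed),
      tumor_median_Ctotal = median(total_concentration(st)[sel]))
  }
  metrics <- do.call(rbind, metrics)
  rel <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), 1e-300)
  changes <- data.frame(
    from = head(metrics$factor, -1), to = tail(metrics$factor, -1),
    d_max_tumor_IFP = rel(head(metrics$max_tumor_IFP_Pa, -1),
                          tail(metrics$max_tumor_IFP_Pa, -1)),
    d_max_IFV = rel(head(metrics$max_IFV_m_s, -1),
                    tail(metrics$max_IFV_m_s, -1)),
    d_tumor_median_Ctotal = rel(head(metrics$tumor_median_Ctotal, -1),
                                tail(metrics$tumor_median_Ctotal, -1)))
  last <- nrow(changes)
  converged <- all(unlist(changes[last, c("d_max_tumor_IFP", "d_max_IFV",
                                          "d_tumor_median_Ctotal")]) <
                     threshold)
  structure(list(metrics = metrics, changes = changes,
                 converged = converged, threshold = threshold),
            class = "mesh_convergence")
}

#' @export
print.mesh_convergence <- function(x, ...) {
  cat("<mesh_convergence>\n")
  print(x$metrics, row.names = FALSE)
  print(x$changes, row.names = FALSE)
  cat(sprintf("finest-pair changes %s %.2g%% threshold\n",
              if (x$converged) "below" else "ABOVE", 100 * x$threshold))
  invisible(x)
}

# --- field output ----------------------------------------------------------

#' Write grid fields as a legacy ASCII VTK structured-points file
#' @param path output `.vtk` path.
#' @param grid a [domain_grid].
#' @param fields named list of `nx x ny` matrices.
#' @return `path`, invisibly.
#' @export
write_vtk_grid <- function(path, grid, fields) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "petflow fields", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", grid$nx, grid$ny),
               sprintf("ORIGIN %g %g 0", grid$hx / 2, grid$hy / 2),
               sprintf("SPACING %g %g 1", grid$hx, grid$hy),
               sprintf("POINT_DATA %d", grid$nx * grid$ny)), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(paste(format(as.vector(fields[[nm]]), digits = 9)), con)
  }
  invisible(path)
}

#' Write a grid field as CSV (x_m, y_m, value)
#' @param path output path.
#' @param grid a [domain_grid].
#' @param field `nx x ny` matrix.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(path, grid, field) {
  d <- data.frame(x_m = rep(grid$xc, grid$ny),
                  y_m = rep(grid$yc, each = grid$nx),
                  value = as.vector(field))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
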