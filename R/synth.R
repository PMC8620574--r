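# Seeded synthetic capillary networks: four parent vessels spanning the
# domain (top and bottom sides plus two mid-height vessels crossing the
# tumor) feed a stochastic branching capillary bed whose centreline length
# density is controlled per region (tumor disc vs surrounding tissue).

#' Synthetic network specification
#'
#' @param mvd_tumor,mvd_normal target capillary centreline length density
#'   (m per m^2 of tissue) inside / outside the tumor disc.
#' @param n_parent_vessels number of parent vessels (default 4: top, bottom
#'   and two mid-height).
#' @param parent_radius,capillary_radius lumen radii (m). Defaults 40 um and
#'   5 um (typical microvascular calibre; not taken from any table).
#' @param inlet_pressure,outlet_pressure blood pressure prescribed at the
#'   left / right ends of each parent vessel (Pa). Defaults 25 / 10 mmHg.
#' @param branch_step characteristic capillary segment length (m).
#' @param seed integer RNG seed; generation is a pure function of
#'   `(domain, spec)`.
#' @return object of class `network_spec`.
#' @export
network_spec <- function(mvd_tumor = 8000, mvd_normal = 3000,
                         n_parent_vessels = 4L,
                         parent_radius = 40e-6, capillary_radius = 5e-6,
                         inlet_pressure = mmHg_to_Pa(25),
                         outlet_pressure = mmHg_to_Pa(10),
                         branch_step = 1.2e-3, seed = 1L) {
  if (mvd_tumor < 0 || mvd_normal < 0)
    stop_validation("network_spec: densities must be >= 0")
  if (parent_radius <= 0 || capillary_radius <= 0)
    stop_validation("network_spec: radii must be > 0")
  structure(list(mvd_tumor = mvd_tumor, mvd_normal = mvd_normal,
                 n_parent_vessels = as.integer(n_parent_vessels),
                 parent_radius = parent_radius,
                 capillary_radius = capillary_radius,
                 inlet_pressure = inlet_pressure,
                 outlet_pressure = outlet_pressure,
                 branch_step = branch_step, seed = as.integer(seed)),
            class = "network_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

in_tumor <- function(domain, x, y) {
  (x - domain$tumor_center[1])^2 + (y - domain$tumor_center[2])^2 <=
    (domain$tumor_diameter / 2)^2
}

#' Generate a seeded synthetic capillary network
#'
#' Parent vessels span the full domain width at the bottom, top, and two
#' mid-height positions (crossing the tumor disc); their end nodes lie on the
#' left/right domain boundary and carry the prescribed inlet/outlet
#' pressures. Capillary branches then grow as seeded random polylines rooted
#' on the existing network (so every capillary is connected to a parent),
#' steered toward whichever region still lacks centreline length, until the
#' realized density per region is within 10% of target (book-kept exactly;
#' the final segment is trimmed to land on target).
#'
#' @param domain a [domain_spec].
#' @param spec a [network_spec].
#' @return a [vessel_graph].
#' @export
generate_network <- function(domain, spec) {
  stopifnot(inherits(domain, "domain_spec"), inherits(spec, "network_spec"))
  W <- domain$width; H <- domain$height
  A_tum <- pi * (domain$tumor_diameter / 2)^2
  A_nor <- W * H - A_tum
  target <- c(normal = spec$mvd_normal * A_nor, tumor = spec$mvd_tumor * A_tum)
  # feasibility: refuse length targets that would exceed a packed capillary bed
  max_density <- 1 / (4 * spec$capillary_radius)  # ~ touching capillaries
  if (spec$mvd_tumor > max_density || spec$mvd_normal > max_density)
    stop_solver("generate_network: requested density infeasible for capillary radius")

  # growable storage (capacity doubling; appended tens of thousands of times)
  cap_n <- 1024L; n_nodes <- 0L
  nx_ <- numeric(cap_n); ny_ <- numeric(cap_n); n_tum <- logical(cap_n)
  cap_e <- 1024L; n_edges <- 0L
  e_from <- integer(cap_e); e_to <- integer(cap_e); e_rad <- numeric(cap_e)
  new_node <- function(x, y) {
    if (n_nodes == cap_n) {
      cap_n <<- cap_n * 2L
      nx_ <<- c(nx_, numeric(n_nodes)); ny_ <<- c(ny_, numeric(n_nodes))
      n_tum <<- c(n_tum, logical(n_nodes))
    }
    n_nodes <<- n_nodes + 1L
    nx_[n_nodes] <<- x; ny_[n_nodes] <<- y
    n_tum[n_nodes] <<- in_tumor(domain, x, y)
    n_nodes
  }
  add_edge <- function(a, b, r) {
    if (n_edges == cap_e) {
      cap_e <<- cap_e * 2L
      e_from <<- c(e_from, integer(n_edges)); e_to <<- c(e_to, integer(n_edges))
      e_rad <<- c(e_rad, numeric(n_edges))
    }
    n_edges <<- n_edges + 1L
    e_from[n_edges] <<- a; e_to[n_edges] <<- b; e_rad[n_edges] <<- r
  }

  # --- parent vessels -------------------------------------------------------
  np <- spec$n_parent_vessels
  m <- spec$parent_radius
  fr <- if (np == 4L) c(0, 0.42, 0.58, 1) else seq(0, 1, length.out = np)
  ys <- m + fr * (H - 2 * m)
  n_sub <- max(4L, round(W / 1.5e-3))
  xs <- seq(0, W, length.out = n_sub + 1L)
  bnode <- integer(0); bpress <- numeric(0)
  for (y0 in ys) {
    ids <- vapply(xs, function(x) new_node(x, y0), integer(1))
    for (k in seq_len(n_sub)) add_edge(ids[k], ids[k + 1L], spec$parent_radius)
    bnode <- c(bnode, ids[1], ids[n_sub + 1L])
    bpress <- c(bpress, spec$inlet_pressure, spec$outlet_pressure)
  }

  # --- capillary bed --------------------------------------------------------
  got <- c(normal = 0, tumor = 0)
  with_seed(spec$seed, {
    guard <- 0L
    max_branches <- 20000L
    while (any(target - got > 0.01 * pmax(target, 1e-9)) &&
           guard < max_branches) {
      guard <- guard + 1L
      region <- if ((target["tumor"] - got["tumor"]) / max(target["tumor"], 1e-12) >=
                    (target["normal"] - got["normal"]) / max(target["normal"], 1e-12))
        "tumor" else "normal"
      want_tumor <- region == "tumor"
      # anchor: a node already in (or nearest to) the wanted region
      inT <- n_tum[seq_len(n_nodes)]
      cand <- if (want_tumor) which(inT) else which(!inT)
      a <- if (length(cand)) cand[sample.int(length(cand), 1L)] else {
        d2 <- (nx_[seq_len(n_nodes)] - domain$tumor_center[1])^2 +
          (ny_[seq_len(n_nodes)] - domain$tumor_center[2])^2
        if (want_tumor) which.min(d2) else which.max(d2)
      }
      x <- nx_[a]; y <- ny_[a]
      cur <- a
      theta <- runif(1, 0, 2 * pi)
      n_seg <- sample(2:6, 1L)
      for (s in seq_len(n_seg)) {
        deficit <- target[region] - got[region]
        if (deficit <= 0) break
        here_tumor <- in_tumor(domain, x, y)
        if (want_tumor != here_tumor) {
          # steer toward / away from the tumor centre
          ang <- atan2(domain$tumor_center[2] - y, domain$tumor_center[1] - x)
          if (!want_tumor) ang <- ang + pi
          theta <- ang + runif(1, -0.5, 0.5)
        } else {
          theta <- theta + runif(1, -0.7, 0.7)
        }
        len <- runif(1, 0.4, 1) * spec$branch_step
        len <- min(len, max(deficit, 0.05 * spec$branch_step))
        xn <- min(max(x + len * cos(theta), m), W - m)
        yn <- min(max(y + len * sin(theta), m), H - m)
        seg <- sqrt((xn - x)^2 + (yn - y)^2)
        if (seg < 1e-6) break
        b <- new_node(xn, yn)
        add_edge(cur, b, spec$capillary_radius)
        mid_tumor <- in_tumor(domain, (x + xn) / 2, (y + yn) / 2)
        got[if (mid_tumor) "tumor" else "normal"] <-
          got[if (mid_tumor) "tumor" else "normal"] + seg
        cur <- b; x <- xn; y <- yn
      }
    }
    if (any(target - got > 0.1 * pmax(target, 1e-9)))
      stop_solver("generate_network: could not reach target densities")
  })
  nodes <- data.frame(id = seq_len(n_nodes), x = nx_[seq_len(n_nodes)],
                      y = ny_[seq_len(n_nodes)])
  edges <- data.frame(from = e_from[seq_len(n_edges)],
                      to = e_to[seq_len(n_edges)],
                      radius = e_rad[seq_len(n_edges)], length = NA_real_)
  vessel_graph(nodes, edges, data.frame(node = bnode, pressure = bpress))
}

#' Rasterize a vessel graph to a binary mask
#'
#' Each edge is drawn as a capsule (stadium) of its radius around the
#' straight segment between its end nodes; centrelines are always at least
#' one pixel wide.
#'
#' @param graph a [vessel_graph].
#' @param pixel_size metres per pixel.
#' @param width,height raster extent (m); defaults to the graph bounding box
#'   padded by the largest radius.
#' @return a [vessel_mask].
#' @export
rasterize_graph <- function(graph, pixel_size, width = NULL, height = NULL) {
  stopifnot(inherits(graph, "vessel_graph"))
  if (!nrow(graph$edges)) {
    if (is.null(width) || is.null(height))
      stop_validation("rasterize_graph: empty graph needs explicit width/height")
    return(vessel_mask(matrix(FALSE, max(1L, round(height / pixel_size)),
                              max(1L, round(width / pixel_size))), pixel_size))
  }
  r <- rasterize_edge_ids(graph, pixel_size, width, height)
  vessel_mask(r$edge_id > 0L, pixel_size)
}

# internal: rasterize returning per-pixel nearest edge index (0 = background);
# psy defaults to psx, Hpx/Wpx derived from the extent
rasterize_edge_ids <- function(graph, pixel_size, width = NULL, height = NULL,
                               pixel_size_y = pixel_size, quiet = FALSE) {
  stopifnot(inherits(graph, "vessel_graph"))
  if (!nrow(graph$edges)) stop_validation("rasterize: empty graph")
  if (any(graph$edges$radius < pixel_size) && !quiet)
    warning("rasterize: pixel_size exceeds some vessel radii; ",
            "centrelines drawn at 1 px width")
  nd <- graph$nodes; ed <- graph$edges
  i1 <- match(ed$from, nd$id); i2 <- match(ed$to, nd$id)
  if (is.null(width)) width <- max(nd$x) + max(ed$radius)
  if (is.null(height)) height <- max(nd$y) + max(ed$radius)
  Wpx <- max(1L, round(width / pixel_size))
  Hpx <- max(1L, round(height / pixel_size_y))
  seg <- cbind(nd$x[i1], nd$y[i1], nd$x[i2], nd$y[i2], ed$radius)
  out <- .cpp_rasterize_capsules(seg, pixel_size, pixel_size_y, Hpx, Wpx)
  out$pixel_size <- pixel_size
  out
}

#' Render a colour micrograph of a vessel mask
#'
#' Produces the kind of image the segmentation pipeline expects: vessels at
#' full intensity in the green channel over a darker background, with seeded
#' Gaussian sensor noise in all channels, clipped to `[0, 255]`. The red and
#' blue channels carry background texture only.
#'
#' @param mask a [vessel_mask].
#' @param noise_sigma Gaussian noise standard deviation (intensity units).
#' @param background_level background green intensity (default 40).
#' @param seed RNG seed; rendering is deterministic given the seed.
#' @return a [raster_image].
#' @export
render_image <- function(mask, noise_sigma = 0, background_level = 40,
                         seed = 1L) {
  stopifnot(inherits(mask, "vessel_mask"))
  if (noise_sigma < 0) stop_validation("render_image: noise_sigma must be >= 0")
  v <- mask$values
  H <- nrow(v); W <- ncol(v)
  px <- array(0, dim = c(H, W, 3))
  with_seed(seed, {
    g <- ifelse(v, 255, background_level)
    rbg <- matrix(background_level * 0.6, H, W)
    if (noise_sigma > 0) {
      g <- g + rnorm(H * W, sd = noise_sigma)
      px[, , 1] <- rbg + rnorm(H * W, sd = noise_sigma)
      px[, , 3] <- rbg + rnorm(H * W, sd = noise_sigma)
    } else {
      px[, , 1] <- rbg * (background_level > 0)
      px[, , 3] <- rbg * (background_level > 0)
    }
    px[, , 2] <- g
  })
  raster_image(pmin(pmax(px, 0), 255), mask$pixel_size)
}
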