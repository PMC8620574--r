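# Shared fixtures, memoised so expensive solves run once per test session.
# The "small" fixture is the default world scaled down 10x in linear extent
# (same tumor/domain proportions, same physics).

.fx <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fx[[name]])) .fx[[name]] <- force(expr)
  .fx[[name]]
}

small_domain <- function(h = 1e-4) {
  domain_spec(width = 0.00672, height = 0.00609, tumor_diameter = 0.0023,
              grid_spacing = h)
}

small_spec <- function(seed = 7, ...) {
  args <- modifyList(list(mvd_tumor = 8000, mvd_normal = 3000,
                          branch_step = 3e-4, seed = seed), list(...))
  do.call(network_spec, args)
}

small_graph <- function() {
  memo("small_graph", generate_network(small_domain(), small_spec()))
}

small_flow <- function() {
  memo("small_flow", couple_flow(small_graph(), small_domain()))
}

small_trajectory <- function() {
  memo("small_traj", run_simulation(
    small_flow(), aif_biexponential(),
    config = sim_config(dt = 1, t_end = 600,
                        output_times = c(60, 120, 180, 600))))
}

# simple hand-built graphs ---------------------------------------------------

straight_tube <- function(L = 1e-3, r = 1e-5, P_in = 3333, P_out = 0) {
  vessel_graph(
    nodes = data.frame(id = 1:3, x = c(0, L / 2, L), y = 0),
    edges = data.frame(from = c(1, 2), to = c(2, 3), radius = r,
                       length = L / 2),
    boundary = data.frame(node = c(1, 3), pressure = c(P_in, P_out)))
}

# mask of a filled axis-aligned rectangle (r0:r1, c0:c1) in an H x W frame
rect_mask <- function(H, W, r0, r1, c0, c1, ps = 1e-5) {
  v <- matrix(FALSE, H, W)
  v[r0:r1, c0:c1] <- TRUE
  vessel_mask(v, ps)
}

disc_mask <- function(H, W, rad, ps = 1e-5) {
  rr <- outer(seq_len(H) - H / 2, rep(1, W))
  cc <- outer(rep(1, H), seq_len(W) - W / 2)
  vessel_mask(rr^2 + cc^2 <= rad^2, ps)
}
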