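# Reduce a binary vessel mask to a centreline graph: Zhang-Suen thinning,
# branch/end-point detection, path tracing, and radius recovery from the
# Euclidean distance transform.

neighbour_offsets <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                           dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Skeletonize a vessel mask into a centreline graph
#'
#' Thins the mask to a one-pixel skeleton, places graph nodes at skeleton
#' end-points and branch-points (clusters of adjacent branch pixels collapse
#' to one node), and traces the degree-2 chains between them. Edge length is
#' the traced centreline length (pixel steps of 1 or sqrt(2) times
#' `pixel_size`); edge radius is the mean distance-transform value along the
#' chain. Isolated skeleton loops get a single anchor node carrying a
#' self-edge.
#'
#' @param mask a [vessel_mask].
#' @return a [vessel_graph] with physical (metre) coordinates and no boundary
#'   nodes (assign them afterwards, e.g. by [assign_boundary_nodes]).
#' @export
skeletonize_to_graph <- function(mask) {
  stopifnot(inherits(mask, "vessel_mask"))
  ps <- mask$pixel_size
  v <- mask$values
  if (!any(v)) return(vessel_graph())
  H <- nrow(v); W <- ncol(v)
  skel <- .cpp_thin(v)
  if (!any(skel)) return(vessel_graph())  # thinning can erase 1-px blobs
  rad_px <- sqrt(.cpp_edt_sq(v))          # distance to background, px

  deg <- matrix(0L, H, W)
  for (k in seq_len(8)) {
    deg <- deg + shift_mat(skel, neighbour_offsets[k, 1],
                           neighbour_offsets[k, 2])
  }
  is_node_px <- skel & (deg != 2L)
  nodeid <- if (any(is_node_px)) .cpp_label_components(is_node_px, 8L) else
    matrix(0L, H, W)
  n_clusters <- max(nodeid)

  nodes_r <- numeric(0); nodes_c <- numeric(0)
  if (n_clusters > 0) {
    idx <- which(nodeid > 0L)
    rr <- (idx - 1L) %% H + 1L; cc <- (idx - 1L) %/% H + 1L
    lab <- nodeid[idx]
    nodes_r <- as.numeric(tapply(rr, lab, mean))
    nodes_c <- as.numeric(tapply(cc, lab, mean))
  }

  edges_from <- integer(0); edges_to <- integer(0)
  edges_len <- numeric(0); edges_rad <- numeric(0)
  add_edge <- function(g1, g2, len_px, rad_mean_px) {
    edges_from <<- c(edges_from, g1); edges_to <<- c(edges_to, g2)
    edges_len <<- c(edges_len, max(len_px, 0.5))
    edges_rad <<- c(edges_rad, max(rad_mean_px, 0.5))
  }

  nb_of <- function(r, c) {
    rr <- r + neighbour_offsets[, 1]; cc <- c + neighbour_offsets[, 2]
    ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    rr <- rr[ok]; cc <- cc[ok]
    on <- skel[cbind(rr, cc)]
    cbind(rr[on], cc[on])
  }

  used <- matrix(FALSE, H, W)      # chain pixels consumed by a trace
  adj_seen <- character(0)         # node-node direct adjacency, deduped

  # walk a degree-2 chain starting at node-cluster pixel (r0,c0) towards its
  # skeleton neighbour (r1,c1); returns when another node cluster is reached
  trace_chain <- function(g0, r0, c0, r1, c1) {
    len <- sqrt((r1 - r0)^2 + (c1 - c0)^2)
    rads <- c(rad_px[r0, c0], rad_px[r1, c1])
    pr <- r0; pc <- c0; r <- r1; c <- c1
    repeat {
      used[r, c] <<- TRUE
      nxt <- nb_of(r, c)
      notprev <- !(nxt[, 1] == pr & nxt[, 2] == pc)
      nxt <- nxt[notprev, , drop = FALSE]
      if (nrow(nxt) == 0L) { add_edge(g0, g0, len, mean(rads)); return() }
      nid <- nodeid[cbind(nxt[, 1], nxt[, 2])]
      other <- nid > 0L & nid != g0
      if (any(other)) {
        j <- which(other)[1]
        len <- len + sqrt((nxt[j, 1] - r)^2 + (nxt[j, 2] - c)^2)
        add_edge(g0, nid[j], len + 0, mean(c(rads, rad_px[nxt[j, 1], nxt[j, 2]])))
        return()
      }
      freec <- nid == 0L & !used[cbind(nxt[, 1], nxt[, 2])]
      if (any(freec)) {
        j <- which(freec)[1]
        nr <- nxt[j, 1]; nc <- nxt[j, 2]
        len <- len + sqrt((nr - r)^2 + (nc - c)^2)
        rads <- c(rads, rad_px[nr, nc])
        pr <- r; pc <- c; r <- nr; c <- nc
        next
      }
      back0 <- nid == g0
      if (any(back0) && len > 2) {  # genuine loop back to the same junction
        add_edge(g0, g0, len + 1, mean(rads))
      }
      return()
    }
  }

  if (n_clusters > 0) {
    for (p in which(nodeid > 0L)) {
      r0 <- (p - 1L) %% H + 1L; c0 <- (p - 1L) %/% H + 1L
      g0 <- nodeid[r0, c0]
      nbs <- nb_of(r0, c0)
      if (nrow(nbs) == 0L) next
      for (k in seq_len(nrow(nbs))) {
        r1 <- nbs[k, 1]; c1 <- nbs[k, 2]
        g1 <- nodeid[r1, c1]
        if (g1 > 0L) {
          if (g1 != g0) {  # directly adjacent junction clusters
            key <- paste(min(g0, g1), max(g0, g1))
            if (!(key %in% adj_seen)) {
              adj_seen <- c(adj_seen, key)
              add_edge(g0, g1, sqrt((r1 - r0)^2 + (c1 - c0)^2),
                       (rad_px[r0, c0] + rad_px[r1, c1]) / 2)
            }
          }
        } else if (!used[r1, c1]) {
          trace_chain(g0, r0, c0, r1, c1)
        }
      }
    }
  }

  # pure cycles: chains with no node pixel anywhere (e.g. a ring)
  leftover <- skel & !used & nodeid == 0L
  while (any(leftover)) {
    p <- which(leftover)[1]
    r0 <- (p - 1L) %% H + 1L; c0 <- (p - 1L) %/% H + 1L
    n_clusters <- n_clusters + 1L
    nodes_r <- c(nodes_r, r0); nodes_c <- c(nodes_c, c0)
    g0 <- n_clusters
    leftover[r0, c0] <- FALSE; used[r0, c0] <- TRUE
    nbs <- nb_of(r0, c0)
    free <- leftover[cbind(nbs[, 1], nbs[, 2])]
    if (!any(free)) next
    r <- nbs[which(free)[1], 1]; c <- nbs[which(free)[1], 2]
    len <- sqrt((r - r0)^2 + (c - c0)^2)
    rads <- c(rad_px[r0, c0])
    pr <- r0; pc <- c0
    repeat {
      leftover[r, c] <- FALSE; used[r, c] <- TRUE
      rads <- c(rads, rad_px[r, c])
      nxt <- nb_of(r, c)
      sel <- leftover[cbind(nxt[, 1], nxt[, 2])] &
        !(nxt[, 1] == pr & nxt[, 2] == pc)
      nxt2 <- nxt[sel, , drop = FALSE]
      if (nrow(nxt2) == 0L) {
        len <- len + sqrt((r0 - r)^2 + (c0 - c)^2)  # close the loop
        add_edge(g0, g0, len, mean(rads))
        break
      }
      nr <- nxt2[1, 1]; nc <- nxt2[1, 2]
      len <- len + sqrt((nr - r)^2 + (nc - c)^2)
      pr <- r; pc <- c; r <- nr; c <- nc
    }
  }

  xy <- px_to_xy(nodes_r, nodes_c, H, ps)
  nodes <- data.frame(id = seq_len(n_clusters), x = xy[, "x"], y = xy[, "y"])
  ed <- data.frame(from = edges_from, to = edges_to,
                   radius = edges_rad * ps, length = edges_len * ps)
  # endpoint correction: thinning retracts the skeleton by about one radius
  # at every free vessel end; extend terminal edges back to the wall
  if (nrow(ed)) {
    deg <- table(factor(c(ed$from, ed$to), levels = seq_len(n_clusters)))
    term <- as.integer(names(deg)[deg == 1L])
    ed$length <- ed$length + ed$radius * ((ed$from %in% term) +
                                            (ed$to %in% term))
  }
  # tracing visits every chain once, but two clusters can still be linked by
  # two all-but-identical parallel chains of diagonal steps; keep those
  vessel_graph(nodes, ed)
}

# integer shift of a logical matrix (zero padding), used for neighbour counts
shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  rs <- max(1, 1 - dr):min(H, H - dr)
  cs <- max(1, 1 - dc):min(W, W - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

#' Assign boundary nodes by proximity to the domain border
#'
#' Marks every node within `tol` of the bounding rectangle `[0, width] x
#' [0, height]` as a boundary node with the given pressure.
#'
#' @param graph a [vessel_graph].
#' @param width,height domain extent (m).
#' @param pressure prescribed blood pressure (Pa), recycled across the
#'   selected nodes.
#' @param tol distance tolerance (m).
#' @return the graph with an updated boundary table.
#' @export
assign_boundary_nodes <- function(graph, width, height, pressure, tol) {
  nd <- graph$nodes
  on_border <- nd$x < tol | nd$x > width - tol | nd$y < tol | nd$y > height - tol
  ids <- nd$id[on_border]
  graph$boundary <- data.frame(node = ids,
                               pressure = rep_len(pressure, length(ids)))
  graph
}
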