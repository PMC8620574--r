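# Centreline vessel graph: the reduced representation on which intravascular
# pressure is solved.

#' Vessel centreline graph
#'
#' Nodes are planar points (metres); edges are straight or traced centreline
#' segments with a lumen radius and a centreline length. Boundary nodes carry
#' prescribed blood pressures (Pa) and anchor the intravascular pressure
#' solve.
#'
#' @param nodes data.frame with columns `id` (integer), `x`, `y` (m).
#' @param edges data.frame with columns `from`, `to` (node ids), `radius` (m),
#'   `length` (m). A missing/NA `length` is replaced by the Euclidean node
#'   distance; lengths shorter than the Euclidean distance are clamped up.
#' @param boundary data.frame with columns `node` (id), `pressure` (Pa); may
#'   be empty.
#' @return object of class `vessel_graph`.
#' @export
vessel_graph <- function(nodes = data.frame(id = integer(), x = numeric(),
                                            y = numeric()),
                         edges = data.frame(from = integer(), to = integer(),
                                            radius = numeric(),
                                            length = numeric()),
                         boundary = data.frame(node = integer(),
                                               pressure = numeric())) {
  nodes <- as.data.frame(nodes)
  edges <- as.data.frame(edges)
  boundary <- as.data.frame(boundary)
  stopifnot(all(c("id", "x", "y") %in% names(nodes)),
            all(c("from", "to", "radius") %in% names(edges)),
            all(c("node", "pressure") %in% names(boundary)))
  if (anyDuplicated(nodes$id)) stop_validation("vessel_graph: duplicate node ids")
  if (nrow(edges)) {
    if (is.null(edges$length)) edges$length <- NA_real_
    idx_f <- match(edges$from, nodes$id)
    idx_t <- match(edges$to, nodes$id)
    if (anyNA(idx_f) || anyNA(idx_t))
      stop_validation("vessel_graph: edge endpoint not in node table")
    eu <- sqrt((nodes$x[idx_f] - nodes$x[idx_t])^2 +
                 (nodes$y[idx_f] - nodes$y[idx_t])^2)
    edges$length <- pmax(ifelse(is.na(edges$length), eu, edges$length), eu)
    if (any(edges$radius <= 0)) stop_validation("vessel_graph: radii must be > 0")
    if (any(edges$length <= 0)) stop_validation("vessel_graph: lengths must be > 0")
  }
  if (nrow(boundary) && !all(boundary$node %in% nodes$id))
    stop_validation("vessel_graph: boundary node not in node table")
  structure(list(nodes = nodes, edges = edges, boundary = boundary),
            class = "vessel_graph")
}

#' @export
print.vessel_graph <- function(x, ...) {
  cat(sprintf(
    "<vessel_graph> %d nodes, %d edges (total length %.3g m), %d boundary nodes\n",
    nrow(x$nodes), nrow(x$edges), sum(x$edges$length), nrow(x$boundary)))
  invisible(x)
}

#' Total centreline length of a vessel graph
#' @param graph a [vessel_graph].
#' @return metres.
#' @export
graph_total_length <- function(graph) sum(graph$edges$length)

#' Convert a vessel graph to an igraph object
#' @param graph a [vessel_graph].
#' @return an undirected `igraph` graph with `x`, `y`, `boundary`, `pressure`
#'   vertex attributes and `radius`, `length` edge attributes.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "vessel_graph"))
  vid <- as.character(graph$nodes$id)
  g <- igraph::make_empty_graph(n = nrow(graph$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = vid)
  g <- igraph::set_vertex_attr(g, "x", value = graph$nodes$x)
  g <- igraph::set_vertex_attr(g, "y", value = graph$nodes$y)
  bsel <- graph$nodes$id %in% graph$boundary$node
  g <- igraph::set_vertex_attr(g, "boundary", value = as.integer(bsel))
  pr <- rep(NA_real_, nrow(graph$nodes))
  pr[match(graph$boundary$node, graph$nodes$id)] <- graph$boundary$pressure
  g <- igraph::set_vertex_attr(g, "pressure_Pa", value = pr)
  if (nrow(graph$edges)) {
    ev <- rbind(match(graph$edges$from, graph$nodes$id),
                match(graph$edges$to, graph$nodes$id))
    g <- igraph::add_edges(g, as.vector(ev))
    g <- igraph::set_edge_attr(g, "radius_m", value = graph$edges$radius)
    g <- igraph::set_edge_attr(g, "length_m", value = graph$edges$length)
  }
  g
}

#' Write a vessel graph to GraphML
#' @param graph a [vessel_graph].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' Write a vessel graph as CSV node and edge lists
#'
#' Writes `<stem>_nodes.csv` (id, x, y, boundary, pressure_Pa) and
#' `<stem>_edges.csv` (from, to, radius_m, length_m).
#' @param graph a [vessel_graph].
#' @param stem output path stem.
#' @return character vector of the two paths, invisibly.
#' @export
write_graph_csv <- function(graph, stem) {
  nd <- graph$nodes
  nd$boundary <- as.integer(nd$id %in% graph$boundary$node)
  nd$pressure_Pa <- NA_real_
  nd$pressure_Pa[match(graph$boundary$node, nd$id)] <- graph$boundary$pressure
  ed <- graph$edges
  names(ed)[names(ed) == "radius"] <- "radius_m"
  names(ed)[names(ed) == "length"] <- "length_m"
  p1 <- paste0(stem, "_nodes.csv"); p2 <- paste0(stem, "_edges.csv")
  write.csv(nd, p1, row.names = FALSE)
  write.csv(ed, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

# connected component membership per node id (integer vector named by id)
graph_components <- function(graph) {
  if (!nrow(graph$nodes)) return(integer(0))
  comp <- igraph::components(as_igraph(graph))$membership
  setNames(as.integer(comp), graph$nodes$id)
}
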