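#' Create a distance model
#'
#' The behavioural rules depend on space only through a distance function, so
#' the model abstracts travel as either straight-line (euclidean) distance or
#' shortest paths on a road network.  In network mode a graph can be supplied
#' directly (e.g. read with [read_road_network()]); otherwise a perturbed grid
#' graph is built over the region as a stand-in street network.
#'
#' Network distances between two points are computed as
#' snap-leg + shortest path + snap-leg: the straight-line legs from each point
#' to its nearest network node plus the shortest path between those nodes.
#' Because every edge weight is at least the straight-line length of the edge,
#' network distance always dominates euclidean distance between the same
#' points.  Identical points are at distance 0; node pairs in different graph
#' components are unreachable (`Inf`).
#'
#' @param mode `"euclidean"` or `"network"`.
#' @param region A `study_region`; required to build the default grid network.
#' @param graph An `igraph` graph with edge attribute `weight` (km); optional.
#' @param nodes A matrix/data frame of node coordinates (columns `x`, `y`) in
#'   the same vertex order as `graph`; required when `graph` is supplied.
#' @param grid_spacing Grid spacing in km for the synthetic network (default 0.5).
#' @param jitter Node position jitter as a fraction of the spacing (default 0.2).
#' @param seed Integer seed for the jitter.
#' @return An object of class `distance_model`.
#' @export
distance_model <- function(mode = c("euclidean", "network"), region = NULL,
                           graph = NULL, nodes = NULL,
                           grid_spacing = 0.5, jitter = 0.2, seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "euclidean") {
    return(structure(list(mode = "euclidean"), class = "distance_model"))
  }
  if (is.null(graph)) {
    if (is.null(region)) stop("network mode needs a `region` or a `graph`", call. = FALSE)
    g <- .make_grid_network(region, grid_spacing, jitter, seed)
    graph <- g$graph
    nodes <- g$nodes
  } else {
    if (is.null(nodes)) stop("a supplied `graph` needs node coordinates in `nodes`", call. = FALSE)
    nodes <- as.matrix(as.data.frame(nodes)[, c("x", "y")])
    if (nrow(nodes) != igraph::vcount(graph)) {
      stop("`nodes` must have one row per graph vertex", call. = FALSE)
    }
  }
  if (!igraph::is_connected(graph)) {
    warning("network graph is not connected; unreachable pairs get distance Inf")
  }
  structure(list(mode = "network", graph = graph, nodes = nodes),
            class = "distance_model")
}

# Perturbed 4-neighbour grid over the region. Edge weights are the euclidean
# lengths of the (jittered) edges, so path length >= straight-line distance.
.make_grid_network <- function(region, spacing, jitter, seed) {
  set.seed(as.integer(seed))
  gx <- seq(0, region$width, by = spacing)
  gy <- seq(0, region$height, by = spacing)
  nx <- length(gx)
  ny <- length(gy)
  xs <- rep(gx, times = ny) + runif(nx * ny, -jitter, jitter) * spacing
  ys <- rep(gy, each = nx) + runif(nx * ny, -jitter, jitter) * spacing
  xs <- pmin(pmax(xs, 0), region$width)
  ys <- pmin(pmax(ys, 0), region$height)
  id <- function(i, j) (j - 1L) * nx + i
  from <- integer(0); to <- integer(0)
  for (j in seq_len(ny)) {
    from <- c(from, id(seq_len(nx - 1L), j)); to <- c(to, id(seq_len(nx - 1L) + 1L, j))
  }
  for (j in seq_len(ny - 1L)) {
    from <- c(from, id(seq_len(nx), j)); to <- c(to, id(seq_len(nx), j + 1L))
  }
  w <- sqrt((xs[from] - xs[to])^2 + (ys[from] - ys[to])^2)
  g <- igraph::make_empty_graph(n = nx * ny, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  list(graph = g, nodes = cbind(x = xs, y = ys))
}

.nearest_node <- function(model, pts) {
  nd <- model$nodes
  vapply(seq_len(nrow(pts)), function(i) {
    which.min((nd[, 1] - pts[i, 1])^2 + (nd[, 2] - pts[i, 2])^2)
  }, integer(1))
}

#' Distance between two locations
#'
#' @param model A `distance_model`.
#' @param a,b Numeric length-2 vectors `c(x, y)` in km.
#' @return Distance in km (`Inf` for unreachable network pairs).
#' @export
#' @examples
#' travel_distance(distance_model("euclidean"), c(0, 0), c(3, 4))  # 5
travel_distance <- function(model, a, b) {
  distance_matrix(model, matrix(a, ncol = 2), matrix(b, ncol = 2))[1L, 1L]
}

#' Pairwise distance matrix between two point sets
#'
#' @param model A `distance_model`.
#' @param from,to Two-column matrices (or data frames with `x`, `y`) of
#'   locations in km.
#' @return A `nrow(from) x nrow(to)` matrix of km distances.
#' @export
distance_matrix <- function(model, from, to) {
  stopifnot(inherits(model, "distance_model"))
  from <- .as_xy(from)
  to <- .as_xy(to)
  if (nrow(from) == 0L || nrow(to) == 0L) {
    return(matrix(numeric(0), nrow = nrow(from), ncol = nrow(to)))
  }
  eu <- sqrt(outer(from[, 1], to[, 1], "-")^2 + outer(from[, 2], to[, 2], "-")^2)
  if (model$mode == "euclidean") return(eu)
  nf <- .nearest_node(model, from)
  nt <- .nearest_node(model, to)
  legf <- sqrt((model$nodes[nf, 1] - from[, 1])^2 + (model$nodes[nf, 2] - from[, 2])^2)
  legt <- sqrt((model$nodes[nt, 1] - to[, 1])^2 + (model$nodes[nt, 2] - to[, 2])^2)
  sp <- igraph::distances(model$graph, v = sort(unique(nf)), to = sort(unique(nt)))
  core <- sp[match(nf, sort(unique(nf))), match(nt, sort(unique(nt))), drop = FALSE]
  d <- core + outer(legf, rep(0, length(legt)), "+") + outer(rep(0, length(legf)), legt, "+")
  # identical coordinates are at distance zero regardless of snapping
  same <- outer(from[, 1], to[, 1], "==") & outer(from[, 2], to[, 2], "==")
  d[same] <- 0
  dimnames(d) <- NULL
  d
}

.as_xy <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y")])
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  storage.mode(p) <- "double"
  p
}
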