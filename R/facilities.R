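#' Default per-visit health-gain coefficients by facility type
#'
#' Prevention facilities (parks, squares) give the smallest per-visit gain,
#' treatment facilities (medical institutions) the largest of the three base
#' types, and long-term care facilities an intermediate gain. Comprehensive
#' hubs, added by the community-centre intervention, bundle all three
#' functions and carry a much larger per-visit gain.
#'
#' @return Named numeric vector over facility types.
#' @export
default_facility_gains <- function() {
  c(prevention = 0.001, treatment = 0.003, care = 0.002, comprehensive = 0.05)
}

#' Generate facility sites
#'
#' Samples facility locations from the region's density surface (services
#' cluster where people do) and assigns types in configured counts.
#'
#' @param region A `study_region`.
#' @param counts Named integer vector of per-type counts; names from
#'   `prevention`, `treatment`, `care`, `comprehensive`. Default 40/40/20,
#'   the urban service ratio the model emulates.
#' @param seed Integer seed.
#' @param gains Named per-visit gain coefficients by type
#'   (default [default_facility_gains()]).
#' @param education_types Facility types flagged as hosts of community health
#'   education sessions (default prevention facilities and comprehensive hubs).
#' @param education_fraction Fraction of facilities of those types flagged
#'   (default 1).
#' @return A tibble with columns `id`, `x`, `y`, `type`, `gain`,
#'   `education_host`, exactly `sum(counts)` rows.
#' @export
generate_facilities <- function(region,
                                counts = c(prevention = 40L, treatment = 40L, care = 20L),
                                seed = 1L,
                                gains = default_facility_gains(),
                                education_types = c("prevention", "comprehensive"),
                                education_fraction = 1) {
  stopifnot(inherits(region, "study_region"))
  if (any(counts < 0)) stop("facility counts must be non-negative", call. = FALSE)
  bad <- setdiff(names(counts), .ftypes)
  if (length(bad)) stop("unknown facility type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  n <- sum(counts)
  set.seed(as.integer(seed))
  pts <- sample_points(region, n)
  type <- rep(names(counts), times = counts)
  fac <- tibble::tibble(
    id = seq_len(n),
    x = pts$x, y = pts$y,
    type = type,
    gain = unname(gains[type]),
    education_host = FALSE
  )
  cand <- which(fac$type %in% education_types)
  if (length(cand) && education_fraction > 0) {
    k <- round(education_fraction * length(cand))
    fac$education_host[sample(cand, min(k, length(cand)))] <- TRUE
  }
  fac
}

#' Read / write facility tables
#'
#' CSV files use columns `id`, `x`, `y`, `type`; GeoJSON files are a
#' `FeatureCollection` of Point features with `id` and `type` properties.
#' Gains and education flags are re-derived from the type on read.
#'
#' @param path File path.
#' @param gains,education_types,education_fraction Passed through as in
#'   [generate_facilities()].
#' @return `read_*` return a facility tibble; `write_*` return `path`
#'   invisibly.
#' @export
read_facilities_csv <- function(path, gains = default_facility_gains(),
                                education_types = c("prevention", "comprehensive"),
                                education_fraction = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "x", "y", "type") %in% names(df)))
  .finish_facilities(df, gains, education_types, education_fraction)
}

#' @rdname read_facilities_csv
#' @param facilities A facility tibble.
#' @export
write_facilities_csv <- function(facilities, path) {
  utils::write.csv(facilities[, c("id", "x", "y", "type")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_facilities_csv
#' @export
read_facilities_geojson <- function(path, gains = default_facility_gains(),
                                    education_types = c("prevention", "comprehensive"),
                                    education_fraction = 1) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  stopifnot(identical(gj$type, "FeatureCollection"))
  rows <- lapply(gj$features, function(f) {
    data.frame(id = f$properties$id,
               x = f$geometry$coordinates[[1]],
               y = f$geometry$coordinates[[2]],
               type = f$properties$type,
               stringsAsFactors = FALSE)
  })
  .finish_facilities(do.call(rbind, rows), gains, education_types, education_fraction)
}

#' @rdname read_facilities_csv
#' @export
write_facilities_geojson <- function(facilities, path) {
  feats <- lapply(seq_len(nrow(facilities)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(facilities$x[i], facilities$y[i])),
         properties = list(id = facilities$id[i], type = facilities$type[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.finish_facilities <- function(df, gains, education_types, education_fraction) {
  bad <- setdiff(unique(df$type), .ftypes)
  if (length(bad)) stop("unknown facility type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  fac <- tibble::as_tibble(df[, c("id", "x", "y", "type")])
  fac$id <- as.integer(fac$id)
  fac$gain <- unname(gains[fac$type])
  fac$education_host <- fac$type %in% education_types
  if (education_fraction < 1) {
    cand <- which(fac$education_host)
    keep <- utils::head(cand, round(education_fraction * length(cand)))
    fac$education_host <- FALSE
    fac$education_host[keep] <- TRUE
  }
  fac
}

#' Read / write a road network
#'
#' The network is stored as two CSVs: an edge list with columns `u`, `v`,
#' `length_km` and a node table with columns `id`, `x`, `y` (km). Node ids
#' must be the integers `1..n`.
#'
#' @param edges_path,nodes_path File paths.
#' @return `read_road_network()` returns a list with an `igraph` `graph` and a
#'   `nodes` coordinate matrix, suitable for [distance_model()].
#' @export
read_road_network <- function(edges_path, nodes_path) {
  ed <- utils::read.csv(edges_path, stringsAsFactors = FALSE)
  nd <- utils::read.csv(nodes_path, stringsAsFactors = FALSE)
  stopifnot(all(c("u", "v", "length_km") %in% names(ed)),
            all(c("id", "x", "y") %in% names(nd)))
  nd <- nd[order(nd$id), ]
  if (!identical(as.integer(nd$id), seq_len(nrow(nd)))) {
    stop("node ids must be 1..n", call. = FALSE)
  }
  g <- igraph::make_empty_graph(n = nrow(nd), directed = FALSE)
  g <- igraph::add_edges(g, rbind(as.integer(ed$u), as.integer(ed$v)))
  igraph::E(g)$weight <- as.numeric(ed$length_km)
  list(graph = g, nodes = cbind(x = nd$x, y = nd$y))
}

#' @rdname read_road_network
#' @param network A list as returned by [read_road_network()].
#' @export
write_road_network <- function(network, edges_path, nodes_path) {
  el <- igraph::as_edgelist(network$graph)
  utils::write.csv(data.frame(u = el[, 1], v = el[, 2],
                              length_km = igraph::E(network$graph)$weight),
                   edges_path, row.names = FALSE)
  utils::write.csv(data.frame(id = seq_len(nrow(network$nodes)),
                              x = network$nodes[, 1], y = network$nodes[, 2]),
                   nodes_path, row.names = FALSE)
  invisible(edges_path)
}
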