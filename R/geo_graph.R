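#' Spatial adjacency graphs for small-area models
#'
#' An `adjacency_graph` is the neighbourhood structure that the intrinsic CAR
#' prior operates on: an ordered set of spatial units (ordered
#' lexicographically by `unit_id` so that all downstream results are
#' reproducible), a symmetric, irreflexive neighbour list, and a connected
#' component labelling. Units with no neighbours ("islands") are retained;
#' the CAR machinery treats them specially (their spatial effect is pinned
#' at zero).
#'
#' @param units character vector of unique unit identifiers.
#' @param neighbors list (same length as `units`) of integer vectors of
#'   neighbour indices into `units`.
#' @return An object of class `adjacency_graph` with elements `units`,
#'   `neighbors`, `n_components` and `component_label`.
#' @seealso [build_adjacency_from_edgelist()], [build_adjacency_from_polygons()],
#'   [lattice_graph()]
#' @export
adjacency_graph <- function(units, neighbors) {
  stopifnot(is.character(units), is.list(neighbors),
            length(units) == length(neighbors))
  if (anyDuplicated(units)) {
    stop("duplicate unit_id: ",
         paste(unique(units[duplicated(units)]), collapse = ", "))
  }
  ord <- order(units, method = "radix")
  rank <- match(seq_along(units), ord)
  neighbors <- lapply(neighbors[ord], function(v) sort(rank[v]))
  units <- units[ord]
  g <- structure(
    list(units = units,
         neighbors = lapply(neighbors, as.integer),
         n_components = 0L,
         component_label = integer(length(units))),
    class = "adjacency_graph")
  comp <- component_labels(g)
  g$component_label <- comp
  g$n_components <- max(comp, 0L)
  validate_adjacency_graph(g)
  g
}

#' Validate the invariants of an adjacency graph
#'
#' Checks symmetry (`j` a neighbour of `i` iff `i` a neighbour of `j`),
#' absence of self-loops, index bounds, and that the stored component
#' labelling agrees with neighbour reachability.
#'
#' @param g an `adjacency_graph`.
#' @return `g`, invisibly; errors describe the first violated invariant.
#' @export
validate_adjacency_graph <- function(g) {
  stopifnot(inherits(g, "adjacency_graph"))
  n <- length(g$units)
  for (i in seq_len(n)) {
    nb <- g$neighbors[[i]]
    if (length(nb) == 0L) next
    if (any(nb < 1L | nb > n)) stop("neighbor index out of range for unit ", g$units[i])
    if (any(nb == i)) stop("self-loop at unit ", g$units[i])
    if (anyDuplicated(nb)) stop("duplicate neighbor entries for unit ", g$units[i])
    for (j in nb) {
      if (!(i %in% g$neighbors[[j]])) {
        stop("asymmetric adjacency between ", g$units[i], " and ", g$units[j])
      }
    }
  }
  if (!identical(component_labels(g), g$component_label)) {
    stop("component labels inconsistent with neighbor reachability")
  }
  invisible(g)
}

# Connected component labelling, delegated to igraph. Labels are renumbered
# so that component 1 contains the lexicographically first unit, etc.
component_labels <- function(g) {
  n <- length(g$units)
  if (n == 0L) return(integer(0))
  ig <- igraph::graph_from_adj_list(g$neighbors, mode = "all")
  memb <- igraph::components(ig)$membership
  as.integer(match(memb, unique(memb)))
}

#' @export
print.adjacency_graph <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf("adjacency_graph: %d units, %d edges, %d component(s)\n",
              length(x$units), sum(deg) %/% 2L, x$n_components))
  if (any(deg == 0L)) cat(sprintf("  %d island unit(s) (degree 0)\n", sum(deg == 0L)))
  invisible(x)
}

#' Per-unit neighbour counts
#' @param g an `adjacency_graph`.
#' @return integer vector of degrees, named by unit id.
#' @export
graph_degrees <- function(g) {
  stats::setNames(lengths(g$neighbors), g$units)
}

#' Edge list of a graph as a two-column character matrix
#' @param g an `adjacency_graph`.
#' @return matrix with columns `unit_id_a`, `unit_id_b`, one row per
#'   undirected edge (a < b lexicographically).
#' @export
as_edge_matrix <- function(g) {
  e <- list()
  for (i in seq_along(g$units)) {
    nb <- g$neighbors[[i]]
    nb <- nb[nb > i]
    if (length(nb)) e[[length(e) + 1L]] <- cbind(g$units[i], g$units[nb])
  }
  out <- if (length(e)) do.call(rbind, e) else matrix(character(0), ncol = 2)
  colnames(out) <- c("unit_id_a", "unit_id_b")
  out
}

#' Build an adjacency graph from an explicit edge list
#'
#' The symmetric closure is applied, duplicate and reversed edges are
#' collapsed, and units without any edge are retained as isolated nodes.
#'
#' @param edges a two-column data frame / matrix of unit-id pairs, or the
#'   path to a delimited text file (tab or comma separated, header row with
#'   two columns).
#' @param units character vector of all unit ids; every edge endpoint must
#'   appear here.
#' @return an [adjacency_graph()].
#' @export
build_adjacency_from_edgelist <- function(edges, units) {
  if (is.character(edges) && length(edges) == 1L && file.exists(edges)) {
    sep <- if (grepl(",", readLines(edges, n = 1L))) "," else ""
    edges <- utils::read.table(edges, header = TRUE, sep = sep,
                               colClasses = "character",
                               stringsAsFactors = FALSE)
  }
  units <- sort(unique(as.character(units)), method = "radix")
  edges <- as.matrix(edges)
  nb <- rep(list(integer(0)), length(units))
  if (nrow(edges) > 0) {
    a <- match(as.character(edges[, 1]), units)
    b <- match(as.character(edges[, 2]), units)
    bad <- is.na(a) | is.na(b)
    if (any(bad)) {
      off <- unique(c(edges[is.na(a), 1], edges[is.na(b), 2]))
      stop("edge endpoint(s) not in unit list: ", paste(off, collapse = ", "))
    }
    if (any(a == b)) {
      stop("self-loop edge(s) for unit(s): ",
           paste(unique(edges[a == b, 1]), collapse = ", "))
    }
    for (k in seq_along(a)) {
      nb[[a[k]]] <- c(nb[[a[k]]], b[k])
      nb[[b[k]]] <- c(nb[[b[k]]], a[k])
    }
    nb <- lapply(nb, function(v) sort(unique(v)))
  }
  adjacency_graph(units, nb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build an adjacency graph from polygon geometries
#'
#' Contiguity is determined from shared polygon vertices: under the default
#' queen rule two units are neighbours when their boundaries share at least
#' one vertex (so corner touches count, as they must for municipality
#' mosaics); under the rook rule they must share at least two vertices,
#' i.e. a boundary segment. This vertex-based rule assumes a topologically
#' consistent mosaic in which touching boundaries carry coincident
#' vertices (true of the generators in this package and of clean
#' administrative tilings); it performs no geometric snapping or repair.
#'
#' @param geometries either the path to a GeoJSON FeatureCollection whose
#'   features carry a `unit_id` property, or a named list (names = unit
#'   ids) of polygon rings, each ring a numeric matrix of xy coordinates
#'   (a list of such matrices is taken as a multipolygon).
#' @param contiguity `"queen"` (default) or `"rook"`.
#' @param digits coordinates are rounded to this many digits before vertex
#'   comparison.
#' @return an [adjacency_graph()].
#' @export
build_adjacency_from_polygons <- function(geometries,
                                          contiguity = c("queen", "rook"),
                                          digits = 8) {
  contiguity <- match.arg(contiguity)
  polys <- if (is.character(geometries) && length(geometries) == 1L) {
    read_geojson_polygons(geometries)
  } else geometries
  if (is.null(names(polys)) || anyDuplicated(names(polys))) {
    stop("polygon collection must be named by unique unit_id")
  }
  verts <- lapply(names(polys), function(id) {
    rings <- polys[[id]]
    if (is.matrix(rings)) rings <- list(rings)
    if (!length(rings)) stop("empty geometry for unit ", id)
    pts <- do.call(rbind, lapply(rings, function(r) {
      r <- as.matrix(r)
      if (!is.numeric(r) || ncol(r) < 2 || nrow(r) < 3 || anyNA(r)) {
        stop("invalid geometry for unit ", id)
      }
      r[, 1:2, drop = FALSE]
    }))
    unique(paste(round(pts[, 1], digits), round(pts[, 2], digits)))
  })
  names(verts) <- names(polys)
  units <- sort(names(polys), method = "radix")
  verts <- verts[units]
  # invert: vertex -> units incident on it
  vkey <- rep(seq_along(units), lengths(verts))
  vtab <- split(vkey, unlist(verts, use.names = FALSE))
  shared <- new.env(parent = emptyenv())
  for (us in vtab) {
    us <- unique(us)
    if (length(us) < 2L) next
    for (i in seq_len(length(us) - 1L)) for (j in seq((i + 1L), length(us))) {
      key <- paste(us[i], us[j])
      shared[[key]] <- (shared[[key]] %||% 0L) + 1L
    }
  }
  need <- if (contiguity == "queen") 1L else 2L
  nb <- rep(list(integer(0)), length(units))
  for (key in ls(shared)) {
    if (shared[[key]] >= need) {
      ij <- as.integer(strsplit(key, " ")[[1]])
      nb[[ij[1]]] <- c(nb[[ij[1]]], ij[2])
      nb[[ij[2]]] <- c(nb[[ij[2]]], ij[1])
    }
  }
  adjacency_graph(units, lapply(nb, function(v) sort(unique(v))))
}

# Parse a GeoJSON FeatureCollection (Polygon / MultiPolygon features) into
# the named-list-of-rings form used above. Feature property "unit_id" required.
read_geojson_polygons <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) stop("expected a GeoJSON FeatureCollection")
  out <- list()
  for (f in gj$features) {
    id <- f$properties$unit_id
    if (is.null(id)) stop("feature without a unit_id property")
    id <- as.character(id)
    if (id %in% names(out)) stop("duplicate unit_id in GeoJSON: ", id)
    geom <- f$geometry
    ring_to_mat <- function(ring) {
      do.call(rbind, lapply(ring, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    }
    rings <- switch(
      geom$type %||% "",
      Polygon = lapply(geom$coordinates, ring_to_mat),
      MultiPolygon = unlist(lapply(geom$coordinates,
                                   function(pg) lapply(pg, ring_to_mat)),
                            recursive = FALSE),
      stop("unsupported geometry type for unit ", id, ": ", geom$type %||% "NULL"))
    out[[id]] <- rings
  }
  out
}

#' Regular lattice adjacency graph
#'
#' A `rows` x `cols` grid of unit squares with rook adjacency (shared
#' edges), the standard test geography standing in for a municipality
#' mosaic. Unit ids are deterministic functions of the cell position,
#' zero-padded so lexicographic order equals row-major order.
#'
#' @param rows,cols positive integers.
#' @return an [adjacency_graph()] with `rows * cols` units.
#' @export
lattice_graph <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L) {
    stop("rows and cols must be positive integers")
  }
  id <- function(r, c) sprintf("g%03d_%03d", r, c)
  units <- character(rows * cols)
  nb <- vector("list", rows * cols)
  idx <- function(r, c) (r - 1L) * cols + c
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    k <- idx(r, c)
    units[k] <- id(r, c)
    v <- integer(0)
    if (r > 1L)    v <- c(v, idx(r - 1L, c))
    if (r < rows)  v <- c(v, idx(r + 1L, c))
    if (c > 1L)    v <- c(v, idx(r, c - 1L))
    if (c < cols)  v <- c(v, idx(r, c + 1L))
    nb[[k]] <- v
  }
  adjacency_graph(units, nb)
}

#' Write a graph's edge list as delimited text
#' @param g an `adjacency_graph`.
#' @param path output file path (tab-separated, header row).
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path) {
  utils::write.table(as_edge_matrix(g), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
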