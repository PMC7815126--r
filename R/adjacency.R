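#' Admin-1 adjacency graphs
#'
#' The spatial smoothing components (ICAR and the space-time interaction)
#' need a symmetric neighbourhood structure on the Admin-1 areas. An
#' `adjacency_graph` stores node labels, a symmetric edge list and the
#' connected-component partition.
#'
#' @param nodes character vector of area labels.
#' @param edges two-column matrix (or data.frame) of node indices or labels;
#'   each row one undirected edge.
#' @return An object of class `adjacency_graph` with elements `nodes`,
#'   `edges` (integer matrix, `from < to`), `n` and `component` (integer
#'   membership vector).
#' @export
adjacency_graph <- function(nodes, edges) {
  nodes <- as.character(nodes)
  n <- length(nodes)
  edges <- as.matrix(edges)
  if (is.character(edges)) {
    edges <- matrix(match(edges, nodes), ncol = 2)
    if (anyNA(edges)) stop("edge labels not all found in `nodes`")
  }
  storage.mode(edges) <- "integer"
  if (nrow(edges) > 0) {
    if (any(edges < 1L | edges > n)) stop("edge indices out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  g <- structure(list(nodes = nodes, edges = edges, n = n), class = "adjacency_graph")
  g$component <- graph_components(g)
  g
}

## connected components by breadth-first search
graph_components <- function(g) {
  n <- g$n
  nbr <- vector("list", n)
  if (nrow(g$edges) > 0) {
    for (k in seq_len(nrow(g$edges))) {
      i <- g$edges[k, 1]; j <- g$edges[k, 2]
      nbr[[i]] <- c(nbr[[i]], j); nbr[[j]] <- c(nbr[[j]], i)
    }
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nbr[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat(sprintf("<adjacency_graph: %d nodes, %d edges, %d component(s)>\n",
              x$n, nrow(x$edges), max(x$component)))
  invisible(x)
}

#' Adjacency matrix of a graph
#' @param g an [adjacency_graph()].
#' @return n x n symmetric 0/1 matrix.
#' @export
adjacency_matrix <- function(g) {
  A <- matrix(0, g$n, g$n, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges) > 0) {
    A[g$edges] <- 1
    A[g$edges[, 2:1, drop = FALSE]] <- 1
  }
  A
}

#' Generate a synthetic Admin-1 adjacency structure
#'
#' Two layouts are supported. `"grid"` arranges the areas on a nearly square
#' lattice with rook contiguity, the usual stylised map in space-time
#' smoothing simulations. `"random_planar"` draws uniform points in the unit
#' square and connects them by their Gabriel graph (an edge when no third
#' point lies in the circle having the edge as diameter), which is planar and
#' connected -- a reasonable stand-in for irregular administrative maps.
#'
#' @param n_areas number of areas (>= 2).
#' @param layout `"grid"` or `"random_planar"`.
#' @param seed integer seed; the result is deterministic given the seed.
#' @return An [adjacency_graph()] with nodes `"A1" ... "A<n>"`.
#' @export
generate_adjacency <- function(n_areas, layout = c("grid", "random_planar"),
                               seed = 1L) {
  layout <- match.arg(layout)
  if (!is.numeric(n_areas) || length(n_areas) != 1 || n_areas < 2)
    stop("`n_areas` must be a single integer >= 2")
  n_areas <- as.integer(n_areas)
  nodes <- paste0("A", seq_len(n_areas))
  if (n_areas == 2L)
    return(adjacency_graph(nodes, cbind(1L, 2L)))
  if (layout == "grid") {
    ncol_ <- ceiling(sqrt(n_areas))
    row <- (seq_len(n_areas) - 1L) %/% ncol_ + 1L
    col <- (seq_len(n_areas) - 1L) %% ncol_ + 1L
    e <- list()
    for (i in seq_len(n_areas)) for (j in seq_len(n_areas)) {
      if (i < j && abs(row[i] - row[j]) + abs(col[i] - col[j]) == 1L)
        e[[length(e) + 1L]] <- c(i, j)
    }
    return(adjacency_graph(nodes, do.call(rbind, e)))
  }
  ## random_planar: Gabriel graph of uniform points
  set.seed(seed)
  x <- runif(n_areas); y <- runif(n_areas)
  e <- list()
  for (i in seq_len(n_areas - 1L)) for (j in seq(i + 1L, n_areas)) {
    cx <- (x[i] + x[j]) / 2; cy <- (y[i] + y[j]) / 2
    r2 <- (x[i] - cx)^2 + (y[i] - cy)^2
    d2 <- (x - cx)^2 + (y - cy)^2
    d2[c(i, j)] <- Inf
    if (all(d2 > r2)) e[[length(e) + 1L]] <- c(i, j)
  }
  adjacency_graph(nodes, do.call(rbind, e))
}

#' Read / write an adjacency edge list
#'
#' The on-disk format is a two-column CSV (`from`, `to`) of area labels, one
#' undirected edge per row.
#'
#' @param g an [adjacency_graph()].
#' @param path file path.
#' @param nodes optional full node set when reading (to keep isolated areas).
#' @export
write_adjacency <- function(g, path) {
  utils::write.csv(data.frame(from = g$nodes[g$edges[, 1]],
                              to   = g$nodes[g$edges[, 2]]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path, nodes = NULL) {
  df <- utils::read.csv(path, colClasses = "character")
  if (is.null(nodes)) nodes <- sort(unique(c(df$from, df$to)))
  adjacency_graph(nodes, cbind(df$from, df$to))
}

#' Derive contiguity from GeoJSON polygons
#'
#' Reads a GeoJSON `FeatureCollection` of (Multi)Polygons and declares two
#' features neighbours when their boundaries share at least two distinct
#' vertices (one common boundary segment under matched digitisation) --
#' rook-style contiguity for polygon layers digitised from a common
#' topology. Feature labels are taken from the property named by `id`.
#'
#' @param path GeoJSON file path.
#' @param id name of the feature property holding the area label.
#' @return An [adjacency_graph()].
#' @export
adjacency_from_geojson <- function(path, id = "name") {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  lab <- character(0); verts <- list()
  for (f in gj$features) {
    lab <- c(lab, as.character(f$properties[[id]]))
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = geom$coordinates,
      MultiPolygon = do.call(c, geom$coordinates),
      stop("unsupported geometry type: ", geom$type))
    vv <- unique(unlist(lapply(rings, function(ring)
      vapply(ring, function(pt) paste(format(as.numeric(pt[[1]]), digits = 12),
                                      format(as.numeric(pt[[2]]), digits = 12)),
             character(1))), use.names = FALSE))
    verts[[length(verts) + 1L]] <- vv
  }
  n <- length(lab)
  e <- list()
  if (n >= 2) for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (length(intersect(verts[[i]], verts[[j]])) >= 2L)
      e[[length(e) + 1L]] <- c(i, j)
  }
  adjacency_graph(lab, if (length(e)) do.call(rbind, e) else
    matrix(integer(0), 0, 2))
}
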