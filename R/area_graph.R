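#' Areal adjacency graph
#'
#' An `area_graph` stores the neighbourhood structure of a set of areal units
#' together with the binary first-order spatial weights \eqn{w_{ij} \in \{0,1\}}
#' used by the CAR models and by every spatial statistic in the package.
#' Areas are kept in the order of first appearance in the input; all matrices
#' produced downstream are indexed in that order.
#'
#' @param w square binary symmetric matrix of spatial weights with zero
#'   diagonal, or a neighbour list (list of integer index vectors).
#' @param ids character vector of area labels. Defaults to rownames of `w`
#'   or `"A1"..."An"`.
#'
#' @return An object of class `area_graph` with components `ids`, `nb`
#'   (per-area integer vector of neighbour indices), `n`, and `w` (dense
#'   binary weight matrix). Areas without any neighbour are retained and
#'   reported by [isolated_areas()].
#' @examples
#' g <- make_lattice(3, 3)
#' g
#' neighbor_mean(g, seq_len(9))
#' @seealso [make_lattice()], [graph_from_edges()], [read_gal()],
#'   [boundary_distances()]
#' @export
area_graph <- function(w, ids = NULL) {
  if (is.list(w) && !is.data.frame(w)) {
    nb <- lapply(w, function(v) sort(unique(as.integer(v))))
    n <- length(nb)
    if (is.null(ids)) ids <- names(w)
    if (is.null(ids)) ids <- paste0("A", seq_len(n))
    W <- matrix(0, n, n)
    for (i in seq_len(n)) W[i, nb[[i]]] <- 1
  } else {
    W <- as.matrix(w)
    n <- nrow(W)
    if (n != ncol(W)) stop("weight matrix must be square")
    if (is.null(ids)) ids <- rownames(W)
    if (is.null(ids)) ids <- paste0("A", seq_len(n))
    if (!all(W %in% c(0, 1))) stop("weights must be binary 0/1")
    nb <- lapply(seq_len(n), function(i) which(W[i, ] == 1))
  }
  if (n < 2L) stop("an area_graph needs at least 2 areas")
  if (any(diag(W) != 0)) stop("self-loops are not allowed (nonzero diagonal)")
  if (!isTRUE(all.equal(W, t(W)))) stop("weight matrix must be symmetric")
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicated area ids")
  dimnames(W) <- list(ids, ids)
  g <- structure(
    list(ids = ids, nb = nb, n = n, w = W),
    class = "area_graph"
  )
  iso <- isolated_areas(g)
  if (length(iso)) {
    warning(sprintf("%d isolated area(s) retained: %s", length(iso),
                    paste(utils::head(ids[iso], 5L), collapse = ", ")))
  }
  g
}

#' @export
print.area_graph <- function(x, ...) {
  ne <- sum(x$w) / 2
  cat(sprintf("area_graph: %d areas, %d edges (binary first-order weights)\n",
              x$n, ne))
  iso <- isolated_areas(x)
  if (length(iso)) cat("isolated areas:", paste(x$ids[iso], collapse = ", "), "\n")
  invisible(x)
}

#' Indices of areas without any neighbour
#'
#' @param graph an [area_graph()].
#' @return integer vector of indices of isolated areas (possibly empty).
#' @export
isolated_areas <- function(graph) {
  which(vapply(graph$nb, length, 1L) == 0L)
}

#' Number of neighbours per area
#' @param graph an [area_graph()].
#' @return integer vector \eqn{d_i = \sum_j w_{ij}}.
#' @export
area_degree <- function(graph) {
  vapply(graph$nb, length, 1L)
}

#' Build a graph from an edge list
#'
#' @param edges two-column matrix or data frame of area labels, one row per
#'   undirected edge.
#' @param ids optional character vector declaring the full set of area labels
#'   (so that areas with no edges are retained as isolated). Defaults to the
#'   labels appearing in `edges`, in order of first appearance.
#' @return an [area_graph()].
#' @export
graph_from_edges <- function(edges, ids = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edge list must have exactly two columns")
  a <- as.character(edges[, 1L]); b <- as.character(edges[, 2L])
  if (is.null(ids)) ids <- unique(c(rbind(a, b)))
  ids <- as.character(ids)
  unknown <- setdiff(c(a, b), ids)
  if (length(unknown)) {
    stop("edge refers to undeclared area id(s): ",
         paste(unique(unknown), collapse = ", "))
  }
  if (any(a == b)) stop("self-loop in edge list")
  n <- length(ids)
  W <- matrix(0, n, n)
  ia <- match(a, ids); ib <- match(b, ids)
  W[cbind(ia, ib)] <- 1
  W[cbind(ib, ia)] <- 1
  area_graph(W, ids = ids)
}

#' Rook-adjacency rectangular lattice
#'
#' Convenience generator for a regular grid of areas where two cells are
#' neighbours iff they share an edge (rook contiguity). Useful for
#' simulations and as the canvas of the synthetic datasets.
#'
#' @param nrow,ncol grid dimensions, with `nrow * ncol >= 2` (a single row
#'   or column gives a path graph).
#' @return an [area_graph()] with ids `"r<row>c<col>"` in row-major order.
#' @export
make_lattice <- function(nrow, ncol) {
  if (nrow * ncol < 2) stop("lattice needs at least 2 cells")
  idx <- function(r, c) (r - 1L) * ncol + c
  n <- nrow * ncol
  nb <- vector("list", n)
  for (r in seq_len(nrow)) {
    for (c in seq_len(ncol)) {
      i <- idx(r, c)
      v <- integer(0)
      if (r > 1L) v <- c(v, idx(r - 1L, c))
      if (r < nrow) v <- c(v, idx(r + 1L, c))
      if (c > 1L) v <- c(v, idx(r, c - 1L))
      if (c < ncol) v <- c(v, idx(r, c + 1L))
      nb[[i]] <- sort(v)
    }
  }
  ids <- as.vector(t(outer(seq_len(nrow), seq_len(ncol),
                           function(r, c) sprintf("r%dc%d", r, c))))
  area_graph(nb, ids = ids)
}

#' Read and write GAL spatial weights files
#'
#' The GAL dialect written here has a header line with the number of areas
#' (a leading `0` and trailing tokens, as emitted by some GIS tools, are
#' tolerated on read), followed by one pair of lines per area: the area id
#' with its neighbour count, then the neighbour ids.
#'
#' @param path file path.
#' @return `read_gal()` returns an [area_graph()]; `write_gal()` returns
#'   `path` invisibly. A graph round-trips exactly through the pair.
#' @export
read_gal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- if (length(hdr) >= 2L && hdr[1L] == "0") as.integer(hdr[2L]) else as.integer(hdr[1L])
  if (is.na(n) || n < 2L) stop("malformed GAL header")
  ids <- character(n)
  nbids <- vector("list", n)
  ln <- 2L
  for (k in seq_len(n)) {
    rec <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    ids[k] <- rec[1L]
    cnt <- as.integer(rec[2L])
    if (cnt > 0L) {
      nbids[[k]] <- strsplit(trimws(lines[ln + 1L]), "\\s+")[[1L]]
      if (length(nbids[[k]]) != cnt) stop("GAL neighbour count mismatch for area ", ids[k])
      ln <- ln + 2L
    } else {
      nbids[[k]] <- character(0)
      # zero-neighbour records may or may not carry an empty line; ours don't
      ln <- ln + 1L
    }
  }
  nb <- lapply(nbids, function(v) {
    i <- match(v, ids)
    if (anyNA(i)) stop("GAL file references unknown area id(s): ",
                       paste(v[is.na(i)], collapse = ", "))
    sort(i)
  })
  suppressWarnings(area_graph(nb, ids = ids))
}

#' @rdname read_gal
#' @param graph an [area_graph()] to serialise.
#' @export
write_gal <- function(graph, path) {
  out <- character(0)
  out <- c(out, as.character(graph$n))
  for (i in seq_len(graph$n)) {
    k <- length(graph$nb[[i]])
    out <- c(out, paste(graph$ids[i], k))
    if (k > 0L) out <- c(out, paste(graph$ids[graph$nb[[i]]], collapse = " "))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read an edge-list CSV
#'
#' Expects a header and two columns of area labels, one row per undirected
#' edge.
#'
#' @param path CSV file path.
#' @param ids optional full universe of area ids (see [graph_from_edges()]).
#' @return an [area_graph()].
#' @export
read_edgelist <- function(path, ids = NULL) {
  df <- utils::read.csv(path, colClasses = "character")
  graph_from_edges(df[, 1:2], ids = ids)
}

#' Contiguity graph from GeoJSON polygons
#'
#' Derives rook or queen contiguity from polygon geometries in a GeoJSON
#' FeatureCollection. Queen contiguity links two polygons sharing at least
#' one vertex; rook requires a shared edge (two consecutive vertices).
#' Coordinates are matched after rounding to `digits` decimal places.
#'
#' @param path GeoJSON file with Polygon or MultiPolygon features.
#' @param contiguity `"queen"` (default) or `"rook"`.
#' @param id_property feature property to use as the area id; falls back to
#'   the feature index when absent.
#' @param digits coordinate rounding used for vertex matching.
#' @return an [area_graph()].
#' @export
graph_from_geojson <- function(path, contiguity = c("queen", "rook"),
                               id_property = "id", digits = 7) {
  contiguity <- match.arg(contiguity)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  feats <- gj$features
  n <- length(feats)
  ids <- vapply(seq_len(n), function(i) {
    p <- feats[[i]]$properties
    if (!is.null(p[[id_property]])) as.character(p[[id_property]]) else as.character(i)
  }, character(1))

  ring_coords <- function(ring) {
    do.call(rbind, lapply(ring, function(pt) c(as.numeric(pt[[1]]), as.numeric(pt[[2]]))))
  }
  # vertex keys and directed edge keys per feature
  vkeys <- vector("list", n)
  ekeys <- vector("list", n)
  for (i in seq_len(n)) {
    geom <- feats[[i]]$geometry
    rings <- switch(geom$type,
      Polygon = geom$coordinates,
      MultiPolygon = do.call(c, geom$coordinates),
      stop("unsupported geometry type: ", geom$type))
    vk <- character(0); ek <- character(0)
    for (ring in rings) {
      xy <- ring_coords(ring)
      key <- sprintf("%.*f|%.*f", digits, xy[, 1], digits, xy[, 2])
      m <- length(key)
      vk <- c(vk, key)
      if (m >= 2L) {
        a <- key[-m]; b <- key[-1L]
        ek <- c(ek, ifelse(a < b, paste(a, b, sep = "~"), paste(b, a, sep = "~")))
      }
    }
    vkeys[[i]] <- unique(vk)
    ekeys[[i]] <- unique(ek)
  }
  keys <- if (contiguity == "queen") vkeys else ekeys
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (length(intersect(keys[[i]], keys[[j]]))) {
        W[i, j] <- W[j, i] <- 1
      }
    }
  }
  area_graph(W, ids = ids)
}

#' Boundary-crossing distances between areas
#'
#' Graph geodesic distances counted in adjacency steps: \eqn{d_{ij}} is the
#' minimum number of area boundaries that must be crossed to move from area
#' i to area j. This is the lag metric of the areal variogram.
#'
#' @param graph an [area_graph()].
#' @param max_lag maximum lag to resolve; pairs further apart (or in
#'   different components) are reported as `Inf`.
#' @return an N x N matrix of class `boundary_dist`: integer steps, `0` on
#'   the diagonal, `Inf` for pairs not reachable within `max_lag`.
#' @examples
#' d <- boundary_distances(make_lattice(3, 3))
#' d["r1c1", "r3c3"]  # 4 boundary crossings
#' @export
boundary_distances <- function(graph, max_lag = Inf) {
  stopifnot(inherits(graph, "area_graph"), max_lag >= 1)
  n <- graph$n
  d <- matrix(Inf, n, n, dimnames = list(graph$ids, graph$ids))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    lvl <- 0
    while (length(frontier) && lvl < max_lag) {
      lvl <- lvl + 1
      nxt <- unique(unlist(graph$nb[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(dist[nxt])]
      dist[nxt] <- lvl
      frontier <- nxt
    }
    d[s, ] <- dist
  }
  class(d) <- c("boundary_dist", class(d))
  d
}

#' Mean over first-order neighbours
#'
#' For each area, the unweighted mean of `z` over its adjacent areas,
#' \eqn{\bar z(w_i) = \sum_j w_{ij} z_j / \sum_j w_{ij}}. Isolated areas get
#' `NA` with a warning: they carry no neighbourhood information.
#'
#' @param graph an [area_graph()].
#' @param z numeric vector of length `graph$n`.
#' @return numeric vector of neighbour means (`NA` for isolated areas).
#' @export
neighbor_mean <- function(graph, z) {
  stopifnot(inherits(graph, "area_graph"))
  if (length(z) != graph$n) stop("z must have one value per area")
  deg <- area_degree(graph)
  if (all(deg == 0L)) stop("all areas are isolated; neighbour means undefined")
  out <- as.vector(graph$w %*% z) / deg
  if (any(deg == 0L)) {
    out[deg == 0L] <- NA_real_
    warning("isolated area(s) have undefined neighbour mean (NA)")
  }
  names(out) <- graph$ids
  out
}

# Greedy graph colouring: returns an integer colour per area such that no two
# adjacent areas share a colour. Used to vectorise single-site Metropolis
# updates (areas within a colour class are conditionally independent).
graph_coloring <- function(graph) {
  n <- graph$n
  col <- integer(n)
  for (i in order(-area_degree(graph))) {
    used <- col[graph$nb[[i]]]
    k <- 1L
    while (k %in% used) k <- k + 1L
    col[i] <- k
  }
  col
}
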