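#' Wireframe graph of a mesh
#'
#' The routing methods operate on the wireframe graph: the mesh's vertices
#' and edges with Euclidean lengths, plus the rotation system (cyclic order
#' of incident edges around each vertex).  Reconditioning may add parallel
#' copies of edges; copies sit next to their original in the rotation.
#'
#' @param mesh a [wf_mesh], or `NULL` when `positions`/`edges` are given
#'   directly (abstract graph mode, angular rotation fallback).
#' @param positions,edges abstract mode: n x 3 vertex coordinates and an
#'   m x 2 matrix of vertex index pairs.
#' @return an object of class `wf_graph`: `positions`, `edges` (data.frame
#'   `u`, `v`, `len`, `copy`), `rotation` (per-vertex integer vector of edge
#'   ids in cyclic order), `manifold` flag.
#' @export
wireframe_graph <- function(mesh = NULL, positions = NULL, edges = NULL) {
  if (!is.null(mesh)) {
    positions <- mesh$vertices
    edges <- mesh$edges
    top <- analyze_topology(mesh)
    manifold <- isTRUE(top$is_closed_manifold) && isTRUE(top$is_orientable)
    rot_nbrs <- rotation_system(mesh)
  } else {
    positions <- matrix(as.numeric(positions), ncol = 3L)
    edges <- matrix(as.integer(edges), ncol = 2L)
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
    manifold <- FALSE
    rot_nbrs <- rotation_system_angular(positions, edges)
  }
  ed <- data.frame(u = as.integer(edges[, 1L]), v = as.integer(edges[, 2L]))
  ed$len <- sqrt(rowSums((positions[ed$u, , drop = FALSE] -
                            positions[ed$v, , drop = FALSE])^2))
  if (any(ed$len <= 0)) stop("zero-length edge in wireframe", call. = FALSE)
  ed$copy <- 1L
  ekey <- paste(ed$u, ed$v)
  rotation <- lapply(seq_len(nrow(positions)), function(vtx) {
    nbrs <- rot_nbrs[[vtx]]
    match(paste(pmin(vtx, nbrs), pmax(vtx, nbrs)), ekey)
  })
  g <- structure(list(positions = positions, edges = ed,
                      rotation = rotation, manifold = manifold),
                 class = "wf_graph")
  if (!graph_connected(g)) {
    stop("wireframe graph must be connected", call. = FALSE)
  }
  g
}

#' @export
print.wf_graph <- function(x, ...) {
  cat(sprintf("wf_graph: %d vertices, %d edges (%d doubled), manifold rotation=%s\n",
              nrow(x$positions), nrow(x$edges), sum(x$edges$copy > 1L),
              x$manifold))
  invisible(x)
}

graph_igraph <- function(graph, multi = TRUE) {
  ed <- graph$edges
  if (!multi) ed <- ed[ed$copy == 1L, , drop = FALSE]
  g <- igraph::graph_from_edgelist(as.matrix(ed[, c("u", "v")]), directed = FALSE)
  nv <- nrow(graph$positions)
  if (igraph::vcount(g) < nv) g <- igraph::add_vertices(g, nv - igraph::vcount(g))
  igraph::E(g)$weight <- ed$len
  g
}

graph_connected <- function(graph) {
  igraph::is_connected(graph_igraph(graph))
}

graph_degrees <- function(graph) {
  tabulate(c(graph$edges$u, graph$edges$v), nbins = nrow(graph$positions))
}

other_end <- function(graph, eid, vtx) {
  u <- graph$edges$u[eid]
  if (u == vtx) graph$edges$v[eid] else u
}

# --- routes -----------------------------------------------------------------

#' @noRd
# A route is a set of closed walks of directed edge traversals.
# `hairpin` traversals go halfway out along the edge and return to `from`
# (kissing-loop halves); all other traversals run from `from` to the other
# endpoint.
new_route <- function(traversals, method, nick_edge = NA_integer_,
                      extra = list()) {
  tr <- as.data.frame(traversals)
  stopifnot(all(c("edge", "from", "walk") %in% names(tr)))
  if (is.null(tr$tree_edge)) tr$tree_edge <- NA
  if (is.null(tr$kissing_loop)) tr$kissing_loop <- FALSE
  if (is.null(tr$hairpin)) tr$hairpin <- FALSE
  if (is.null(tr$turn)) tr$turn <- NA_character_
  structure(c(list(traversals = tr, method = method, nick_edge = nick_edge),
              extra),
            class = "wf_route")
}

#' @export
print.wf_route <- function(x, ...) {
  tr <- x$traversals
  cat(sprintf("wf_route [%s]: %d traversals in %d walk(s); %d kissing-loop, %d hairpin\n",
              x$method, nrow(tr), length(unique(tr$walk)),
              sum(tr$kissing_loop), sum(tr$hairpin)))
  if (!is.na(x$nick_edge)) cat(sprintf("  nick at edge %d\n", x$nick_edge))
  invisible(x)
}

#' Validate a route against its wireframe graph
#'
#' Checks the structural laws every routing method must satisfy: each walk is
#' closed (consecutive traversals share a vertex, the last connects to the
#' first), and edge coverage matches the method: once per (multi-)edge for
#' A-trails, twice per edge - once in each direction - for the spanning-tree
#' and cycle-cover families (hairpin halves count as one coverage from each
#' endpoint).
#'
#' @param route a `wf_route`.
#' @param graph the `wf_graph` it was computed on.
#' @return a list with `ok`, per-edge `coverage`, and character `problems`.
#' @export
validate_route <- function(route, graph) {
  tr <- route$traversals
  problems <- character(0)
  for (w in unique(tr$walk)) {
    tw <- tr[tr$walk == w, , drop = FALSE]
    cur <- tw$from[1L]
    for (i in seq_len(nrow(tw))) {
      if (tw$from[i] != cur) {
        problems <- c(problems, sprintf("walk %s breaks at traversal %d", w, i))
        break
      }
      cur <- if (tw$hairpin[i]) tw$from[i] else other_end(graph, tw$edge[i], tw$from[i])
    }
    if (cur != tw$from[1L]) {
      problems <- c(problems, sprintf("walk %s is not closed", w))
    }
  }
  cov <- tabulate(tr$edge, nbins = nrow(graph$edges))
  expected <- if (route$method == "at_dna") 1L else 2L
  if (any(cov != expected)) {
    problems <- c(problems, sprintf("%d edge(s) with coverage != %d",
                                    sum(cov != expected), expected))
  }
  # antiparallel check for full (non-hairpin) double coverage
  if (expected == 2L) {
    full <- tr[!tr$hairpin, , drop = FALSE]
    if (nrow(full) > 0L) {
      bad <- vapply(split(full$from, full$edge),
                    function(f) length(f) == 2L && f[1L] == f[2L], logical(1L))
      if (any(bad)) {
        problems <- c(problems, sprintf(
          "%d edge(s) traversed twice in the same direction", sum(bad)))
      }
    }
    hp <- tr[tr$hairpin, , drop = FALSE]
    if (nrow(hp) > 0L) {
      bad <- vapply(split(hp$from, hp$edge),
                    function(f) length(f) != 2L || f[1L] == f[2L], logical(1L))
      if (any(bad)) {
        problems <- c(problems, sprintf(
          "%d kissing-loop edge(s) without one hairpin from each endpoint",
          sum(bad)))
      }
    }
  }
  list(ok = length(problems) == 0L, coverage = cov, problems = problems)
}
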