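#' Maximally branching spanning tree (Prim)
#'
#' Grows a spanning tree from a seed vertex, always attaching the frontier
#' vertex adjacent to the largest number of tree vertices.  This is the
#' maximally branching variant of Prim's algorithm used by the spanning-tree
#' DNA design method; branchier trees keep the scaffold's double traversal
#' compact.  Ties are broken by lowest vertex index, and the connecting edge
#' is the lowest-id edge to the lowest-index tree neighbour.
#'
#' @param graph a [wireframe_graph()].
#' @param seed_vertex index of the starting vertex.
#' @return a `wf_tree`: list with `edge_ids` (tree edges), `cotree_ids`, and
#'   `components` (co-tree connected components as edge-id vectors).
#' @export
prim_max_branching_tree <- function(graph, seed_vertex = 1L) {
  nv <- nrow(graph$positions)
  ed_ids <- which(graph$edges$copy == 1L)
  in_tree <- rep(FALSE, nv)
  in_tree[seed_vertex] <- TRUE
  tree_edges <- integer(0)
  adj <- vector("list", nv)
  for (k in seq_along(ed_ids)) {
    i <- ed_ids[k]
    u <- graph$edges$u[i]; v <- graph$edges$v[i]
    adj[[u]] <- rbind(adj[[u]], c(v, i))
    adj[[v]] <- rbind(adj[[v]], c(u, i))
  }
  for (step in seq_len(nv - 1L)) {
    # frontier score: number of tree vertices adjacent to each outside vertex
    best <- 0L; best_score <- -1L
    for (w in seq_len(nv)) {
      if (in_tree[w] || is.null(adj[[w]])) next
      score <- sum(in_tree[adj[[w]][, 1L]])
      if (score > best_score || (score == best_score && w < best)) {
        if (score > 0L) { best <- w; best_score <- score }
      }
    }
    if (best == 0L) stop("graph is disconnected; no spanning tree", call. = FALSE)
    cand <- adj[[best]]
    cand <- cand[in_tree[cand[, 1L]], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    tree_edges <- c(tree_edges, cand[1L, 2L])
    in_tree[best] <- TRUE
  }
  make_tree(graph, sort(tree_edges))
}

make_tree <- function(graph, edge_ids) {
  all_ids <- which(graph$edges$copy == 1L)
  cotree <- setdiff(all_ids, edge_ids)
  structure(list(edge_ids = edge_ids, cotree_ids = cotree,
                 components = cotree_components(graph, cotree)),
            class = "wf_tree")
}

#' @export
print.wf_tree <- function(x, ...) {
  par <- vapply(x$components, length, integer(1L)) %% 2L
  cat(sprintf("wf_tree: %d tree edges, %d co-tree edges in %d component(s) (%d odd)\n",
              length(x$edge_ids), length(x$cotree_ids),
              length(x$components), sum(par == 1L)))
  invisible(x)
}

# Connected components of the co-tree edge set (edges sharing a vertex are in
# the same component); returned as a list of edge-id vectors.
cotree_components <- function(graph, cotree_ids) {
  if (length(cotree_ids) == 0L) return(list())
  verts <- sort(unique(c(graph$edges$u[cotree_ids], graph$edges$v[cotree_ids])))
  g <- igraph::graph_from_edgelist(
    cbind(match(graph$edges$u[cotree_ids], verts),
          match(graph$edges$v[cotree_ids], verts)),
    directed = FALSE)
  comp <- igraph::components(g)$membership
  split(cotree_ids, comp[match(graph$edges$u[cotree_ids], verts)])
}

odd_component_count <- function(tree) {
  sum(vapply(tree$components, length, integer(1L)) %% 2L == 1L)
}

#' Xuong tree: spanning tree minimising odd co-tree components
#'
#' Each odd-sized co-tree component of the spanning tree forces one kissing
#' loop in the Xuong-tree RNA routing, so the tree sought is the one with
#' the fewest odd components.  For upper-embeddable graphs (all fully
#' triangulated meshes among them) the minimum is 0 or 1, matching the
#' cycle rank's parity, which is always a lower bound.
#'
#' @param graph a [wireframe_graph()].
#' @param mode `"exact"` enumerates every spanning tree (guaranteed minimum;
#'   refuses graphs with more than `budget` trees), `"heuristic"` runs a
#'   tree-edge swap local search from the maximally branching Prim tree and
#'   is never worse than that starting point.
#' @param budget maximum number of spanning trees exact mode will enumerate.
#' @return a `wf_tree` with attribute `odd_components`.
#' @export
xuong_tree <- function(graph, mode = c("heuristic", "exact"), budget = 1e5) {
  mode <- match.arg(mode)
  if (mode == "exact") {
    nt <- count_spanning_trees(graph)
    if (nt > budget) {
      stop(sprintf("graph has %.0f spanning trees (> budget %g); use mode = \"heuristic\"",
                   nt, budget), call. = FALSE)
    }
    best <- NULL; best_odd <- Inf
    for (ids in enumerate_spanning_trees(graph)) {
      tr <- make_tree(graph, ids)
      odd <- odd_component_count(tr)
      if (odd < best_odd) { best <- tr; best_odd <- odd }
      if (best_odd == betti_parity(graph)) break
    }
    attr(best, "odd_components") <- best_odd
    return(best)
  }
  tree <- prim_max_branching_tree(graph)
  best_odd <- odd_component_count(tree)
  lower <- betti_parity(graph)
  repeat {
    if (best_odd <= lower) break
    improved <- FALSE
    for (f in tree$cotree_ids) {
      cyc <- tree_cycle_edges(graph, tree, f)
      for (e in cyc) {
        cand <- make_tree(graph, sort(c(setdiff(tree$edge_ids, e), f)))
        odd <- odd_component_count(cand)
        if (odd < best_odd) {
          tree <- cand; best_odd <- odd; improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  attr(tree, "odd_components") <- best_odd
  tree
}

betti_parity <- function(graph) {
  ne <- sum(graph$edges$copy == 1L)
  (ne - nrow(graph$positions) + 1L) %% 2L
}

# tree edges on the unique cycle closed by co-tree edge f
tree_cycle_edges <- function(graph, tree, f) {
  ed <- graph$edges[tree$edge_ids, , drop = FALSE]
  g <- igraph::graph_from_edgelist(as.matrix(ed[, c("u", "v")]), directed = FALSE)
  nv <- nrow(graph$positions)
  if (igraph::vcount(g) < nv) g <- igraph::add_vertices(g, nv - igraph::vcount(g))
  p <- igraph::shortest_paths(g, graph$edges$u[f], graph$edges$v[f],
                              output = "vpath")$vpath[[1L]]
  p <- as.integer(p)
  ids <- integer(0)
  for (i in seq_len(length(p) - 1L)) {
    a <- min(p[i], p[i + 1L]); b <- max(p[i], p[i + 1L])
    ids <- c(ids, which(graph$edges$u == a & graph$edges$v == b &
                          graph$edges$copy == 1L)[1L])
  }
  ids
}

# Kirchhoff's theorem (determinant of a Laplacian minor)
count_spanning_trees <- function(graph) {
  nv <- nrow(graph$positions)
  ed <- graph$edges[graph$edges$copy == 1L, , drop = FALSE]
  lap <- matrix(0, nv, nv)
  for (i in seq_len(nrow(ed))) {
    u <- ed$u[i]; v <- ed$v[i]
    lap[u, v] <- lap[u, v] - 1; lap[v, u] <- lap[v, u] - 1
    lap[u, u] <- lap[u, u] + 1; lap[v, v] <- lap[v, v] + 1
  }
  round(det(lap[-1L, -1L, drop = FALSE]))
}

# All spanning trees by include/exclude recursion over the edge list, pruning
# branches that can no longer connect the graph.
enumerate_spanning_trees <- function(graph) {
  ids <- which(graph$edges$copy == 1L)
  nv <- nrow(graph$positions)
  out <- list()
  rec <- function(i, chosen, excluded) {
    if (length(chosen) == nv - 1L) {
      out[[length(out) + 1L]] <<- sort(chosen)
      return()
    }
    if (i > length(ids)) return()
    e <- ids[i]
    # include e if it does not close a cycle
    uf_ok <- !same_component(graph, chosen, graph$edges$u[e], graph$edges$v[e])
    if (uf_ok) rec(i + 1L, c(chosen, e), excluded)
    # exclude e if the remaining edges can still span
    rest <- setdiff(ids, c(excluded, e))
    if (spans(graph, rest, nv)) rec(i + 1L, chosen, c(excluded, e))
  }
  rec(1L, integer(0), integer(0))
  out
}

same_component <- function(graph, edge_set, a, b) {
  if (length(edge_set) == 0L) return(FALSE)
  ed <- graph$edges[edge_set, , drop = FALSE]
  g <- igraph::graph_from_edgelist(as.matrix(ed[, c("u", "v")]), directed = FALSE)
  nv <- nrow(graph$positions)
  if (igraph::vcount(g) < nv) g <- igraph::add_vertices(g, nv - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  comp[a] == comp[b]
}

spans <- function(graph, edge_set, nv) {
  if (length(edge_set) < nv - 1L) return(FALSE)
  ed <- graph$edges[edge_set, , drop = FALSE]
  g <- igraph::graph_from_edgelist(as.matrix(ed[, c("u", "v")]), directed = FALSE)
  if (igraph::vcount(g) < nv) g <- igraph::add_vertices(g, nv - igraph::vcount(g))
  igraph::is_connected(g)
}
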