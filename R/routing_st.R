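# Spanning-tree based routes: the scaffold (DNA) or the single RNA strand is
# walked twice around a spanning tree, visiting the co-tree edges from the
# tree tour.  All three variants share the same recursive tree tour; they
# differ only in how a co-tree edge is realised:
#   st_route     - out-and-back spur (both directions of the edge; scaffold
#                  crossover annotation)
#   st_rna_route - two hairpin halves, one from each endpoint, meeting at the
#                  edge midpoint as a 180-degree kissing-loop pair
#   xt_route     - spur duplexes for edges in even co-tree components; one
#                  edge per odd component realised as a kissing-loop pair

tree_tour <- function(graph, tree, cotree_mode, kl_edges = integer(0),
                      root = NULL) {
  in_tree <- logical(nrow(graph$edges))
  in_tree[tree$edge_ids] <- TRUE
  if (is.null(root)) root <- graph$edges$u[tree$edge_ids[1L]]
  rows <- list()
  spur_done <- logical(nrow(graph$edges))
  emit <- function(edge, from, tree_edge, kl = FALSE, hairpin = FALSE) {
    rows[[length(rows) + 1L]] <<- list(edge = edge, from = from,
                                       tree_edge = tree_edge,
                                       kissing_loop = kl, hairpin = hairpin)
  }
  visit <- function(vtx, parent_edge) {
    rot <- graph$rotation[[vtx]]
    ord <- if (is.na(parent_edge)) rot else {
      k <- match(parent_edge, rot)
      rot[c(seq_len(length(rot))[-seq_len(k)], seq_len(k - 1L))]
    }
    for (e in ord) {
      if (in_tree[e]) {
        w <- other_end(graph, e, vtx)
        emit(e, vtx, TRUE)
        visit(w, e)
        emit(e, w, TRUE)
      } else if (cotree_mode == "hairpin" || e %in% kl_edges) {
        emit(e, vtx, FALSE, kl = TRUE, hairpin = TRUE)
      } else {
        if (!spur_done[e]) {
          w <- other_end(graph, e, vtx)
          emit(e, vtx, FALSE)
          emit(e, w, FALSE)
          spur_done[e] <<- TRUE
        }
      }
    }
  }
  visit(root, NA_integer_)
  tr <- do.call(rbind, lapply(rows, as.data.frame))
  tr$walk <- 1L
  tr
}

#' Spanning-tree DNA scaffold route
#'
#' Routes the scaffold strand twice around the spanning tree: every edge of
#' the wireframe is traversed exactly twice, once per direction, in a single
#' closed walk.  Tree edges lie on the boundary walk of the tree; co-tree
#' edges are visited out-and-back and annotated as scaffold-crossover edges
#' (`tree_edge = FALSE`).
#'
#' @param graph a [wireframe_graph()].
#' @param tree a spanning tree from [prim_max_branching_tree()].
#' @return a `wf_route` with one closed walk of `2 * E` traversals.
#' @export
st_route <- function(graph, tree) {
  new_route(tree_tour(graph, tree, "spur"), "st_dna")
}

#' Spanning-tree RNA route with kissing loops
#'
#' A single RNA strand is routed twice around the spanning tree; every
#' co-tree edge is bulged out as two hairpins, one from each endpoint,
#' meeting at the edge midpoint so that the pair can fold as a 180-degree
#' kissing loop.  The strand's single 3'-to-5' nick is placed at the longest
#' wireframe edge.
#'
#' @inheritParams st_route
#' @return a `wf_route`; co-tree traversals are flagged `kissing_loop` and
#'   `hairpin`, `nick_edge` is the longest edge.
#' @export
st_rna_route <- function(graph, tree) {
  new_route(tree_tour(graph, tree, "hairpin"), "st_rna",
            nick_edge = longest_edge(graph))
}

#' Xuong-tree RNA route
#'
#' Same double tree traversal as [st_rna_route()], but co-tree edges in
#' even-sized co-tree components pair into ordinary duplexes; only one edge
#' per odd-sized component must be realised as a kissing loop.  On
#' upper-embeddable graphs (all fully triangulated meshes) this leaves at
#' most one kissing loop in the whole structure.
#'
#' @param graph a [wireframe_graph()].
#' @param tree a tree from [xuong_tree()].
#' @return a `wf_route`; exactly one edge per odd co-tree component is
#'   flagged `kissing_loop`, `nick_edge` is the longest edge.
#' @export
xt_route <- function(graph, tree) {
  kl <- vapply(tree$components, function(comp) {
    if (length(comp) %% 2L == 1L) min(comp) else NA_integer_
  }, integer(1L))
  kl <- kl[!is.na(kl)]
  new_route(tree_tour(graph, tree, "spur", kl_edges = kl), "xt_rna",
            nick_edge = longest_edge(graph))
}

longest_edge <- function(graph) {
  orig <- which(graph$edges$copy == 1L)
  orig[which.max(graph$edges$len[orig])]
}
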