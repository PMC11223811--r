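#' Antiparallel double cycle cover
#'
#' Covers every edge of the wireframe exactly once in each direction by a
#' set of closed directed walks, built bottom-up from strand crossovers at
#' the vertices: at every junction each incoming directed edge is paired to
#' the outgoing edge next in the rotation order, which keeps all arms of the
#' junction connected through a single cyclic transition.  On a mesh this
#' tracing reproduces the face-boundary cycles; on an abstract wireframe the
#' angular-fallback rotation plays the same role, so any connected wireframe
#' can be covered.
#'
#' @param graph a [wireframe_graph()].
#' @return a `wf_route` whose walks are directed cycles; each undirected
#'   edge appears exactly twice, once per direction.
#' @export
cycle_cover <- function(graph) {
  rot <- graph$rotation
  ne <- nrow(graph$edges)
  visited <- matrix(FALSE, ne, 2L)  # column 1: from == u, 2: from == v
  dir_col <- function(e, from) if (graph$edges$u[e] == from) 1L else 2L
  rows <- list()
  walk_id <- 0L
  for (e0 in seq_len(ne)) {
    for (f0 in c(graph$edges$u[e0], graph$edges$v[e0])) {
      if (visited[e0, dir_col(e0, f0)]) next
      walk_id <- walk_id + 1L
      e <- e0; from <- f0
      repeat {
        visited[e, dir_col(e, from)] <- TRUE
        rows[[length(rows) + 1L]] <- list(edge = e, from = from, walk = walk_id)
        w <- other_end(graph, e, from)
        s <- match(e, rot[[w]])
        t <- (s %% length(rot[[w]])) + 1L
        e <- rot[[w]][t]
        from <- w
        if (e == e0 && from == f0) break
      }
    }
  }
  tr <- do.call(rbind, lapply(rows, as.data.frame))
  new_route(tr, "cc_dna")
}
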