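#' Recondition a wireframe to even vertex degrees
#'
#' An Eulerian circuit needs every vertex degree even.  Reconditioning adds
#' parallel copies of existing edges along a minimum-total-length T-join over
#' the odd-degree vertex set: odd vertices are matched pairwise by shortest
#' path distance (exact matching for up to 14 odd vertices, greedy beyond),
#' and each edge on a matched shortest path gains one parallel copy.
#' Original edges are never removed; copies are inserted next to their
#' original in the rotation system.
#'
#' @param graph a [wireframe_graph()].
#' @return the graph with added edge copies (`copy > 1`).
#' @export
recondition <- function(graph) {
  deg <- graph_degrees(graph)
  odd <- which(deg %% 2L == 1L)
  if (length(odd) == 0L) return(graph)
  g <- graph_igraph(graph)
  dm <- igraph::distances(g, v = odd, to = odd)
  pairs <- if (length(odd) <= 14L) {
    match_min_weight(dm)
  } else {
    match_greedy(dm)
  }
  for (p in pairs) {
    a <- odd[p[1L]]; b <- odd[p[2L]]
    path <- as.integer(igraph::shortest_paths(g, a, b, output = "vpath")$vpath[[1L]])
    for (i in seq_len(length(path) - 1L)) {
      graph <- add_edge_copy(graph, path[i], path[i + 1L])
    }
  }
  stopifnot(all(graph_degrees(graph) %% 2L == 0L))
  graph
}

# exact minimum-weight perfect matching by bitmask dynamic programming
match_min_weight <- function(dm) {
  k <- nrow(dm)
  full <- bitwShiftL(1L, k) - 1L
  memo <- rep(NA_real_, full + 1L)
  choice <- rep(NA_integer_, full + 1L)
  memo[1L] <- 0
  solve <- function(mask) {
    if (!is.na(memo[mask + 1L])) return(memo[mask + 1L])
    i <- 0L
    for (b in seq_len(k)) if (bitwAnd(mask, bitwShiftL(1L, b - 1L)) != 0L) { i <- b; break }
    best <- Inf; bestj <- NA_integer_
    for (j in seq_len(k)) {
      if (j == i || bitwAnd(mask, bitwShiftL(1L, j - 1L)) == 0L) next
      rest <- bitwAnd(mask, bitwNot(bitwOr(bitwShiftL(1L, i - 1L), bitwShiftL(1L, j - 1L))))
      rest <- bitwAnd(rest, full)
      val <- dm[i, j] + solve(rest)
      if (val < best) { best <- val; bestj <- j }
    }
    memo[mask + 1L] <<- best
    choice[mask + 1L] <<- bestj
    best
  }
  solve(full)
  pairs <- list()
  mask <- full
  while (mask != 0L) {
    i <- 0L
    for (b in seq_len(k)) if (bitwAnd(mask, bitwShiftL(1L, b - 1L)) != 0L) { i <- b; break }
    j <- choice[mask + 1L]
    pairs[[length(pairs) + 1L]] <- c(i, j)
    mask <- bitwAnd(mask, bitwNot(bitwOr(bitwShiftL(1L, i - 1L), bitwShiftL(1L, j - 1L))))
  }
  pairs
}

match_greedy <- function(dm) {
  k <- nrow(dm)
  left <- seq_len(k)
  pairs <- list()
  while (length(left) > 0L) {
    sub <- dm[left, left, drop = FALSE]
    diag(sub) <- Inf
    ij <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
    pairs[[length(pairs) + 1L]] <- c(left[ij[1L]], left[ij[2L]])
    left <- left[-c(ij[1L], ij[2L])]
  }
  pairs
}

add_edge_copy <- function(graph, a, b) {
  u <- min(a, b); v <- max(a, b)
  orig <- which(graph$edges$u == u & graph$edges$v == v)[1L]
  if (is.na(orig)) stop("T-join path uses a non-edge", call. = FALSE)
  new_id <- nrow(graph$edges) + 1L
  graph$edges <- rbind(graph$edges,
                       data.frame(u = u, v = v, len = graph$edges$len[orig],
                                  copy = sum(graph$edges$u == u & graph$edges$v == v) + 1L))
  for (vtx in c(u, v)) {
    rot <- graph$rotation[[vtx]]
    k <- match(orig, rot)
    graph$rotation[[vtx]] <- append(rot, new_id, after = k)
  }
  graph
}

#' Branch-and-bound A-trail search
#'
#' An A-trail is an Eulerian circuit in which every junction is taken with a
#' sharp turn: the exit edge is an immediate neighbour of the entry edge in
#' the vertex's rotation order.  At a vertex of even degree d the slots of
#' the rotation cycle admit exactly two perfect matchings into adjacent
#' pairs, so the search branches over two transition configurations per
#' vertex (vertices in decreasing degree order) and prunes with a union-find
#' over edges: a configuration that closes a second separate cycle can never
#' yield a single circuit.  On topological spheres the sharp-turn condition
#' guarantees the scaffold route is unknotted; toroidal meshes are searched
#' too, but without that guarantee.
#'
#' @param graph a reconditioned [wireframe_graph()] with a manifold rotation
#'   system (see [recondition()]).
#' @param time_limit seconds before the search gives up.
#' @param allow_nonmanifold run on a non-manifold wireframe using its
#'   angular-fallback rotation system (sharp turns are then defined by that
#'   rotation, with no unknottedness guarantee).
#' @return a `wf_route` (one walk traversing every multi-edge exactly once,
#'   with per-traversal `turn` in `{"L","R"}` and a `vertex_config` element),
#'   or an object of class `wf_atrail_miss` with search statistics when no
#'   A-trail exists or the time limit is hit.
#' @export
atrail_search <- function(graph, time_limit = 10, allow_nonmanifold = FALSE) {
  if (!isTRUE(graph$manifold) && !allow_nonmanifold) {
    stop("A-trail search needs a manifold mesh rotation system", call. = FALSE)
  }
  deg <- graph_degrees(graph)
  if (any(deg %% 2L == 1L)) {
    stop("graph has odd-degree vertices; recondition() it first", call. = FALSE)
  }
  nv <- nrow(graph$positions)
  ne <- nrow(graph$edges)
  rot <- graph$rotation
  vorder <- order(-deg, seq_len(nv))
  # union-find with undo
  parent <- seq_len(ne); size <- rep(1L, ne)
  undo <- list()
  ufind <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  # pairing per vertex per config: list of 2-col matrices of slot indices
  pairings <- lapply(seq_len(nv), function(v) {
    d <- length(rot[[v]])
    a <- matrix(seq_len(d), ncol = 2L, byrow = TRUE)
    b <- matrix(c(seq_len(d)[-1L], 1L), ncol = 2L, byrow = TRUE)
    list(a, b)
  })
  config <- rep(NA_integer_, nv)
  nodes <- 0L
  deadline <- Sys.time() + time_limit
  timed_out <- FALSE
  found <- FALSE
  dfs <- function(i, closed) {
    if (found || timed_out) return()
    nodes <<- nodes + 1L
    if (nodes %% 256L == 0L && Sys.time() > deadline) { timed_out <<- TRUE; return() }
    if (i > nv) {
      if (closed == 1L) found <<- TRUE
      return()
    }
    v <- vorder[i]
    for (cfg in 1:2) {
      pr <- pairings[[v]][[cfg]]
      ops <- 0L; new_closed <- closed; ok <- TRUE
      for (r in seq_len(nrow(pr))) {
        e1 <- ufind(rot[[v]][pr[r, 1L]])
        e2 <- ufind(rot[[v]][pr[r, 2L]])
        if (e1 == e2) {
          new_closed <- new_closed + 1L
          if (new_closed > 1L) { ok <- FALSE; break }
        } else {
          if (size[e1] < size[e2]) { tmp <- e1; e1 <- e2; e2 <- tmp }
          undo[[length(undo) + 1L]] <<- c(e2, size[e1])
          parent[e2] <<- e1
          size[e1] <<- size[e1] + size[e2]
          ops <- ops + 1L
        }
      }
      if (ok) {
        config[v] <<- cfg
        dfs(i + 1L, new_closed)
        if (found) return()
        config[v] <<- NA_integer_
      }
      for (k in seq_len(ops)) {
        op <- undo[[length(undo)]]
        undo[[length(undo)]] <<- NULL
        root <- parent[op[1L]]
        size[root] <<- op[2L]
        parent[op[1L]] <<- op[1L]
      }
    }
  }
  dfs(1L, 0L)
  if (!found) {
    return(structure(list(found = FALSE, nodes_explored = nodes,
                          timed_out = timed_out),
                     class = "wf_atrail_miss"))
  }
  route <- atrail_walk(graph, config)
  route$vertex_config <- config
  route$nodes_explored <- nodes
  route
}

#' @export
print.wf_atrail_miss <- function(x, ...) {
  cat(sprintf("A-trail not found (%s) after %d search nodes\n",
              if (x$timed_out) "time limit" else "exhausted", x$nodes_explored))
  invisible(x)
}

# extract the single Eulerian circuit from a full vertex configuration
atrail_walk <- function(graph, config) {
  rot <- graph$rotation
  pair_of <- lapply(seq_along(rot), function(v) {
    d <- length(rot[[v]])
    p <- integer(d)
    if (d == 0L) return(p)
    if (config[v] == 1L) {
      for (s in seq(1L, d, by = 2L)) { p[s] <- s + 1L; p[s + 1L] <- s }
    } else {
      for (s in seq(2L, d, by = 2L)) {
        nxt <- if (s == d) 1L else s + 1L
        p[s] <- nxt; p[nxt] <- s
      }
    }
    p
  })
  e0 <- 1L
  from0 <- graph$edges$u[e0]
  rows <- list()
  e <- e0; from <- from0
  repeat {
    w <- other_end(graph, e, from)
    s <- match(e, rot[[w]])
    t <- pair_of[[w]][s]
    d <- length(rot[[w]])
    turn <- if (t == (s %% d) + 1L) "R" else "L"
    rows[[length(rows) + 1L]] <- list(edge = e, from = from, turn = turn)
    e2 <- rot[[w]][t]
    if (e2 == e0 && w == from0) break
    e <- e2; from <- w
    if (length(rows) > nrow(graph$edges)) {
      stop("internal error: A-trail walk does not close", call. = FALSE)
    }
  }
  tr <- do.call(rbind, lapply(rows, as.data.frame))
  tr$walk <- 1L
  new_route(tr, "at_dna")
}

#' Import a manually designed A-trail
#'
#' Accepts an externally produced Eulerian circuit (for instance an unknotted
#' trail on a toroidal mesh designed elsewhere) as an ordered edge sequence,
#' validates coverage and closure, and annotates turns.  A circuit that
#' violates the sharp-turn condition at some junction is accepted with a
#' warning, not rejected.
#'
#' @param graph a [wireframe_graph()] (reconditioned if it had odd degrees).
#' @param edge_sequence an m x 2 matrix of vertex pairs in walk order.
#' @return a `wf_route` as from [atrail_search()].
#' @export
import_atrail <- function(graph, edge_sequence) {
  es <- matrix(as.integer(edge_sequence), ncol = 2L)
  ne <- nrow(graph$edges)
  if (nrow(es) != ne) {
    stop(sprintf("sequence has %d edges but the graph has %d", nrow(es), ne),
         call. = FALSE)
  }
  used <- logical(ne)
  ids <- integer(nrow(es))
  for (i in seq_len(nrow(es))) {
    u <- min(es[i, ]); v <- max(es[i, ])
    cand <- which(graph$edges$u == u & graph$edges$v == v & !used)
    if (length(cand) == 0L) {
      stop(sprintf("edge %d-%d missing or over-covered", u, v), call. = FALSE)
    }
    ids[i] <- cand[1L]
    used[cand[1L]] <- TRUE
  }
  # orient the walk
  from <- integer(ne)
  a <- es[1L, ]; b <- es[2L, ]
  shared <- intersect(a, b)[1L]
  if (is.na(shared)) stop("consecutive edges do not share a vertex", call. = FALSE)
  from[1L] <- setdiff(a, shared)[1L]
  if (length(setdiff(a, shared)) == 0L) from[1L] <- shared  # parallel edges
  cur <- other_end(graph, ids[1L], from[1L])
  for (i in 2L:ne) {
    if (!cur %in% es[i, ]) stop("walk breaks at step ", i, call. = FALSE)
    from[i] <- cur
    cur <- other_end(graph, ids[i], cur)
  }
  if (cur != from[1L]) stop("edge sequence is not a closed walk", call. = FALSE)
  # turn annotation
  rot <- graph$rotation
  turn <- rep(NA_character_, ne)
  sharp <- TRUE
  for (i in seq_len(ne)) {
    w <- other_end(graph, ids[i], from[i])
    j <- if (i == ne) 1L else i + 1L
    s <- match(ids[i], rot[[w]])
    t <- match(ids[j], rot[[w]])
    d <- length(rot[[w]])
    if (t == (s %% d) + 1L) turn[i] <- "R"
    else if (s == (t %% d) + 1L) turn[i] <- "L"
    else sharp <- FALSE
  }
  if (!sharp) {
    warning("imported circuit is Eulerian but not sharp-turn at every junction")
  }
  new_route(data.frame(edge = ids, from = from, turn = turn, walk = 1L),
            "at_dna")
}
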