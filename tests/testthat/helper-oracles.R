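# Independent oracles and small abstract graphs used across the suite.
# Every oracle here deliberately uses a different algorithm from the
# implementation it checks.

# --- abstract graphs --------------------------------------------------------

abstract_graph <- function(positions, edges) {
  wireframe_graph(positions = positions, edges = edges)
}

graph_k4 <- function() {
  m <- make_mesh("tetrahedron")
  abstract_graph(m$vertices, m$edges)
}

graph_path <- function(n) {
  pos <- cbind(seq_len(n), 0, 0)
  abstract_graph(pos, cbind(1:(n - 1L), 2:n))
}

graph_cycle <- function(n) {
  ang <- 2 * pi * (0:(n - 1L)) / n
  abstract_graph(cbind(cos(ang), sin(ang), 0),
                 cbind(1:n, c(2:n, 1L)))
}

# wheel: hub vertex 1, outer cycle 2..n+1
graph_wheel <- function(n_outer) {
  ang <- 2 * pi * (0:(n_outer - 1L)) / n_outer
  pos <- rbind(c(0, 0, 0), cbind(cos(ang), sin(ang), 0))
  outer <- 2:(n_outer + 1L)
  edges <- rbind(cbind(1L, outer),
                 cbind(outer, c(outer[-1L], outer[1L])))
  abstract_graph(pos, edges)
}

# two triangles sharing one edge (2-3): vertices 1..4
graph_two_triangles_edge <- function() {
  pos <- rbind(c(0, 0, 0), c(1, 1, 0), c(1, -1, 0), c(2, 0, 0))
  abstract_graph(pos, rbind(c(1, 2), c(1, 3), c(2, 3), c(2, 4), c(3, 4)))
}

# two triangles sharing one vertex (bowtie, cut vertex 3 of degree 4)
graph_bowtie <- function() {
  pos <- rbind(c(-2, 1, 0), c(-2, -1, 0), c(0, 0, 0), c(2, 1, 0), c(2, -1, 0))
  abstract_graph(pos, rbind(c(1, 2), c(1, 3), c(2, 3), c(3, 4), c(3, 5), c(4, 5)))
}

# --- Eulerian / A-trail oracle ---------------------------------------------

# Backtracking search for an Eulerian circuit; when sharp = TRUE the next
# edge must be an immediate rotation neighbour of the entry edge.  Returns
# the first circuit found (list of edge ids with from-vertices) or NULL.
oracle_euler_trail <- function(graph, sharp = TRUE) {
  ne <- nrow(graph$edges)
  rot <- graph$rotation
  used <- logical(ne)
  path_e <- integer(ne)
  path_f <- integer(ne)
  start_e <- 1L
  start_v <- graph$edges$u[1L]
  found <- NULL
  rec <- function(depth, e, from) {
    if (!is.null(found)) return()
    used[e] <<- TRUE
    path_e[depth] <<- e
    path_f[depth] <<- from
    w <- other_end_oracle(graph, e, from)
    if (depth == ne) {
      if (w == start_v) {
        if (!sharp || sharp_ok(graph, path_e, path_f)) {
          found <<- list(edge = path_e, from = path_f)
        }
      }
    } else {
      cand <- if (sharp) {
        s <- match(e, rot[[w]])
        d <- length(rot[[w]])
        rot[[w]][c((s %% d) + 1L, ((s - 2L) %% d) + 1L)]
      } else rot[[w]]
      for (e2 in unique(cand)) {
        if (!used[e2]) rec(depth + 1L, e2, w)
      }
    }
    used[e] <<- FALSE
  }
  rec(1L, start_e, start_v)
  found
}

other_end_oracle <- function(graph, e, v) {
  u <- graph$edges$u[e]
  if (u == v) graph$edges$v[e] else u
}

# sharpness of a complete closed trail, checked from scratch
sharp_ok <- function(graph, edges, froms) {
  n <- length(edges)
  for (i in seq_len(n)) {
    w <- other_end_oracle(graph, edges[i], froms[i])
    j <- if (i == n) 1L else i + 1L
    rot <- graph$rotation[[w]]
    s <- match(edges[i], rot)
    t <- match(edges[j], rot)
    d <- length(rot)
    if (!(t == (s %% d) + 1L || s == (t %% d) + 1L)) return(FALSE)
  }
  TRUE
}

# --- spanning trees ---------------------------------------------------------

# enumerate spanning trees by brute force over edge subsets (combn), check
# acyclic + spanning with a simple union-find
oracle_spanning_trees <- function(graph) {
  ids <- which(graph$edges$copy == 1L)
  nv <- nrow(graph$positions)
  out <- list()
  for (sel in utils::combn(ids, nv - 1L, simplify = FALSE)) {
    parent <- seq_len(nv)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    ok <- TRUE
    for (e in sel) {
      a <- find(graph$edges$u[e]); b <- find(graph$edges$v[e])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) out[[length(out) + 1L]] <- sel
  }
  out
}

# odd co-tree components counted independently (union-find over co-tree)
oracle_odd_components <- function(graph, tree_ids) {
  ids <- setdiff(which(graph$edges$copy == 1L), tree_ids)
  if (length(ids) == 0L) return(0L)
  nv <- nrow(graph$positions)
  parent <- seq_len(nv)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in ids) parent[find(graph$edges$u[e])] <- find(graph$edges$v[e])
  comp <- vapply(ids, function(e) find(graph$edges$u[e]), integer(1L))
  sum(table(comp) %% 2L == 1L)
}

oracle_min_odd_components <- function(graph) {
  min(vapply(oracle_spanning_trees(graph),
             function(t) oracle_odd_components(graph, t), integer(1L)))
}

# --- longest repeated substring --------------------------------------------

# suffix-sort oracle: pool all suffixes of all strands, sort, the answer is
# the maximum common-prefix length of adjacent sorted suffixes
oracle_lrs <- function(strands) {
  suf <- unlist(lapply(strands, function(s) {
    n <- nchar(s)
    if (n == 0L) return(character(0))
    substring(s, 1:n, n)
  }))
  if (length(suf) < 2L) return(0L)
  suf <- sort(suf, method = "radix")
  best <- 0L
  for (i in seq_len(length(suf) - 1L)) {
    a <- charToRaw(suf[i]); b <- charToRaw(suf[i + 1L])
    k <- min(length(a), length(b))
    if (k <= best) next
    neq <- which(a[seq_len(k)] != b[seq_len(k)])
    lcp <- if (length(neq) == 0L) k else neq[1L] - 1L
    if (lcp > best) best <- lcp
  }
  best
}

# --- misc -------------------------------------------------------------------

rotation_mat <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# randomly displace/rotate every cylinder of a model (for relax tests)
perturb_model <- function(model, sd = 1, seed = 1L) {
  set.seed(seed)
  for (i in seq_along(model$cylinders)) {
    cyl <- model$cylinders[[i]]
    tf <- cyl$transform
    tf[1:3, 4L] <- tf[1:3, 4L] + stats::rnorm(3, sd = sd)
    R <- rotation_mat(stats::rnorm(3), stats::rnorm(1, sd = 0.2))
    tf[1:3, 1:3] <- R %*% tf[1:3, 1:3]
    model$cylinders[[i]]$transform <- tf
    local_pts <- wirefold:::port_local(cyl$bp_count, model$geom)
    model$cylinders[[i]]$conn <- wirefold:::apply_transform(tf, local_pts)
    rownames(model$cylinders[[i]]$conn) <- c("first5", "first3", "second5", "second3")
  }
  model
}

tetra_obj_text <- function() {
  write_obj(make_mesh("tetrahedron"))
}
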