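#' Polygon surface meshes
#'
#' A `wf_mesh` stores the vertices and ordered face rings of a polygon mesh,
#' together with its derived edge set.  Meshes are the geometric input to
#' every design method: their edges become double helices, their faces (when
#' present) define the rotation system that makes "sharp turns" at junctions
#' well defined.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mesh units;
#'   conversion to nanometres happens later, via the design scale).
#' @param faces list of integer vectors, each an ordered ring of vertex
#'   indices (1-based).  Winding order is preserved as given.
#' @param merge_epsilon if not `NULL`, vertices closer than this distance are
#'   welded into one.  Off by default: welding can silently change topology.
#' @return an object of class `wf_mesh` with elements `vertices`, `faces`,
#'   `edges` (m x 2 matrix, each row an unordered pair with `u < v`).
#' @export
wf_mesh <- function(vertices, faces, merge_epsilon = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3L)
  faces <- lapply(faces, as.integer)
  if (!is.null(merge_epsilon)) {
    merged <- weld_vertices(vertices, faces, merge_epsilon)
    vertices <- merged$vertices
    faces <- merged$faces
  }
  nv <- nrow(vertices)
  for (f in faces) {
    if (length(f) < 3L || anyDuplicated(f)) {
      stop("every face needs at least 3 distinct vertices", call. = FALSE)
    }
    if (any(f < 1L | f > nv)) {
      stop("face vertex index out of range", call. = FALSE)
    }
  }
  structure(
    list(vertices = vertices, faces = faces, edges = derive_edges(faces)),
    class = "wf_mesh"
  )
}

derive_edges <- function(faces) {
  if (length(faces) == 0L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("u", "v"))))
  }
  pairs <- do.call(rbind, lapply(faces, function(f) {
    cbind(f, c(f[-1L], f[1L]))
  }))
  und <- cbind(u = pmin(pairs[, 1L], pairs[, 2L]),
               v = pmax(pairs[, 1L], pairs[, 2L]))
  und <- unique(und)
  und[order(und[, 1L], und[, 2L]), , drop = FALSE]
}

weld_vertices <- function(vertices, faces, eps) {
  nv <- nrow(vertices)
  map <- seq_len(nv)
  for (i in seq_len(nv)) {
    if (map[i] != i) next
    if (i < nv) {
      later <- (i + 1L):nv
      d2 <- rowSums((vertices[later, , drop = FALSE] -
                       matrix(vertices[i, ], length(later), 3L, byrow = TRUE))^2)
      map[later[d2 <= eps^2 & map[later] == later]] <- i
    }
  }
  keep <- which(map == seq_len(nv))
  newid <- integer(nv)
  newid[keep] <- seq_along(keep)
  list(vertices = vertices[keep, , drop = FALSE],
       faces = lapply(faces, function(f) newid[map[f]]))
}

#' @export
print.wf_mesh <- function(x, ...) {
  cat(sprintf("wf_mesh: %d vertices, %d edges, %d faces\n",
              nrow(x$vertices), nrow(x$edges), length(x$faces)))
  invisible(x)
}

#' Read a Wavefront OBJ document
#'
#' Accepts `v` and `f` records; `vn`, `vt`, `o`, `g`, `s`, `usemtl`, `mtllib`
#' and comments are skipped silently (files exported from Blender or Maya
#' routinely carry them).  `f v/t/n` triplets are reduced to the vertex
#' field; OBJ 1-based and negative (relative) indices are both accepted.
#'
#' @param text a character scalar (whole document) or vector of lines, or a
#'   file path if `is_path = TRUE`.
#' @param is_path read `text` as a file path.
#' @inheritParams wf_mesh
#' @return a [wf_mesh].
#' @export
parse_obj <- function(text, is_path = FALSE, merge_epsilon = NULL) {
  lines <- if (is_path) readLines(text, warn = FALSE) else
    unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  verts <- list()
  faces <- list()
  for (ln in lines) {
    tok <- strsplit(ln, "[ \t]+")[[1L]]
    key <- tok[1L]
    if (key == "v") {
      if (length(tok) < 4L) stop("malformed vertex record: ", ln, call. = FALSE)
      verts[[length(verts) + 1L]] <- as.numeric(tok[2:4])
    } else if (key == "f") {
      idx <- vapply(tok[-1L], function(t) {
        as.integer(strsplit(t, "/", fixed = TRUE)[[1L]][1L])
      }, integer(1L), USE.NAMES = FALSE)
      if (length(idx) < 3L) {
        stop("face with fewer than 3 vertices: ", ln, call. = FALSE)
      }
      # negative OBJ indices count back from the vertices seen so far
      idx <- ifelse(idx < 0L, length(verts) + idx + 1L, idx)
      if (any(idx < 1L | idx > length(verts))) {
        stop("face vertex index out of range: ", ln, call. = FALSE)
      }
      faces[[length(faces) + 1L]] <- idx
    }
    # every other record type is ignored
  }
  if (length(verts) == 0L || length(faces) == 0L) {
    stop("OBJ document must contain at least one `v` and one `f` record",
         call. = FALSE)
  }
  wf_mesh(do.call(rbind, verts), faces, merge_epsilon = merge_epsilon)
}

#' Write a mesh as Wavefront OBJ text
#'
#' @param mesh a [wf_mesh].
#' @param path optional file path; when `NULL` the OBJ text is returned.
#' @return the OBJ document as a character scalar (invisibly when written to
#'   a file).  Vertex indices are converted back to OBJ's 1-based convention.
#' @export
write_obj <- function(mesh, path = NULL) {
  vl <- sprintf("v %.6f %.6f %.6f",
                mesh$vertices[, 1L], mesh$vertices[, 2L], mesh$vertices[, 3L])
  fl <- vapply(mesh$faces, function(f) paste("f", paste(f, collapse = " ")),
               character(1L))
  txt <- paste(c(vl, fl, ""), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(c(vl, fl), path)
  invisible(txt)
}

#' Topological analysis of a mesh
#'
#' Classifies the mesh surface: closed 2-manifold (every edge shared by
#' exactly two faces, every vertex star a single fan), orientability
#' (consistent winding: each directed edge used at most once), connectivity,
#' and - for closed orientable manifolds - the genus from the Euler
#' characteristic V - E + F = 2 - 2g.
#'
#' @param mesh a [wf_mesh].
#' @return a list of class `wf_topology` with flags `is_closed_manifold`,
#'   `is_orientable`, `connected`, integer `genus` (`NA` unless closed,
#'   orientable and connected) and `odd_degree_vertex_count` over the edge
#'   graph.
#' @export
analyze_topology <- function(mesh) {
  nv <- nrow(mesh$vertices)
  ne <- nrow(mesh$edges)
  nf <- length(mesh$faces)
  dir_edges <- do.call(rbind, lapply(mesh$faces, function(f) {
    cbind(f, c(f[-1L], f[1L]))
  }))
  dkey <- paste(dir_edges[, 1L], dir_edges[, 2L])
  ukey <- paste(pmin(dir_edges[, 1L], dir_edges[, 2L]),
                pmax(dir_edges[, 1L], dir_edges[, 2L]))
  per_edge <- table(ukey)
  orientable <- !anyDuplicated(dkey)
  closed <- all(per_edge == 2L)
  g <- igraph::graph_from_edgelist(mesh$edges, directed = FALSE)
  if (igraph::vcount(g) < nv) g <- igraph::add_vertices(g, nv - igraph::vcount(g))
  connected <- igraph::is_connected(g)
  manifold <- closed && vertex_stars_are_disks(mesh)
  genus <- NA_integer_
  if (manifold && orientable && connected) {
    chi <- nv - ne + nf
    if ((2L - chi) %% 2L == 0L && chi <= 2L) genus <- (2L - chi) %/% 2L
  }
  deg <- igraph::degree(g)
  structure(
    list(is_closed_manifold = manifold,
         is_orientable = orientable,
         connected = connected,
         genus = genus,
         odd_degree_vertex_count = sum(deg %% 2L == 1L)),
    class = "wf_topology"
  )
}

#' @export
print.wf_topology <- function(x, ...) {
  cat(sprintf(
    "wf_topology: closed manifold=%s orientable=%s connected=%s genus=%s odd-degree vertices=%d\n",
    x$is_closed_manifold, x$is_orientable, x$connected,
    ifelse(is.na(x$genus), "NA", x$genus), x$odd_degree_vertex_count))
  invisible(x)
}

# For each vertex, walking the face corners around it must form one closed
# fan; otherwise the star is pinched (bowtie vertex) or has a boundary.
vertex_stars_are_disks <- function(mesh) {
  succ <- succ_maps(mesh)
  for (v in seq_len(nrow(mesh$vertices))) {
    sv <- succ[[v]]
    if (length(sv) == 0L) return(FALSE)
    nbrs <- as.integer(names(sv))
    if (anyDuplicated(names(sv))) return(FALSE)
    start <- nbrs[1L]
    cur <- start
    seen <- 0L
    repeat {
      nxt <- sv[[as.character(cur)]]
      if (is.null(nxt)) return(FALSE)
      seen <- seen + 1L
      cur <- nxt
      if (cur == start) break
      if (seen > length(nbrs)) return(FALSE)
    }
    if (seen != length(nbrs)) return(FALSE)
  }
  TRUE
}

# succ[[v]][[as.character(a)]] = b when some face runs ... a, v, b ...
succ_maps <- function(mesh) {
  nv <- nrow(mesh$vertices)
  succ <- vector("list", nv)
  for (i in seq_len(nv)) succ[[i]] <- list()
  for (f in mesh$faces) {
    k <- length(f)
    for (i in seq_len(k)) {
      a <- f[if (i == 1L) k else i - 1L]
      v <- f[i]
      b <- f[if (i == k) 1L else i + 1L]
      succ[[v]][[as.character(a)]] <- b
    }
  }
  succ
}

#' Rotation system of a mesh
#'
#' The rotation system gives, for every vertex, the cyclic order of its
#' incident edges around the vertex.  On a closed orientable manifold mesh it
#' is induced by face adjacency (walk the fan of faces around the vertex),
#' which is what makes the "sharp left / sharp right" turns of A-trail
#' routing well defined.  For non-manifold wireframes the order falls back to
#' the angular order of edge directions projected on the vertex's estimated
#' normal plane.
#'
#' @param mesh a [wf_mesh].
#' @return a list, one integer vector per vertex: the neighbouring vertex
#'   indices in cyclic order.
#' @export
rotation_system <- function(mesh) {
  d <- mesh$vertices[mesh$edges[, 1L], , drop = FALSE] -
    mesh$vertices[mesh$edges[, 2L], , drop = FALSE]
  if (any(rowSums(d * d) < 1e-24)) {
    stop("mesh contains a zero-length edge", call. = FALSE)
  }
  top <- analyze_topology(mesh)
  if (top$is_closed_manifold && top$is_orientable) {
    succ <- succ_maps(mesh)
    lapply(seq_len(nrow(mesh$vertices)), function(v) {
      sv <- succ[[v]]
      nbrs <- as.integer(names(sv))
      out <- integer(length(nbrs))
      cur <- min(nbrs)
      for (i in seq_along(out)) {
        out[i] <- cur
        cur <- sv[[as.character(cur)]]
      }
      out
    })
  } else {
    rotation_system_angular(mesh$vertices, mesh$edges)
  }
}

# Angular fallback: project incident edge directions on the plane orthogonal
# to the star's least-variance axis and sort by angle.
rotation_system_angular <- function(vertices, edges) {
  nv <- nrow(vertices)
  adj <- vector("list", nv)
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1L]; v <- edges[i, 2L]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  lapply(seq_len(nv), function(v) {
    nbrs <- sort(unique(adj[[v]]))
    if (length(nbrs) <= 2L) return(nbrs)
    dirs <- vertices[nbrs, , drop = FALSE] -
      matrix(vertices[v, ], length(nbrs), 3L, byrow = TRUE)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    ev <- eigen(crossprod(dirs), symmetric = TRUE)
    normal <- ev$vectors[, 3L]
    # deterministic sign
    s <- sign(normal[which.max(abs(normal))])
    if (s < 0) normal <- -normal
    fr <- frame_from_axis(normal)
    ang <- atan2(dirs %*% fr[, "z"], dirs %*% fr[, "x"])
    ord <- order(ang, nbrs)
    out <- nbrs[ord]
    # canonical start: lowest neighbour index first
    k <- which.min(out)
    c(out[k:length(out)], out[seq_len(k - 1L)])
  })
}
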