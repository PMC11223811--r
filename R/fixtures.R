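#' Canonical test meshes
#'
#' Generates the package's reference meshes programmatically: the four
#' Platonic solids used throughout the documentation and tests, a triangular
#' prism, and a quad-grid torus.  All Platonic solids have unit circumradius;
#' the torus has major radius 2 and minor radius 0.7 (mesh units).  Every
#' fixture is a closed orientable manifold with consistent outward-facing
#' winding, so its genus and rotation system are well defined.
#'
#' @param shape one of `"tetrahedron"`, `"cube"`, `"octahedron"`,
#'   `"icosahedron"`, `"prism"`, `"torus"`.
#' @param scale multiplies all coordinates (mesh units stay arbitrary; the
#'   nm conversion belongs to the design scale parameter).
#' @param m,n torus only: number of segments around the major / minor
#'   circle (both at least 3).
#' @return a [wf_mesh].
#' @examples
#' m <- make_mesh("octahedron")
#' analyze_topology(m)
#' @export
make_mesh <- function(shape = c("tetrahedron", "cube", "octahedron",
                                "icosahedron", "prism", "torus"),
                      scale = 1, m = 4L, n = 4L) {
  shape <- match.arg(shape)
  spec <- switch(shape,
    tetrahedron = fixture_tetrahedron(),
    cube = fixture_cube(),
    octahedron = fixture_octahedron(),
    icosahedron = fixture_icosahedron(),
    prism = fixture_prism(),
    torus = fixture_torus(m, n)
  )
  mesh <- wf_mesh(spec$vertices * scale, orient_faces(spec$vertices, spec$faces))
  mesh
}

fixture_tetrahedron <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  f <- list(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  list(vertices = v, faces = f)
}

fixture_cube <- function() {
  v <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
             c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1)) / sqrt(3)
  f <- list(c(1, 4, 3, 2), c(5, 6, 7, 8), c(1, 2, 6, 5),
            c(2, 3, 7, 6), c(3, 4, 8, 7), c(4, 1, 5, 8))
  list(vertices = v, faces = f)
}

fixture_octahedron <- function() {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
             c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  f <- list(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
            c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  list(vertices = v, faces = f)
}

fixture_icosahedron <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
    c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  v <- v / sqrt(1 + p^2)
  f <- list(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

fixture_prism <- function() {
  h <- 0.5
  r <- sqrt(1 - h^2)
  ang <- pi / 2 + c(0, 1, 2) * 2 * pi / 3
  bot <- cbind(r * cos(ang), r * sin(ang), -h)
  top <- cbind(r * cos(ang), r * sin(ang), h)
  v <- rbind(bot, top)
  f <- list(c(1, 2, 3), c(4, 5, 6),
            c(1, 2, 5, 4), c(2, 3, 6, 5), c(3, 1, 4, 6))
  list(vertices = v, faces = f)
}

fixture_torus <- function(m, n, major = 2, minor = 0.7) {
  m <- as.integer(m); n <- as.integer(n)
  if (m < 3L || n < 3L) {
    stop("torus needs at least 3 segments around each circle", call. = FALSE)
  }
  id <- function(i, j) ((i %% m)) * n + (j %% n) + 1L
  v <- matrix(0, m * n, 3L)
  for (i in 0:(m - 1L)) {
    th <- 2 * pi * i / m
    for (j in 0:(n - 1L)) {
      ph <- 2 * pi * j / n
      v[id(i, j), ] <- c((major + minor * cos(ph)) * cos(th),
                         (major + minor * cos(ph)) * sin(th),
                         minor * sin(ph))
    }
  }
  f <- list()
  for (i in 0:(m - 1L)) {
    for (j in 0:(n - 1L)) {
      f[[length(f) + 1L]] <- c(id(i, j), id(i + 1L, j),
                               id(i + 1L, j + 1L), id(i, j + 1L))
    }
  }
  list(vertices = v, faces = f)
}

# Make face windings mutually consistent (BFS over the face adjacency,
# flipping rings whose shared edge runs in the same direction as an already
# oriented neighbour), then outward (positive signed volume).  Works on any
# closed orientable surface given with arbitrary per-face winding.
orient_faces <- function(vertices, faces) {
  nf <- length(faces)
  if (nf == 0L) return(faces)
  edge_faces <- list()
  for (fi in seq_len(nf)) {
    f <- faces[[fi]]
    for (k in seq_along(f)) {
      a <- f[k]; b <- f[if (k == length(f)) 1L else k + 1L]
      key <- paste(min(a, b), max(a, b))
      edge_faces[[key]] <- c(edge_faces[[key]], fi)
    }
  }
  flipped <- rep(FALSE, nf)
  visited <- rep(FALSE, nf)
  dir_in_face <- function(fi, a, b) {
    f <- faces[[fi]]
    if (flipped[fi]) f <- rev(f)
    k <- match(a, f)
    f[if (k == length(f)) 1L else k + 1L] == b
  }
  queue <- 1L
  visited[1L] <- TRUE
  while (length(queue) > 0L) {
    fi <- queue[1L]; queue <- queue[-1L]
    f <- faces[[fi]]
    if (flipped[fi]) f <- rev(f)
    for (k in seq_along(f)) {
      a <- f[k]; b <- f[if (k == length(f)) 1L else k + 1L]
      key <- paste(min(a, b), max(a, b))
      for (fj in edge_faces[[key]]) {
        if (fj == fi || visited[fj]) next
        # consistent orientation: fj must traverse the shared edge b -> a
        if (dir_in_face(fj, a, b)) flipped[fj] <- TRUE
        visited[fj] <- TRUE
        queue <- c(queue, fj)
      }
    }
  }
  out <- lapply(seq_len(nf), function(i) {
    if (flipped[i]) rev(faces[[i]]) else faces[[i]]
  })
  vol <- 0
  for (f in out) {
    for (k in 2:(length(f) - 1L)) {
      p1 <- vertices[f[1L], ]; p2 <- vertices[f[k], ]; p3 <- vertices[f[k + 1L], ]
      vol <- vol + sum(p1 * vcross(p2, p3)) / 6
    }
  }
  if (vol < 0) out <- lapply(out, rev)
  out
}
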