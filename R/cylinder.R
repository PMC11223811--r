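#' Helix geometry constants
#'
#' Geometric constants of the double helix used by the cylinder and
#' nucleotide models.  The diameter is 2.0 nm for DNA (B-form) and 2.3 nm
#' for RNA (A-form); rise and bases per turn default to the standard B-/A-
#' form values consistent with those diameters (DNA 0.332 nm/bp at 10.5
#' bp/turn, RNA 0.281 nm/bp at 11.0 bp/turn).  The minor-groove angular
#' offset between paired backbones is 120 degrees for DNA and 139 for RNA.
#' All values are configurable.
#'
#' @param nucleic_acid `"DNA"` or `"RNA"`.
#' @param diameter,rise_per_bp,bp_per_turn,groove_offset override defaults
#'   (nm, nm/bp, bp, degrees).
#' @return a list of class `wf_helix_geometry`; `twist_per_bp` (degrees) is
#'   derived as 360 / `bp_per_turn`.
#' @export
helix_geometry <- function(nucleic_acid = c("DNA", "RNA"),
                           diameter = NULL, rise_per_bp = NULL,
                           bp_per_turn = NULL, groove_offset = NULL) {
  nucleic_acid <- match.arg(nucleic_acid)
  def <- if (nucleic_acid == "DNA") {
    list(diameter = 2.0, rise_per_bp = 0.332, bp_per_turn = 10.5,
         groove_offset = 120)
  } else {
    list(diameter = 2.3, rise_per_bp = 0.281, bp_per_turn = 11.0,
         groove_offset = 139)
  }
  g <- list(nucleic_acid = nucleic_acid,
            diameter = diameter %||% def$diameter,
            rise_per_bp = rise_per_bp %||% def$rise_per_bp,
            bp_per_turn = bp_per_turn %||% def$bp_per_turn,
            groove_offset = groove_offset %||% def$groove_offset)
  g$twist_per_bp <- 360 / g$bp_per_turn
  structure(g, class = "wf_helix_geometry")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Design parameters
#'
#' @param method one of `"at_dna"`, `"st_dna"`, `"cc_dna"`, `"st_rna"`,
#'   `"xt_rna"`.
#' @param scale nanometres per mesh length unit (an edge of mesh length 1 at
#'   scale 1 becomes a 1 nm cylinder).
#' @param min_overlap minimum binding-domain length (nt) a nick may leave.
#' @param min_bp smallest base-pair count a cylinder may carry before the
#'   scale is rejected as too small.
#' @param linker_policy fixed linker base (`"T"`/`"U"`) or `"N"` to leave
#'   linkers free for sequence design.
#' @param linker_count fixed number of linker nucleotides per connection, or
#'   `NA` to derive it from the connection gap (round(gap / 0.6 nm) - 1,
#'   capped at 5).
#' @param gc_bounds length-2 GC-fraction bounds for designed strands.
#' @param forbidden_subsequences character vector of prohibited subsequences.
#' @param seed integer seed for all stochastic steps.
#' @param relax logical: run cylinder relaxation.
#' @param relax_iterations,relax_dt spring relaxation settings.
#' @return a list of class `wf_design_parameters`.
#' @export
design_parameters <- function(method = c("at_dna", "st_dna", "cc_dna",
                                         "st_rna", "xt_rna"),
                              scale = 10, min_overlap = 8L, min_bp = 1L,
                              linker_policy = NULL, linker_count = NA_integer_,
                              gc_bounds = c(0.3, 0.7),
                              forbidden_subsequences = character(0),
                              seed = 1L, relax = FALSE,
                              relax_iterations = 500L, relax_dt = 0.01) {
  method <- match.arg(method)
  stopifnot(scale > 0, min_overlap >= 1)
  rna <- method %in% c("st_rna", "xt_rna")
  structure(list(method = method, scale = scale,
                 min_overlap = as.integer(min_overlap),
                 min_bp = as.integer(min_bp),
                 linker_policy = linker_policy %||% (if (rna) "U" else "T"),
                 linker_count = linker_count,
                 gc_bounds = gc_bounds,
                 forbidden_subsequences = toupper(forbidden_subsequences),
                 seed = as.integer(seed), relax = relax,
                 relax_iterations = as.integer(relax_iterations),
                 relax_dt = relax_dt),
            class = "wf_design_parameters")
}

#' Round a helix length to whole turns
#'
#' The spanning-tree DNA method rounds each helix to an integer number of
#' turns so its stapling pattern lines up.  Rounding is half-down on the
#' turn count and on the resulting base count, never below one full turn.
#'
#' @param bp_count integer base-pair count.
#' @param geom a [helix_geometry()].
#' @return integer base-pair count at a whole number of turns.
#' @export
round_to_turns <- function(bp_count, geom) {
  stopifnot(bp_count >= 1)
  half_down <- function(x) as.integer(ceiling(x - 0.5))
  turns <- max(1L, half_down(bp_count / geom$bp_per_turn))
  half_down(turns * geom$bp_per_turn)
}

# template (cylinder-local) nucleotide positions of one strand pass.
# strand 1 runs 5'->3' along +Y; strand 2 antiparallel (its nt j pairs
# strand 1 nt bp-j-1).  Backbones sit at 0.9 x radius, the paired backbone
# offset by the minor-groove angle.
template_strand_positions <- function(bp, geom, strand) {
  rb <- 0.9 * geom$diameter / 2
  tw <- geom$twist_per_bp * pi / 180
  gro <- geom$groove_offset * pi / 180
  i <- if (strand == 1L) 0:(bp - 1L) else (bp - 1L):0
  theta <- i * tw + if (strand == 2L) gro else 0
  cbind(rb * cos(theta), i * geom$rise_per_bp, rb * sin(theta))
}

port_local <- function(bp, geom) {
  s1 <- template_strand_positions(bp, geom, 1L)
  s2 <- template_strand_positions(bp, geom, 2L)
  rbind(first5 = s1[1L, ], first3 = s1[bp, ],
        second5 = s2[1L, ], second3 = s2[bp, ])
}

#' Build the cylinder model of a route
#'
#' Converts the routing model into positioned double-helix cylinders.  Each
#' duplex segment of the route becomes one cylinder: for A-trail and
#' spanning-tree DNA every scaffold traversal is its own duplex (spanning
#' tree edges therefore carry a two-helix bundle, offset laterally), while
#' the cycle-cover and RNA methods pair the two antiparallel passes of an
#' edge into a single duplex.  Nominal cylinder length is edge length times
#' the scale, shortened at each end by the vertex clearance
#' d = radius / tan(alpha/2) (alpha the smallest angle to a neighbouring
#' edge) so that helices meeting at a junction do not overlap;
#' `bp_count = floor(usable length / rise)`.  Spanning-tree DNA lengths are
#' then rounded to whole turns.
#'
#' @param route a `wf_route`.
#' @param graph the `wf_graph` the route was computed on.
#' @param params a [design_parameters()].
#' @param geom a [helix_geometry()]; defaults to the method's nucleic acid.
#' @return a `wf_cylinder_model`: cylinders (each with a 4 x 4 `transform`,
#'   `length`, `bp_count`, `radius`, world-space connection points and
#'   flags), symmetric `links` between connection ports, and the traversal
#'   to (cylinder, strand) map.
#' @export
build_cylinder_model <- function(route, graph, params, geom = NULL) {
  if (is.null(geom)) {
    geom <- helix_geometry(if (route$method %in% c("st_rna", "xt_rna")) "RNA" else "DNA")
  }
  tr <- route$traversals
  radius <- geom$diameter / 2
  scale <- params$scale
  per_traversal_cyl <- route$method %in% c("at_dna", "st_dna")

  # assign traversals to cylinders
  if (per_traversal_cyl) {
    cyl_of <- seq_len(nrow(tr))
    strand_of <- rep(1L, nrow(tr))
    cyl_edge <- tr$edge
    cyl_base <- tr$from          # cylinder axis runs from -> other end
    cyl_kl <- rep(FALSE, nrow(tr))
    cyl_tree <- tr$tree_edge
  } else {
    first_idx <- match(unique(tr$edge), tr$edge)
    cyl_edge <- tr$edge[first_idx]
    cyl_of <- match(tr$edge, cyl_edge)
    cyl_base <- graph$edges$u[cyl_edge]
    strand_of <- ifelse(tr$from == cyl_base[cyl_of], 1L, 2L)
    cyl_kl <- tr$kissing_loop[first_idx]
    cyl_tree <- tr$tree_edge[first_idx]
  }
  ncyl <- length(cyl_edge)

  # lateral offsets for multiple cylinders on one geometric edge
  ekey <- paste(graph$edges$u[cyl_edge], graph$edges$v[cyl_edge])
  clearance <- vertex_clearances(graph, radius / scale)
  cylinders <- vector("list", ncyl)
  offenders <- integer(0)
  group_count <- table(ekey)
  group_seen <- integer(0)
  for (ci in seq_len(ncyl)) {
    e <- cyl_edge[ci]
    a <- cyl_base[ci]
    b <- other_end(graph, e, a)
    pa <- graph$positions[a, ] * scale
    pb <- graph$positions[b, ] * scale
    axis <- pb - pa
    fr <- edge_frame(graph, e, a, b, axis)
    da <- min(clearance[[a]][[as.character(e)]] * scale, vnorm(axis) * 0.4)
    db <- min(clearance[[b]][[as.character(e)]] * scale, vnorm(axis) * 0.4)
    usable <- vnorm(axis) - da - db
    bp <- floor(usable / geom$rise_per_bp)
    if (bp < params$min_bp) offenders <- c(offenders, e)
    bp <- max(1L, as.integer(bp))
    if (route$method == "st_dna") bp <- round_to_turns(bp, geom)
    n_here <- group_count[[ekey[ci]]]
    k_here <- sum(group_seen == ekey[ci]) + 1L
    group_seen <- c(group_seen, ekey[ci])
    lateral <- if (n_here > 1L) {
      (k_here - (n_here + 1) / 2) * geom$diameter * fr[, "x"]
    } else c(0, 0, 0)
    origin <- pa + fr[, "y"] * da + lateral
    cylinders[[ci]] <- list(
      id = ci, edge = e, base_vertex = a, end_vertex = b,
      transform = make_transform(fr, origin),
      nominal_length = vnorm(axis),
      length = bp * geom$rise_per_bp, bp_count = bp, radius = radius,
      kissing_loop = isTRUE(cyl_kl[ci]),
      tree_edge = cyl_tree[ci],
      conn = NULL)
  }
  if (length(offenders) > 0L) {
    stop(sprintf("scale %g nm is too small: edges %s would carry fewer than %d bp",
                 scale, paste(sort(unique(offenders)), collapse = ", "),
                 params$min_bp), call. = FALSE)
  }
  for (ci in seq_len(ncyl)) {
    cyl <- cylinders[[ci]]
    cylinders[[ci]]$conn <- apply_transform(cyl$transform,
                                            port_local(cyl$bp_count, geom))
    rownames(cylinders[[ci]]$conn) <- c("first5", "first3", "second5", "second3")
  }

  links <- build_links(route, graph, cyl_of, strand_of, cyl_base)
  model <- structure(
    list(cylinders = cylinders, links = links, scale = scale, geom = geom,
         vertex_positions = graph$positions * scale,
         method = route$method,
         traversal_map = data.frame(cylinder = cyl_of, strand = strand_of),
         route = route),
    class = "wf_cylinder_model")
  model
}

# Orthonormal cylinder frame (local Y = edge axis).  The azimuth reference
# (local X) points toward the lowest-index neighbouring vertex of the base
# vertex, so the frame - and with it every nucleotide position - moves
# rigidly with the mesh; a lone edge without neighbours falls back to a
# fixed world reference.
edge_frame <- function(graph, e, a, b, axis) {
  y <- vunit(axis)
  nbrs <- setdiff(vapply(graph$rotation[[a]], function(ee) {
    other_end(graph, ee, a)
  }, integer(1L)), b)
  for (nb in sort(nbrs)) {
    d <- graph$positions[nb, ] - graph$positions[a, ]
    perp <- d - sum(d * y) * y
    if (vnorm(perp) > 1e-8) {
      x <- vunit(perp)
      return(cbind(x = x, y = y, z = vcross(x, y)))
    }
  }
  frame_from_axis(axis)
}

# clearance per vertex per incident edge: radius / tan(alpha/2), alpha the
# smallest 3D angle between the edge and any other edge at the vertex
# (mesh units; caller multiplies by scale)
vertex_clearances <- function(graph, radius_mesh_units) {
  nv <- nrow(graph$positions)
  out <- vector("list", nv)
  for (v in seq_len(nv)) {
    inc <- unique(graph$rotation[[v]])
    dirs <- lapply(inc, function(e) {
      vunit(graph$positions[other_end(graph, e, v), ] - graph$positions[v, ])
    })
    out[[v]] <- list()
    for (i in seq_along(inc)) {
      alpha <- pi
      for (j in seq_along(inc)) {
        if (i == j) next
        d <- max(-1, min(1, sum(dirs[[i]] * dirs[[j]])))
        ang <- acos(d)
        if (ang > 1e-6) alpha <- min(alpha, ang)
      }
      cl <- if (alpha >= pi - 1e-9) 0 else radius_mesh_units / tan(alpha / 2)
      out[[v]][[as.character(inc[i])]] <- max(0, cl)
    }
  }
  out
}

# entry/exit ports of each traversal, then link exit(i) -> entry(i+1) within
# each walk; for scaffold methods the complement (staple) side is linked
# along the reversed route.
traversal_ports <- function(route, cyl_of, strand_of) {
  tr <- route$traversals
  n <- nrow(tr)
  entry <- character(n); exit <- character(n)
  for (i in seq_len(n)) {
    if (tr$hairpin[i]) {
      if (strand_of[i] == 1L) { entry[i] <- "first5"; exit[i] <- "second3" }
      else { entry[i] <- "second5"; exit[i] <- "first3" }
    } else if (strand_of[i] == 1L) {
      entry[i] <- "first5"; exit[i] <- "first3"
    } else {
      entry[i] <- "second5"; exit[i] <- "second3"
    }
  }
  data.frame(cylinder = cyl_of, entry = entry, exit = exit)
}

build_links <- function(route, graph, cyl_of, strand_of, cyl_base) {
  tr <- route$traversals
  ports <- traversal_ports(route, cyl_of, strand_of)
  rows <- list()
  add <- function(cf, pf, ct, pt, vertex) {
    rows[[length(rows) + 1L]] <<- data.frame(
      cyl_from = cf, port_from = pf, cyl_to = ct, port_to = pt, vertex = vertex)
  }
  for (w in unique(tr$walk)) {
    idx <- which(tr$walk == w)
    n <- length(idx)
    for (k in seq_len(n)) {
      i <- idx[k]; j <- idx[if (k == n) 1L else k + 1L]
      vertex <- if (tr$hairpin[i]) tr$from[i] else
        other_end(graph, tr$edge[i], tr$from[i])
      add(ports$cylinder[i], ports$exit[i], ports$cylinder[j], ports$entry[j],
          vertex)
    }
  }
  scaffold_method <- route$method %in% c("at_dna", "st_dna")
  if (scaffold_method) {
    # staple side: complement strand (strand 2) of each cylinder, linked
    # along the reversed scaffold route
    idx <- seq_len(nrow(tr))
    n <- length(idx)
    for (k in seq_len(n)) {
      i <- idx[k]; j <- idx[if (k == 1L) n else k - 1L]
      # strand 2 of cylinder i runs 3'->(base vertex); its 5' sits at the
      # to-vertex of traversal j's duplex (the shared junction)
      vertex <- tr$from[i]
      add(ports$cylinder[i], "second3", ports$cylinder[j], "second5", vertex)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.wf_cylinder_model <- function(x, ...) {
  bp <- vapply(x$cylinders, function(c) c$bp_count, numeric(1L))
  cat(sprintf("wf_cylinder_model [%s]: %d cylinders (%d kissing-loop), %d links, %d bp total, diameter %.1f nm\n",
              x$method, length(x$cylinders),
              sum(vapply(x$cylinders, function(c) c$kissing_loop, logical(1L))),
              nrow(x$links), sum(bp), x$geom$diameter))
  invisible(x)
}

#' Spring objective of a cylinder model
#'
#' Sum of squared distances between linked connection points; the quantity
#' [relax()] descends.
#'
#' @param model a `wf_cylinder_model`.
#' @return a non-negative number (nm^2).
#' @export
spring_objective <- function(model) {
  s <- 0
  for (i in seq_len(nrow(model$links))) {
    l <- model$links[i, ]
    p <- model$cylinders[[l$cyl_from]]$conn[l$port_from, ]
    q <- model$cylinders[[l$cyl_to]]$conn[l$port_to, ]
    s <- s + sum((p - q)^2)
  }
  s
}

#' Relax inter-cylinder strain
#'
#' Damped rigid-body spring dynamics: cylinders are rigid bodies, each link
#' a zero-rest-length spring between the two connection points, with a
#' penalty force that keeps non-linked cylinder axes at least the sum of
#' their radii apart.  The state with the lowest spring objective seen
#' during integration is returned, so the objective never increases; the
#' collision penalty keeps overlaps within a 0.1 nm tolerance.
#'
#' @param model a `wf_cylinder_model`.
#' @param iterations integration steps.
#' @param dt time step; non-finite states abort with advice to reduce it.
#' @param stiffness,damping spring constant and velocity damping per step.
#' @param collision_stiffness penalty constant for overlapping bodies.
#' @return the model with updated cylinder transforms and connection points.
#' @export
relax <- function(model, iterations = 500L, dt = 0.01, stiffness = 1,
                  damping = 0.5, collision_stiffness = 10) {
  ncyl <- length(model$cylinders)
  if (ncyl == 0L) return(model)
  centers <- t(vapply(model$cylinders, function(c) {
    apply_transform(c$transform, c(0, c$length / 2, 0))[1, ]
  }, numeric(3L)))
  rots <- lapply(model$cylinders, function(c) c$transform[1:3, 1:3])
  conn_local <- lapply(model$cylinders, function(c) {
    sweep(port_local(c$bp_count, model$geom), 2L, c(0, c$length / 2, 0), `-`)
  })
  halflen <- vapply(model$cylinders, function(c) c$length / 2, numeric(1L))
  radii <- vapply(model$cylinders, function(c) c$radius, numeric(1L))
  linked_pair <- matrix(FALSE, ncyl, ncyl)
  for (i in seq_len(nrow(model$links))) {
    a <- model$links$cyl_from[i]; b <- model$links$cyl_to[i]
    linked_pair[a, b] <- TRUE; linked_pair[b, a] <- TRUE
  }
  vel <- matrix(0, ncyl, 3L)
  ang <- matrix(0, ncyl, 3L)
  world_conn <- function() {
    lapply(seq_len(ncyl), function(i) {
      sweep(conn_local[[i]] %*% t(rots[[i]]), 2L, centers[i, ], `+`)
    })
  }
  objective <- function(wc) {
    s <- 0
    for (i in seq_len(nrow(model$links))) {
      l <- model$links[i, ]
      p <- wc[[l$cyl_from]][l$port_from, ]
      q <- wc[[l$cyl_to]][l$port_to, ]
      s <- s + sum((p - q)^2)
    }
    s
  }
  best <- list(obj = objective(world_conn()), centers = centers, rots = rots)
  for (step in seq_len(iterations)) {
    wc <- world_conn()
    force <- matrix(0, ncyl, 3L)
    torque <- matrix(0, ncyl, 3L)
    for (i in seq_len(nrow(model$links))) {
      l <- model$links[i, ]
      p <- wc[[l$cyl_from]][l$port_from, ]
      q <- wc[[l$cyl_to]][l$port_to, ]
      f <- stiffness * (q - p)
      force[l$cyl_from, ] <- force[l$cyl_from, ] + f
      force[l$cyl_to, ] <- force[l$cyl_to, ] - f
      torque[l$cyl_from, ] <- torque[l$cyl_from, ] +
        vcross(p - centers[l$cyl_from, ], f)
      torque[l$cyl_to, ] <- torque[l$cyl_to, ] +
        vcross(q - centers[l$cyl_to, ], -f)
    }
    for (a in seq_len(ncyl - 1L)) {
      for (b in (a + 1L):ncyl) {
        cp <- segment_closest_points(
          centers[a, ] - rots[[a]][, 2L] * halflen[a],
          centers[a, ] + rots[[a]][, 2L] * halflen[a],
          centers[b, ] - rots[[b]][, 2L] * halflen[b],
          centers[b, ] + rots[[b]][, 2L] * halflen[b])
        gap <- cp$dist - (radii[a] + radii[b])
        if (gap < 0) {
          nrm <- cp$p - cp$q
          nn <- vnorm(nrm)
          nrm <- if (nn > 1e-9) nrm / nn else c(1, 0, 0)
          f <- -collision_stiffness * gap * nrm
          force[a, ] <- force[a, ] + f
          force[b, ] <- force[b, ] - f
        }
      }
    }
    vel <- (vel + dt * force) * (1 - damping * dt)
    ang <- (ang + dt * torque) * (1 - damping * dt)
    centers <- centers + dt * vel
    for (i in seq_len(ncyl)) {
      wv <- ang[i, ] * dt
      th <- vnorm(wv)
      if (th > 1e-12) rots[[i]] <- axis_angle_matrix(wv / th, th) %*% rots[[i]]
    }
    if (!all(is.finite(centers)) || !all(vapply(rots, function(r) all(is.finite(r)), logical(1L)))) {
      stop("relaxation diverged (non-finite state); reduce dt", call. = FALSE)
    }
    obj <- objective(world_conn())
    # ties go to the later state: with the spring objective flat (e.g. no
    # links) the collision resolution should still take effect
    if (obj <= best$obj + 1e-12) best <- list(obj = obj, centers = centers, rots = rots)
  }
  centers <- best$centers; rots <- best$rots
  for (i in seq_len(ncyl)) {
    origin <- centers[i, ] - rots[[i]][, 2L] * halflen[i]
    model$cylinders[[i]]$transform <- make_transform(rots[[i]], origin)
    model$cylinders[[i]]$conn <- apply_transform(
      model$cylinders[[i]]$transform,
      port_local(model$cylinders[[i]]$bp_count, model$geom))
    rownames(model$cylinders[[i]]$conn) <- c("first5", "first3", "second5", "second3")
  }
  model
}

axis_angle_matrix <- function(axis, theta) {
  a <- vunit(axis)
  c1 <- cos(theta); s1 <- sin(theta)
  K <- matrix(c(0, a[3L], -a[2L], -a[3L], 0, a[1L], a[2L], -a[1L], 0), 3L, 3L)
  diag(3) + s1 * K + (1 - c1) * (K %*% K)
}

# closest points between two 3D segments
segment_closest_points <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a < 1e-12 && e < 1e-12) {
    return(list(p = p1, q = q1, dist = vnorm(p1 - q1)))
  }
  if (a < 1e-12) {
    s <- 0; t <- max(0, min(1, f / e))
  } else {
    c1 <- sum(d1 * r)
    if (e < 1e-12) {
      t <- 0; s <- max(0, min(1, -c1 / a))
    } else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > 1e-12) max(0, min(1, (b * f - c1 * e) / den)) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- max(0, min(1, -c1 / a)) }
      else if (t > 1) { t <- 1; s <- max(0, min(1, (b - c1) / a)) }
    }
  }
  p <- p1 + s * d1; q <- q1 + t * d2
  list(p = p, q = q, dist = vnorm(p - q))
}
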