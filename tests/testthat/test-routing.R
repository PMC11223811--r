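# Spanning trees, tree routes, reconditioning and the cycle cover.

test_that("maximally branching Prim: K4 star, path, wheel hub", {
  g <- graph_k4()
  tr <- prim_max_branching_tree(g, seed_vertex = 1L)
  expect_length(tr$edge_ids, 3L)
  # star from the seed: every tree edge touches vertex 1
  expect_true(all(g$edges$u[tr$edge_ids] == 1L | g$edges$v[tr$edge_ids] == 1L))

  p4 <- graph_path(4L)
  expect_setequal(prim_max_branching_tree(p4)$edge_ids, 1:3)

  w5 <- graph_wheel(4L)
  trw <- prim_max_branching_tree(w5, seed_vertex = 1L)
  expect_true(all(w5$edges$u[trw$edge_ids] == 1L | w5$edges$v[trw$edge_ids] == 1L))
})

test_that("st_route traverses every edge twice antiparallel in one walk", {
  cases <- list(graph_k4(), graph_path(2L),
                wireframe_graph(make_mesh("cube")))
  for (g in cases) {
    r <- st_route(g, prim_max_branching_tree(g))
    expect_equal(nrow(r$traversals), 2L * nrow(g$edges))
    v <- validate_route(r, g)
    expect_true(v$ok, info = paste(v$problems, collapse = "; "))
    expect_equal(length(unique(r$traversals$walk)), 1L)
  }
})

test_that("reconditioning yields even degrees by a minimum T-join", {
  # octahedron: already all even, unchanged
  go <- wireframe_graph(make_mesh("octahedron"))
  expect_equal(nrow(recondition(go)$edges), 12L)

  # tetrahedron: 4 odd vertices, exactly one perfect matching's worth of
  # doubled edges; on the regular tetrahedron all 3 matchings cost the same
  gt <- wireframe_graph(make_mesh("tetrahedron"))
  g2 <- recondition(gt)
  added <- which(g2$edges$copy > 1L)
  expect_length(added, 2L)
  ends <- c(g2$edges$u[added], g2$edges$v[added])
  expect_setequal(ends, 1:4)  # a perfect matching of the 4 odd vertices
  # brute-force matching cost oracle
  d <- as.matrix(dist(gt$positions))
  costs <- c(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4], d[1, 4] + d[2, 3])
  expect_equal(sum(g2$edges$len[added]), min(costs), tolerance = 1e-9)
  expect_true(all(tabulate(c(g2$edges$u, g2$edges$v)) %% 2 == 0))

  # path P3: both edges doubled
  p3 <- recondition(graph_path(3L))
  expect_equal(nrow(p3$edges), 4L)
  expect_equal(sort(table(paste(p3$edges$u, p3$edges$v))), sort(c(2L, 2L)),
               ignore_attr = TRUE)
})

test_that("cycle cover: face cycles on meshes, double cover on any graph", {
  gt <- wireframe_graph(make_mesh("tetrahedron"))
  cc <- cycle_cover(gt)
  expect_equal(length(unique(cc$traversals$walk)), 4L)  # the 4 faces
  expect_equal(nrow(cc$traversals), 12L)
  expect_true(validate_route(cc, gt)$ok)

  ge <- graph_path(2L)   # a single edge
  cce <- cycle_cover(ge)
  expect_equal(nrow(cce$traversals), 2L)
  expect_equal(length(unique(cce$traversals$walk)), 1L)
  expect_true(validate_route(cce, ge)$ok)

  # abstract K4 without faces: each edge once per direction
  gk <- graph_k4()
  cck <- cycle_cover(gk)
  tr <- cck$traversals
  for (e in seq_len(nrow(gk$edges))) {
    expect_equal(sort(tr$from[tr$edge == e]),
                 sort(c(gk$edges$u[e], gk$edges$v[e])))
  }
})

test_that("cycle cover junction transitions keep the arms connected", {
  g <- graph_k4()
  tr <- cycle_cover(g)$traversals
  n <- nrow(tr)
  for (v in seq_len(nrow(g$positions))) {
    # transition pairs (incoming edge, outgoing edge) at v
    pairs <- list()
    for (w in unique(tr$walk)) {
      idx <- which(tr$walk == w)
      for (k in seq_along(idx)) {
        i <- idx[k]; j <- idx[if (k == length(idx)) 1L else k + 1L]
        to_v <- setdiff(c(g$edges$u[tr$edge[i]], g$edges$v[tr$edge[i]]), tr$from[i])
        if (to_v == v) pairs[[length(pairs) + 1L]] <- c(tr$edge[i], tr$edge[j])
      }
    }
    arms <- unique(unlist(pairs))
    # union-find over arms through the transition pairs: one block
    parent <- seq_along(arms)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (p in pairs) {
      a <- find(match(p[1L], arms)); b <- find(match(p[2L], arms))
      if (a != b) parent[a] <- b
    }
    expect_equal(length(unique(vapply(seq_along(arms), find, integer(1L)))), 1L,
                 info = paste("vertex", v))
  }
})

test_that("st_rna_route bulges one kissing-loop pair per co-tree edge", {
  g <- graph_k4()
  r <- st_rna_route(g, prim_max_branching_tree(g))
  expect_true(validate_route(r, g)$ok)
  expect_equal(sum(r$traversals$hairpin), 2L * 3L)  # E - (V-1) = 3 loops
  expect_equal(sum(r$traversals$kissing_loop), 6L)

  # a tree graph has no co-tree edges, hence no loops
  p4 <- graph_path(4L)
  rp <- st_rna_route(p4, prim_max_branching_tree(p4))
  expect_equal(sum(rp$traversals$kissing_loop), 0L)
  expect_true(validate_route(rp, p4)$ok)

  gi <- wireframe_graph(make_mesh("icosahedron"))
  ri <- st_rna_route(gi, prim_max_branching_tree(gi))
  expect_equal(sum(ri$traversals$hairpin) / 2L, 19L)  # 30 - 11
})

test_that("RNA routes place the nick at the longest wireframe edge", {
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 3, 0), c(0.5, 1, 1))
  g <- wireframe_graph(positions = pos,
                       edges = t(utils::combn(4L, 2L)))
  r <- st_rna_route(g, prim_max_branching_tree(g))
  expect_equal(r$nick_edge, which.max(g$edges$len))
})

test_that("routes are deterministic", {
  g <- wireframe_graph(make_mesh("cube"))
  expect_identical(st_route(g, prim_max_branching_tree(g)),
                   st_route(g, prim_max_branching_tree(g)))
  expect_identical(cycle_cover(g), cycle_cover(g))
})
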