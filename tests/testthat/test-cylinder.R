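# Cylinder model: diameters, scale law, turn rounding, transforms,
# rigid-motion equivariance, relaxation.

test_that("helix geometry carries the fixed diameters and derived twist", {
  dna <- helix_geometry("DNA")
  rna <- helix_geometry("RNA")
  expect_equal(dna$diameter, 2.0)
  expect_equal(rna$diameter, 2.3)
  expect_equal(dna$twist_per_bp, 360 / dna$bp_per_turn)
  custom <- helix_geometry("DNA", bp_per_turn = 10)
  expect_equal(custom$twist_per_bp, 36)
})

test_that("a unit edge at scale 1 nm becomes a 1 nm nominal cylinder", {
  g <- graph_path(2L)   # one isolated unit-length edge
  cm <- build_cylinder_model(cycle_cover(g), g,
                             design_parameters("cc_dna", scale = 1))
  expect_length(cm$cylinders, 1L)
  expect_equal(cm$cylinders[[1L]]$nominal_length, 1.0, tolerance = 1e-12)
  expect_equal(cm$cylinders[[1L]]$radius, 1.0)
})

test_that("cylinder radii follow the nucleic-acid type", {
  g <- graph_k4()
  cm_d <- build_cylinder_model(cycle_cover(g), g,
                               design_parameters("cc_dna", scale = 18))
  expect_true(all(vapply(cm_d$cylinders, function(c) c$radius, numeric(1L)) == 1.0))
  r <- st_rna_route(g, prim_max_branching_tree(g))
  cm_r <- build_cylinder_model(r, g, design_parameters("st_rna", scale = 18))
  expect_true(all(vapply(cm_r$cylinders, function(c) c$radius, numeric(1L)) == 1.15))
})

test_that("round_to_turns applies the half-down rule, minimum one turn", {
  geom <- helix_geometry("DNA")  # 10.5 bp/turn
  expect_equal(round_to_turns(21L, geom), 21L)  # exactly 2 turns
  expect_equal(round_to_turns(25L, geom), 21L)  # 2.38 turns -> 2
  expect_equal(round_to_turns(27L, geom), 31L)  # 2.57 -> 3 turns, 31.5 -> 31
  expect_equal(round_to_turns(2L, geom), 10L)   # never below one full turn
})

test_that("too small a scale is a parameter error listing the edges", {
  g <- graph_k4()
  expect_error(
    build_cylinder_model(cycle_cover(g), g,
                         design_parameters("cc_dna", scale = 0.5, min_bp = 20L)),
    "too small.*edges")
})

test_that("transforms reproduce stored connection points to 1e-6 nm", {
  g <- graph_k4()
  cm <- build_cylinder_model(cycle_cover(g), g,
                             design_parameters("cc_dna", scale = 15))
  for (cyl in cm$cylinders) {
    world <- wirefold:::apply_transform(
      cyl$transform, wirefold:::port_local(cyl$bp_count, cm$geom))
    expect_lt(max(abs(world - cyl$conn)), 1e-6)
  }
})

test_that("connection points sit on the cylinder ends at backbone radius", {
  g <- graph_path(2L)
  cm <- build_cylinder_model(cycle_cover(g), g,
                             design_parameters("cc_dna", scale = 10))
  cyl <- cm$cylinders[[1L]]
  local <- wirefold:::port_local(cyl$bp_count, cm$geom)
  expect_equal(unname(sqrt(local[, 1L]^2 + local[, 3L]^2)),
               rep(0.9 * cyl$radius, 4L), tolerance = 1e-9)
  expect_setequal(round(local[, 2L], 9),
                  round(c(0, (cyl$bp_count - 1L) * cm$geom$rise_per_bp), 9))
})

test_that("link records pair every 3' port with exactly one 5' port", {
  for (method in c("cc_dna", "st_dna")) {
    g <- graph_k4()
    route <- if (method == "cc_dna") cycle_cover(g) else
      st_route(g, prim_max_branching_tree(g))
    cm <- build_cylinder_model(route, g, design_parameters(method, scale = 18))
    from_key <- paste(cm$links$cyl_from, cm$links$port_from)
    to_key <- paste(cm$links$cyl_to, cm$links$port_to)
    expect_false(anyDuplicated(from_key) > 0)
    expect_false(anyDuplicated(to_key) > 0)
    expect_true(all(grepl("3$", cm$links$port_from)))
    expect_true(all(grepl("5$", cm$links$port_to)))
    # every cylinder end participates
    expect_equal(nrow(cm$links), 2L * length(cm$cylinders))
  }
})

test_that("rigid motion of the mesh moves all cylinders identically", {
  m <- make_mesh("tetrahedron")
  R <- rotation_mat(c(1, 2, 3), 0.7)
  shift <- c(5, -2, 1)
  m2 <- wf_mesh(m$vertices %*% t(R) + matrix(shift, 4, 3, byrow = TRUE),
                m$faces)
  p <- design_parameters("cc_dna", scale = 12)
  cm1 <- build_cylinder_model(cycle_cover(wireframe_graph(m)),
                              wireframe_graph(m), p)
  cm2 <- build_cylinder_model(cycle_cover(wireframe_graph(m2)),
                              wireframe_graph(m2), p)
  bp1 <- vapply(cm1$cylinders, function(c) c$bp_count, numeric(1L))
  bp2 <- vapply(cm2$cylinders, function(c) c$bp_count, numeric(1L))
  expect_equal(bp1, bp2)
  for (i in seq_along(cm1$cylinders)) {
    moved <- cm1$cylinders[[i]]$conn %*% t(R) +
      matrix(shift * p$scale, 4, 3, byrow = TRUE)
    expect_equal(unname(moved), unname(cm2$cylinders[[i]]$conn),
                 tolerance = 1e-8)
  }
})

test_that("relax leaves a zero-objective model unchanged and descends otherwise", {
  g <- graph_k4()
  cm <- build_cylinder_model(cycle_cover(g), g,
                             design_parameters("cc_dna", scale = 15))
  obj0 <- spring_objective(cm)
  rel <- relax(cm, iterations = 150L)
  expect_lte(spring_objective(rel), obj0 + 1e-9)

  for (seed in 1:5) {
    pert <- perturb_model(cm, sd = 1.5, seed = seed)
    obj_p <- spring_objective(pert)
    rel_p <- relax(pert, iterations = 150L)
    expect_lte(spring_objective(rel_p), obj_p + 1e-9)
    expect_lt(spring_objective(rel_p), obj_p)  # strictly improves when strained
  }
})

test_that("relax separates overlapping unlinked cylinders", {
  geom <- helix_geometry("DNA")
  mk_cyl <- function(id, origin) {
    tf <- wirefold:::make_transform(diag(3), origin)
    conn <- wirefold:::apply_transform(tf, wirefold:::port_local(10L, geom))
    rownames(conn) <- c("first5", "first3", "second5", "second3")
    list(id = id, edge = id, base_vertex = 1L, end_vertex = 2L,
         transform = tf, nominal_length = 10 * geom$rise_per_bp,
         length = 10 * geom$rise_per_bp, bp_count = 10L, radius = 1,
         kissing_loop = FALSE, tree_edge = NA, conn = conn)
  }
  model <- structure(list(
    cylinders = list(mk_cyl(1L, c(0, 0, 0)), mk_cyl(2L, c(0.8, 0, 0))),
    links = data.frame(cyl_from = integer(0), port_from = character(0),
                       cyl_to = integer(0), port_to = character(0),
                       vertex = integer(0)),
    scale = 1, geom = geom, vertex_positions = matrix(0, 2, 3),
    method = "cc_dna"), class = "wf_cylinder_model")
  rel <- relax(model, iterations = 400L)
  axes <- lapply(rel$cylinders, function(c) {
    o <- c$transform[1:3, 4L]
    list(a = o, b = o + c$transform[1:3, 2L] * c$length)
  })
  d <- wirefold:::segment_closest_points(axes[[1L]]$a, axes[[1L]]$b,
                                         axes[[2L]]$a, axes[[2L]]$b)$dist
  expect_gte(d, 2 - 0.1)  # sum of radii minus tolerance
})
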