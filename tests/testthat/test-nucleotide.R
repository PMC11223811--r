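# Nucleotide model: template helices, instantiation, linkers, kissing-loop
# rerouting, nicking.

test_that("template helix geometry: pairing, azimuths, axial extent", {
  geom <- helix_geometry("DNA")
  t1 <- generate_template_helix(1L, geom)
  expect_equal(nrow(t1$s1$pos), 1L)
  expect_lt(wirefold:::vnorm(t1$s1$pos[1L, ] - t1$s2$pos[1L, ]), geom$diameter)

  # advancing one full turn restores the azimuth (integer bp/turn geometry)
  g10 <- helix_geometry("DNA", bp_per_turn = 10)
  t11 <- generate_template_helix(11L, g10)
  az <- atan2(t11$s1$pos[, 3L], t11$s1$pos[, 1L])
  expect_equal(az[11L], az[1L], tolerance = 1e-9)

  t10 <- generate_template_helix(10L, geom)
  extent <- max(t10$s1$pos[, 2L]) - min(t10$s1$pos[, 2L])
  expect_equal(extent, 9 * 0.332, tolerance = 1e-12)

  # antiparallel: s2 runs back down the axis and pairs in reverse
  expect_equal(t10$s2$pos[1L, 2L], 9 * 0.332, tolerance = 1e-12)
  expect_equal(t10$s1$a3[1L, ], c(0, -1, 0))
  expect_equal(t10$s2$a3[1L, ], c(0, 1, 0))
})

test_that("instantiation maps templates by the cylinder transform", {
  g <- graph_path(2L)
  cm <- build_cylinder_model(cycle_cover(g), g,
                             design_parameters("cc_dna", scale = 10))
  nm <- instantiate_nucleotides(cm)
  expect_equal(wirefold:::n_nucleotides(nm), 2L * cm$cylinders[[1L]]$bp_count)
  # pure translation: positions shift by exactly the translation vector
  cm2 <- cm
  cm2$cylinders[[1L]]$transform[1:3, 4L] <-
    cm2$cylinders[[1L]]$transform[1:3, 4L] + c(3, 4, 5)
  nm2 <- instantiate_nucleotides(cm2)
  shift <- nm2$pos - nm$pos
  expect_equal(unname(colMeans(shift)), c(3, 4, 5), tolerance = 1e-9)
  expect_lt(max(abs(sweep(shift, 2L, c(3, 4, 5)))), 1e-9)
})

test_that("nucleotide counts add up over cylinders (2 x sum bp)", {
  g <- graph_k4()
  cm <- build_cylinder_model(cycle_cover(g), g,
                             design_parameters("cc_dna", scale = 14))
  nm <- instantiate_nucleotides(cm)
  expect_equal(wirefold:::n_nucleotides(nm),
               sum(vapply(cm$cylinders, function(c) 2L * c$bp_count, integer(1L))))
})

test_that("zero-count linkers bond ends directly; slerp places k linkers", {
  g <- graph_k4()
  cm <- build_cylinder_model(cycle_cover(g), g,
                             design_parameters("cc_dna", scale = 14))
  nm0 <- add_linkers(instantiate_nucleotides(cm), cm, linker_count = 0L)
  expect_equal(sum(nm0$linker), 0L)
  expect_true(all(vapply(nm0$strands, function(s) s$circular, logical(1L))))

  nm2 <- add_linkers(instantiate_nucleotides(cm), cm, linker_count = 2L)
  expect_equal(sum(nm2$linker), 2L * nrow(cm$links))
  expect_true(all(is.na(nm2$pair[nm2$linker])))
  # each linker chain steps monotonically from the 3' to the 5' anchor
  for (i in which(nm2$linker)) {
    p <- nm2$prev[i]; n <- nm2$nxt[i]
    gap <- wirefold:::vnorm(nm2$pos[n, ] - nm2$pos[p, ])
    expect_lt(wirefold:::vnorm(nm2$pos[i, ] - nm2$pos[p, ]), gap + 1e-6)
  }
})

test_that("slerp falls back to linear interpolation when degenerate", {
  a <- c(1, 0, 0); b <- c(-1, 0, 0)  # antipodal
  mid <- wirefold:::slerp_vec(a, b, 0.5)
  expect_true(all(is.finite(mid)))
  expect_equal(mid, c(0, 0, 0))
  near <- wirefold:::slerp_vec(a, a + 1e-9, 0.5)
  expect_true(all(is.finite(near)))
})

test_that("kissing-loop rerouting builds paired hairpins and conserves counts", {
  g <- graph_k4()
  r <- st_rna_route(g, prim_max_branching_tree(g))
  cm <- build_cylinder_model(r, g, design_parameters("st_rna", scale = 16))
  nm <- add_linkers(instantiate_nucleotides(cm), cm)
  n0 <- wirefold:::n_nucleotides(nm)
  nm <- reroute_kissing_loops(nm, cm)
  expect_equal(wirefold:::n_nucleotides(nm), n0)
  expect_equal(sum(nm$kl & !is.na(nm$pair)) / 2, 3 * 7)  # 3 loops x 7 pairs
  # one single strand after rerouting (route is one walk)
  expect_length(nm$strands, 1L)
  expect_true(nm$strands[[1L]]$circular)

  # XT-RNA on K4: a single kissing loop
  rx <- xt_route(g, xuong_tree(g, "exact"))
  cmx <- build_cylinder_model(rx, g, design_parameters("xt_rna", scale = 16))
  nmx <- reroute_kissing_loops(add_linkers(instantiate_nucleotides(cmx), cmx), cmx)
  expect_equal(sum(nmx$kl & !is.na(nmx$pair)) / 2, 7)
})

test_that("models without kissing loops pass through unchanged", {
  g <- graph_k4()
  cm <- build_cylinder_model(cycle_cover(g), g,
                             design_parameters("cc_dna", scale = 14))
  nm <- add_linkers(instantiate_nucleotides(cm), cm)
  expect_identical(reroute_kissing_loops(nm, cm), nm)
})

test_that("a kissing-loop cylinder too short for the motif is an error", {
  g <- graph_k4()
  r <- st_rna_route(g, prim_max_branching_tree(g))
  cm <- build_cylinder_model(r, g, design_parameters("st_rna", scale = 2.2))
  nm <- add_linkers(instantiate_nucleotides(cm), cm)
  expect_error(reroute_kissing_loops(nm, cm), "at least")
})

test_that("pairing is an involution with antiparallel orientation vectors", {
  g <- wireframe_graph(make_mesh("cube"))
  cm <- build_cylinder_model(st_route(g, prim_max_branching_tree(g)), g,
                             design_parameters("st_dna", scale = 16))
  nm <- add_linkers(instantiate_nucleotides(cm), cm)
  idx <- which(!is.na(nm$pair))
  expect_true(all(nm$pair[nm$pair[idx]] == idx))
  dots <- rowSums(nm$a3[idx, ] * nm$a3[nm$pair[idx], ])
  expect_true(all(dots < 0))
})

test_that("nicking conserves nucleotides and respects the minimum overlap", {
  g <- graph_k4()
  cm <- build_cylinder_model(cycle_cover(g), g,
                             design_parameters("cc_dna", scale = 18))
  nm <- add_linkers(instantiate_nucleotides(cm), cm)
  n0 <- wirefold:::n_nucleotides(nm)
  min_ov <- 8L
  nm2 <- nick_strands(nm, cm, min_overlap = min_ov)
  expect_equal(wirefold:::n_nucleotides(nm2), n0)
  expect_gt(length(nm2$strands), length(nm$strands))
  # independent domain check: walk each strand, maximal consecutive-pair runs
  for (s in nm2$strands) {
    run <- 0L; prev_p <- NA_integer_
    doms <- integer(0)
    for (i in s$nts) {
      p <- nm2$pair[i]
      if (is.na(p)) { if (run) doms <- c(doms, run); run <- 0L }
      else if (run && !is.na(prev_p) && abs(p - prev_p) == 1L) run <- run + 1L
      else { if (run) doms <- c(doms, run); run <- 1L }
      prev_p <- p
    }
    if (run) doms <- c(doms, run)
    expect_true(all(doms >= min_ov),
                info = paste("domains:", paste(doms, collapse = ",")))
  }
  # number of new strands equals number of nicks on a set of cycles
  expect_equal(length(nm2$strands), sum(is.na(nm2$prev)))
})

test_that("an impossible overlap leaves the cycle circular with a warning", {
  g <- graph_path(2L)
  cm <- build_cylinder_model(cycle_cover(g), g,
                             design_parameters("cc_dna", scale = 6))
  nm <- add_linkers(instantiate_nucleotides(cm), cm)
  expect_warning(nm2 <- nick_strands(nm, cm, min_overlap = 1000L),
                 "left circular")
  expect_true(all(vapply(nm2$strands, function(s) s$circular, logical(1L))))
})

test_that("RNA designs get exactly one nick, at the longest edge", {
  # stretch one vertex so a unique longest edge exists
  m <- make_mesh("tetrahedron")
  v <- m$vertices
  v[1L, ] <- v[1L, ] * 1.6
  g <- wireframe_graph(wf_mesh(v, m$faces))
  r <- st_rna_route(g, prim_max_branching_tree(g))
  cm <- build_cylinder_model(r, g, design_parameters("st_rna", scale = 16))
  nm <- reroute_kissing_loops(add_linkers(instantiate_nucleotides(cm), cm), cm)
  nm2 <- nick_strands(nm, cm)
  expect_length(nm2$strands, 1L)
  expect_false(nm2$strands[[1L]]$circular)
  first <- nm2$strands[[1L]]$nts[1L]
  longest <- which.max(g$edges$len)
  expect_equal(cm$cylinders[[nm2$cylinder[first]]]$edge, longest)
})

test_that("rigid-motion equivariance holds end to end", {
  m <- make_mesh("tetrahedron")
  R <- rotation_mat(c(0, 1, 1), 1.1)
  shift <- c(-3, 2, 7)
  m2 <- wf_mesh(m$vertices %*% t(R) + matrix(shift, 4, 3, byrow = TRUE), m$faces)
  p <- design_parameters("cc_dna", scale = 12)
  build_nm <- function(mesh) {
    g <- wireframe_graph(mesh)
    cm <- build_cylinder_model(cycle_cover(g), g, p)
    add_linkers(instantiate_nucleotides(cm), cm, linker_count = 1L)
  }
  nm1 <- build_nm(m); nm2 <- build_nm(m2)
  expect_equal(unname(nm1$pos %*% t(R) +
                        matrix(shift * p$scale, nrow(nm1$pos), 3, byrow = TRUE)),
               unname(nm2$pos), tolerance = 1e-8)
})
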