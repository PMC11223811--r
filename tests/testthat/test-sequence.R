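# Sequence design: scaffold complementation, longest repeated substring,
# Focused Metropolis Search, kissing loops, NUPACK round trip.

cc_model <- function(scale = 18, mesh = "tetrahedron") {
  g <- wireframe_graph(make_mesh(mesh))
  p <- design_parameters("cc_dna", scale = scale)
  cm <- build_cylinder_model(cycle_cover(g), g, p)
  nm <- nick_strands(add_linkers(instantiate_nucleotides(cm), cm), cm,
                     min_overlap = p$min_overlap)
  list(nm = nm, cm = cm, p = p)
}

test_that("assign_scaffold writes the scaffold and complements the staples", {
  g <- wireframe_graph(make_mesh("tetrahedron"))
  p <- design_parameters("st_dna", scale = 16)
  cm <- build_cylinder_model(st_route(g, prim_max_branching_tree(g)), g, p)
  nm <- nick_strands(add_linkers(instantiate_nucleotides(cm), cm), cm, 8L)
  roles <- vapply(nm$strands, function(s) s$role, character(1L))
  need <- length(nm$strands[[which(roles == "scaffold")]]$nts)
  set.seed(11)
  sc <- random_sequence(need + 50L, "DNA")
  nm2 <- assign_scaffold(nm, sc, cm)
  nts <- nm2$strands[[which(roles == "scaffold")]]$nts
  expect_equal(paste(nm2$base[nts], collapse = ""), substr(sc, 1, need))
  idx <- which(!is.na(nm2$pair))
  expect_true(all(nm2$base[nm2$pair[idx]] ==
                    wirefold:::wc_complement(nm2$base[idx], "DNA")))
  expect_false(any(nm2$base == "N"))
})

test_that("scaffold errors: too short, wrong alphabet", {
  g <- wireframe_graph(make_mesh("tetrahedron"))
  p <- design_parameters("st_dna", scale = 16)
  cm <- build_cylinder_model(st_route(g, prim_max_branching_tree(g)), g, p)
  nm <- nick_strands(add_linkers(instantiate_nucleotides(cm), cm), cm, 8L)
  expect_error(assign_scaffold(nm, "ACGT", cm), "too short")
  roles <- vapply(nm$strands, function(s) s$role, character(1L))
  need <- length(nm$strands[[which(roles == "scaffold")]]$nts)
  expect_error(assign_scaffold(nm, strrep("ACGU", need), cm),
               "outside the DNA alphabet")
})

test_that("longest_repeated_substring on the documented examples", {
  expect_equal(longest_repeated_substring("ACGTACGT"), 4L)
  expect_equal(longest_repeated_substring("ACGT"), 0L)
  expect_equal(longest_repeated_substring(c("ACGTT", "ACGAA")), 3L)
  expect_equal(longest_repeated_substring(c("AAAA")), 3L)  # "AAA" twice
  expect_equal(longest_repeated_substring(character(0)), 0L)
})

test_that("longest_repeated_substring agrees with the suffix-sort oracle", {
  set.seed(421)
  for (rep in 1:60) {
    k <- sample(1:3, 1L)
    lens <- sample(5:120, k, replace = TRUE)
    strands <- vapply(lens, function(n) random_sequence(n, "DNA"),
                      character(1L))
    expect_equal(longest_repeated_substring(strands), oracle_lrs(strands),
                 info = paste(strands, collapse = "+"))
  }
})

test_that("fms_optimize: reproducible, monotone, constraint-satisfying", {
  x <- cc_model()
  run <- function() fms_optimize(x$nm, x$p, x$cm, seed = 5L, max_iters = 120L)
  a <- run(); b <- run()
  expect_identical(a$base, b$base)   # same seed, same output
  tr <- attr(a, "objective_trace")
  expect_true(all(diff(tr) <= 0))    # best objective never increases
  seqs <- vapply(a$strands, function(s) wirefold:::strand_sequence(a, s),
                 character(1L))
  gcs <- vapply(seqs, wirefold:::gc_fraction, numeric(1L))
  expect_true(all(gcs >= x$p$gc_bounds[1L] - 1e-9 &
                    gcs <= x$p$gc_bounds[2L] + 1e-9))
  idx <- which(!is.na(a$pair))
  expect_true(all(a$base[a$pair[idx]] ==
                    wirefold:::wc_complement(a$base[idx], "DNA")))
})

test_that("forbidden subsequences never appear in the result", {
  x <- cc_model()
  p <- design_parameters("cc_dna", scale = 18,
                         forbidden_subsequences = c("GGGG", "CCCC"))
  out <- fms_optimize(x$nm, p, x$cm, seed = 2L, max_iters = 150L)
  seqs <- vapply(out$strands, function(s) wirefold:::strand_sequence(out, s),
                 character(1L))
  expect_false(any(grepl("GGGG|CCCC", seqs)))
})

test_that("on a single short duplex FMS reaches the brute-force optimum", {
  # one 4-bp duplex: two linear 4-nt strands, reverse complements of each
  # other; exhaustive search over all 4^4 assignments gives the optimum
  g <- graph_path(2L)
  geom <- helix_geometry("DNA")
  p <- design_parameters("cc_dna", scale = 4 * geom$rise_per_bp + 0.01,
                         gc_bounds = c(0, 1))
  cm <- build_cylinder_model(cycle_cover(g), g, p)
  expect_equal(cm$cylinders[[1L]]$bp_count, 4L)
  nm <- instantiate_nucleotides(cm)
  nm <- wirefold:::recompute_strands(nm, "cc_dna")  # two bare linear strands
  revcomp <- function(s) paste(rev(wirefold:::wc_complement(
    strsplit(s, "")[[1L]], "DNA")), collapse = "")
  lets <- c("A", "C", "G", "T")
  best_brute <- min(vapply(seq_len(256L) - 1L, function(code) {
    s <- paste(lets[(code %/% c(1L, 4L, 16L, 64L)) %% 4L + 1L], collapse = "")
    longest_repeated_substring(c(s, revcomp(s)))
  }, numeric(1L)))
  out <- fms_optimize(nm, p, cm, seed = 3L, max_iters = 400L)
  expect_equal(attr(out, "objective"), best_brute)
})

test_that("kissing-loop assignment uses distinct table entries and pins them", {
  g <- graph_k4()
  r <- st_rna_route(g, prim_max_branching_tree(g))
  cm <- build_cylinder_model(r, g, design_parameters("st_rna", scale = 16))
  nm <- reroute_kissing_loops(add_linkers(instantiate_nucleotides(cm), cm), cm)
  tab <- kissing_loop_table()
  nm2 <- assign_kissing_loops(nm, cm, tab)
  kl_cyls <- which(vapply(cm$cylinders, function(c) c$kissing_loop, logical(1L)))
  got <- vapply(kl_cyls, function(ci) {
    ids <- intersect(wirefold:::pass_ids(nm2, ci, 1L), which(nm2$kl))
    paste(nm2$base[ids], collapse = "")
  }, character(1L))
  expect_equal(sort(got), sort(tab$seq_a[seq_along(kl_cyls)]))
  expect_true(all(nm2$fixed[nm2$kl]))
  # partners carry the complement
  ids <- which(nm2$kl & !is.na(nm2$pair))
  expect_true(all(nm2$base[nm2$pair[ids]] ==
                    wirefold:::wc_complement(nm2$base[ids], "RNA")))

  # capacity error
  expect_error(assign_kissing_loops(nm, cm, tab[1:2, ]), "only 2")
  # no loops: unchanged
  gc <- graph_k4()
  cmc <- build_cylinder_model(cycle_cover(gc), gc,
                              design_parameters("cc_dna", scale = 16))
  nmc <- add_linkers(instantiate_nucleotides(cmc), cmc)
  expect_identical(assign_kissing_loops(nmc, cmc, tab), nmc)
})

test_that("random fill completes a complementary RNA primary structure", {
  g <- wireframe_graph(make_mesh("octahedron"))
  r <- xt_route(g, xuong_tree(g, "heuristic"))
  cm <- build_cylinder_model(r, g, design_parameters("xt_rna", scale = 16))
  nm <- nick_strands(reroute_kissing_loops(
    add_linkers(instantiate_nucleotides(cm), cm), cm), cm)
  nm <- assign_kissing_loops(nm, cm)
  nm <- assign_random_sequences(nm, cm, seed = 9L)
  expect_false(any(nm$base == "N"))
  idx <- which(!is.na(nm$pair))
  expect_true(all(nm$base[nm$pair[idx]] ==
                    wirefold:::wc_complement(nm$base[idx], "RNA")))
  # same seed reproduces
  nm_b <- assign_random_sequences(
    assign_kissing_loops(nick_strands(reroute_kissing_loops(
      add_linkers(instantiate_nucleotides(cm), cm), cm), cm), cm),
    cm, seed = 9L)
  expect_identical(nm$base, nm_b$base)
})

test_that("NUPACK export writes matching structures and fixed letters", {
  g <- graph_k4()
  r <- st_rna_route(g, prim_max_branching_tree(g))
  cm <- build_cylinder_model(r, g, design_parameters("st_rna", scale = 16))
  nm <- nick_strands(reroute_kissing_loops(
    add_linkers(instantiate_nucleotides(cm), cm), cm), cm)
  nm <- assign_kissing_loops(nm, cm)
  txt <- export_nupack(nm)
  lines <- strsplit(txt, "\n")[[1L]]
  st <- sub(".*= ", "", grep("^structure", lines, value = TRUE))
  sq <- sub(".*= ", "", grep("^sequence", lines, value = TRUE))
  expect_length(st, length(nm$strands))
  for (i in seq_along(st)) {
    expect_equal(nchar(st[i]), length(nm$strands[[i]]$nts))
    expect_equal(nchar(sq[i]), nchar(st[i]))
    # balanced brackets
    expect_equal(sum(strsplit(st[i], "")[[1L]] == "("),
                 sum(strsplit(st[i], "")[[1L]] == ")"))
  }
  # kissing-loop letters present in the constraint line
  expect_true(any(grepl("[ACGU]", sq)))
  # fixed letters sit exactly at the pinned positions
  nts <- nm$strands[[1L]]$nts
  cons <- strsplit(sq[1L], "")[[1L]]
  expect_equal(which(cons != "N"), which(nm$fixed[nts]))

  # import round trip
  seqs <- vapply(nm$strands, function(s) {
    paste(ifelse(nm$base[s$nts] == "N", "A", nm$base[s$nts]), collapse = "")
  }, character(1L))
  nm2 <- import_nupack(nm, paste(seqs, collapse = "\n"))
  expect_equal(vapply(nm2$strands, function(s) {
    paste(nm2$base[s$nts], collapse = "")
  }, character(1L)), seqs)
  expect_error(import_nupack(nm, substr(seqs[1L], 1, 10)), "length")
})
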