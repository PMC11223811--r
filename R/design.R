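#' Design a nucleic-acid wireframe nanostructure
#'
#' Runs the full design pipeline on a polygon mesh: strand routing by the
#' chosen method, cylinder (double helix) model at the given scale,
#' nucleotide-level 3D model with linkers, kissing-loop rerouting and
#' nicking, and primary sequence design.  The five methods are
#' `at_dna` (A-trail Eulerian scaffold routing; needs a closed orientable
#' manifold mesh), `st_dna` (scaffold routed twice around a maximally
#' branching spanning tree, two-helix bundle per edge), `cc_dna`
#' (scaffold-free antiparallel double cycle cover with Focused Metropolis
#' sequence design), `st_rna` (single RNA strand around a spanning tree,
#' one kissing loop per co-tree edge) and `xt_rna` (Xuong-tree routing
#' minimising the kissing-loop count).
#'
#' @param mesh a [wf_mesh], an OBJ file path, or OBJ text.
#' @param method design method (see above).
#' @param scale nanometres per mesh unit.
#' @param sequence_mode `"auto"` picks the method's default (`scaffold`
#'   with a random emulated scaffold for `at_dna`/`st_dna`, `fms` for
#'   `cc_dna`, kissing-loop table + `random` fill for the RNA methods);
#'   `"none"` skips sequence design; `"nupack"` (RNA) assigns kissing
#'   loops and leaves the rest `N` for [export_nupack()].
#' @param scaffold scaffold sequence text or FASTA path (scaffolded DNA
#'   methods); when `NULL` a random scaffold of the required length is
#'   generated from the seed.
#' @param params a [design_parameters()]; when `NULL` one is built from
#'   `method`, `scale`, `seed` and `...`.
#' @param seed seed for every stochastic step.
#' @param outdir when given, writes `design.top`/`design.dat` (oxDNA),
#'   `design.unf.json`, `strands.csv`, `route.txt`, `report.json` and the
#'   effective configuration `config.json` there.
#' @param fms_iters Metropolis iterations for `cc_dna` sequence design.
#' @param ... further arguments to [design_parameters()].
#' @return a `wf_design` object: the mesh, graph, route, cylinder model,
#'   nucleotide model, parameters and a validator `report`.
#' @examples
#' d <- run_design(make_mesh("tetrahedron"), "st_dna", scale = 18, seed = 7)
#' summary(d)
#' @export
run_design <- function(mesh, method = c("at_dna", "st_dna", "cc_dna",
                                        "st_rna", "xt_rna"),
                       scale = 10, sequence_mode = c("auto", "scaffold",
                                                     "fms", "random",
                                                     "nupack", "none"),
                       scaffold = NULL, params = NULL, seed = 1L,
                       outdir = NULL, fms_iters = 2000L, ...) {
  method <- match.arg(method)
  sequence_mode <- match.arg(sequence_mode)
  if (is.character(mesh)) {
    mesh <- if (file.exists(mesh)) parse_obj(mesh, is_path = TRUE) else parse_obj(mesh)
  }
  if (is.null(params)) {
    params <- design_parameters(method, scale = scale, seed = seed, ...)
  }
  if (!is.null(scaffold) && method == "cc_dna") {
    stop("a scaffold sequence makes no sense for the scaffold-free cc_dna method",
         call. = FALSE)
  }
  graph <- wireframe_graph(mesh)
  rt <- route_for_method(graph, method)
  graph <- rt$graph
  route <- rt$route
  cm <- build_cylinder_model(route, graph, params)
  if (isTRUE(params$relax)) {
    cm <- relax(cm, iterations = params$relax_iterations, dt = params$relax_dt)
  }
  nm <- instantiate_nucleotides(cm)
  nm <- add_linkers(nm, cm, linker_count = params$linker_count)
  nm <- reroute_kissing_loops(nm, cm)
  nm <- nick_strands(nm, cm, min_overlap = params$min_overlap)
  nm <- design_sequences(nm, cm, params, sequence_mode, scaffold, fms_iters)
  design <- structure(
    list(mesh = mesh, graph = graph, route = route, cylinder_model = cm,
         nucleotide_model = nm, params = params,
         sequence_mode = sequence_mode),
    class = "wf_design")
  design$report <- design_report(design)
  if (!is.null(outdir)) write_design(design, outdir)
  design
}

route_for_method <- function(graph, method) {
  route <- switch(method,
    at_dna = {
      if (!isTRUE(graph$manifold)) {
        stop("at_dna needs a closed orientable 2-manifold mesh; ",
             "use st_dna/cc_dna/st_rna/xt_rna for general wireframes",
             call. = FALSE)
      }
      graph <- recondition(graph)
      r <- atrail_search(graph)
      if (inherits(r, "wf_atrail_miss")) {
        stop("no A-trail found for this mesh", call. = FALSE)
      }
      r
    },
    st_dna = st_route(graph, prim_max_branching_tree(graph)),
    cc_dna = cycle_cover(graph),
    st_rna = st_rna_route(graph, prim_max_branching_tree(graph)),
    xt_rna = xt_route(graph, xuong_tree(graph, "heuristic")))
  list(graph = graph, route = route)
}

design_sequences <- function(nm, cm, params, mode, scaffold, fms_iters) {
  method <- cm$method
  if (mode == "auto") {
    mode <- switch(method, at_dna = "scaffold", st_dna = "scaffold",
                   cc_dna = "fms", st_rna = "random", xt_rna = "random")
  }
  if (mode == "none") return(nm)
  if (mode == "scaffold") {
    roles <- vapply(nm$strands, function(s) s$role, character(1L))
    need <- length(nm$strands[[which(roles == "scaffold")]]$nts)
    if (is.null(scaffold)) {
      set.seed(params$seed)
      scaffold <- random_sequence(need, model_alphabet(nm, cm))
    } else if (file.exists(scaffold)) {
      scaffold <- read_fasta_sequence(scaffold)
    }
    return(assign_scaffold(nm, scaffold, cm,
                           linker_base = params$linker_policy))
  }
  if (mode == "fms") {
    return(fms_optimize(nm, params, cm, seed = params$seed,
                        max_iters = fms_iters))
  }
  # random / nupack: kissing loops first, from the bundled table
  nm <- assign_kissing_loops(nm, cm)
  if (mode == "random") {
    nm <- assign_random_sequences(nm, cm, seed = params$seed,
                                  linker_base = params$linker_policy)
  }
  nm
}

#' Validators of a finished design
#'
#' Re-checks the structural laws of a design: route closure and coverage,
#' pairing involution with antiparallel orientation vectors,
#' Watson-Crick complementarity of every assigned pair, minimum staple
#' binding-domain length, and connection-point/transform consistency.
#'
#' @param design a `wf_design`.
#' @return a list of named booleans plus the staple length histogram and
#'   kissing-loop count; element `ok` is the conjunction.
#' @export
design_report <- function(design) {
  nm <- design$nucleotide_model
  cm <- design$cylinder_model
  rv <- validate_route(design$route, design$graph)
  pair_ok <- pairing_involution_ok(nm)
  comp_ok <- complementarity_ok(nm, cm)
  tf_ok <- transforms_consistent(cm)
  roles <- vapply(nm$strands, function(s) s$role, character(1L))
  staple_lens <- vapply(nm$strands, function(s) length(s$nts), integer(1L))
  staple_lens <- staple_lens[roles == "staple"]
  kl_pairs <- sum(nm$kl & !is.na(nm$pair)) / 2
  ok <- rv$ok && pair_ok && comp_ok && tf_ok
  list(ok = ok, route_ok = rv$ok, route_problems = rv$problems,
       pairing_ok = pair_ok, complementarity_ok = comp_ok,
       transforms_ok = tf_ok,
       coverage = as.integer(rv$coverage),
       kissing_loop_pairs = as.integer(round(kl_pairs)),
       n_strands = length(nm$strands),
       n_nucleotides = n_nucleotides(nm),
       staple_length_histogram = if (length(staple_lens) > 0L)
         table(staple_lens) else NULL,
       turn_config = design$route$vertex_config)
}

pairing_involution_ok <- function(nm) {
  p <- nm$pair
  idx <- which(!is.na(p))
  if (length(idx) == 0L) return(TRUE)
  if (!all(p[p[idx]] == idx)) return(FALSE)
  # non-linker pairs antiparallel: a3 vectors oppose
  dots <- rowSums(nm$a3[idx, , drop = FALSE] * nm$a3[p[idx], , drop = FALSE])
  all(dots[!nm$kl[idx]] < 0)
}

complementarity_ok <- function(nm, cm) {
  alpha <- model_alphabet(nm, cm)
  idx <- which(!is.na(nm$pair) & nm$base != "N")
  if (length(idx) == 0L) return(TRUE)
  idx <- idx[nm$base[nm$pair[idx]] != "N"]
  all(nm$base[nm$pair[idx]] == wc_complement(nm$base[idx], alpha))
}

transforms_consistent <- function(cm, tol = 1e-6) {
  for (cyl in cm$cylinders) {
    world <- apply_transform(cyl$transform, port_local(cyl$bp_count, cm$geom))
    if (max(abs(world - cyl$conn)) > tol) return(FALSE)
  }
  TRUE
}

write_design <- function(design, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  nm <- design$nucleotide_model
  write_oxdna(nm, top_path = file.path(outdir, "design.top"),
              dat_path = file.path(outdir, "design.dat"))
  write_unf(nm, na_type = design$cylinder_model$geom$nucleic_acid,
            path = file.path(outdir, "design.unf.json"))
  write_strand_csv(nm, path = file.path(outdir, "strands.csv"),
                   allow_N = design$sequence_mode %in% c("none", "nupack"))
  write_route_txt(design$route, design$graph,
                  path = file.path(outdir, "route.txt"))
  rep <- design$report
  rep$staple_length_histogram <- as.list(rep$staple_length_histogram)
  jsonlite::write_json(rep, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  cfg <- design$params
  class(cfg) <- NULL
  cfg$sequence_mode <- design$sequence_mode
  jsonlite::write_json(cfg, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  if (design$params$method %in% c("st_rna", "xt_rna") &&
      design$sequence_mode == "nupack") {
    export_nupack(nm, path = file.path(outdir, "design.npd"))
  }
  invisible(outdir)
}

#' @export
print.wf_design <- function(x, ...) {
  cat(sprintf("wf_design [%s] at %g nm/unit: %d vertices, %d edges\n",
              x$params$method, x$params$scale,
              nrow(x$mesh$vertices), nrow(x$mesh$edges)))
  print(x$cylinder_model)
  print(x$nucleotide_model)
  cat(sprintf("validators: %s\n", if (x$report$ok) "all pass" else "FAILING"))
  invisible(x)
}

#' @export
summary.wf_design <- function(object, ...) {
  x <- object
  print(x)
  r <- x$report
  cat(sprintf("  edge coverage: %s\n",
              paste(unique(r$coverage), collapse = "/")))
  cat(sprintf("  kissing-loop pairs: %d\n", r$kissing_loop_pairs))
  if (!is.null(r$staple_length_histogram)) {
    cat("  staple lengths:\n")
    print(r$staple_length_histogram)
  }
  invisible(r)
}
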