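#' Template double helix along the Y axis
#'
#' Generates the two antiparallel strands of an ideal double helix in
#' cylinder-local coordinates: successive bases advance `rise_per_bp` along
#' Y and rotate `twist_per_bp` about it; backbones sit at 0.9 x radius with
#' the paired backbone offset by the minor-groove angle.  Orientation
#' vectors follow the oxDNA convention: `a1` points from the backbone
#' toward the helix axis (base direction), `a3` along the axis in the
#' 3'-to-5' direction of the strand.
#'
#' @param bp_count number of base pairs (>= 1).
#' @param geom a [helix_geometry()].
#' @return a list with `s1` and `s2`, each holding `pos`, `a1`, `a3`
#'   (bp x 3 matrices, rows in 5'-to-3' order).  `s1` nucleotide `i` pairs
#'   `s2` nucleotide `bp_count + 1 - i`.
#' @export
generate_template_helix <- function(bp_count, geom) {
  stopifnot(bp_count >= 1)
  out <- list()
  for (strand in 1:2) {
    pos <- template_strand_positions(bp_count, geom, strand)
    a1 <- -cbind(pos[, 1L], 0, pos[, 3L])
    a1 <- a1 / sqrt(rowSums(a1^2))
    a3 <- matrix(rep(if (strand == 1L) c(0, -1, 0) else c(0, 1, 0),
                     each = bp_count), ncol = 3L)
    out[[paste0("s", strand)]] <- list(pos = pos, a1 = a1, a3 = a3)
  }
  out
}

new_nucleotide_model <- function(n) {
  structure(list(
    pos = matrix(NA_real_, n, 3L),
    a1 = matrix(NA_real_, n, 3L),
    a3 = matrix(NA_real_, n, 3L),
    base = rep("N", n),
    prev = rep(NA_integer_, n),
    nxt = rep(NA_integer_, n),
    pair = rep(NA_integer_, n),
    linker = rep(FALSE, n),
    kl = rep(FALSE, n),
    fixed = rep(FALSE, n),
    cylinder = rep(NA_integer_, n),
    cyl_strand = rep(NA_integer_, n),
    strands = NULL
  ), class = "wf_nucleotide_model")
}

n_nucleotides <- function(nm) length(nm$base)

#' @export
print.wf_nucleotide_model <- function(x, ...) {
  ns <- if (is.null(x$strands)) NA_integer_ else length(x$strands)
  cat(sprintf("wf_nucleotide_model: %d nucleotides (%d paired, %d linker, %d kissing-loop), %s strand(s)\n",
              n_nucleotides(x), sum(!is.na(x$pair)), sum(x$linker),
              sum(x$kl), ns))
  if (!is.null(x$strands)) {
    role <- vapply(x$strands, function(s) s$role, character(1L))
    circ <- vapply(x$strands, function(s) s$circular, logical(1L))
    for (r in unique(role)) {
      lens <- vapply(x$strands[role == r], function(s) length(s$nts), integer(1L))
      cat(sprintf("  %s: %d strand(s), lengths %s%s\n", r, length(lens),
                  paste(range(lens), collapse = "-"),
                  if (any(circ[role == r])) " (circular)" else ""))
    }
  }
  invisible(x)
}

#' Instantiate nucleotides from a cylinder model
#'
#' Generates a template helix per cylinder and maps it to world coordinates
#' with the cylinder's 4 x 4 transform.  Base pairing is set within each
#' cylinder; strands are not yet connected across cylinders (see
#' [add_linkers()]).
#'
#' @param model a `wf_cylinder_model`.
#' @return a `wf_nucleotide_model` with `sum(2 * bp_count)` nucleotides.
#' @export
instantiate_nucleotides <- function(model) {
  total <- sum(vapply(model$cylinders, function(c) 2L * c$bp_count, integer(1L)))
  nm <- new_nucleotide_model(total)
  at <- 0L
  for (cyl in model$cylinders) {
    if (abs(det(cyl$transform[1:3, 1:3])) < 1e-9) {
      stop("cylinder ", cyl$id, " has a singular transform", call. = FALSE)
    }
    tpl <- generate_template_helix(cyl$bp_count, model$geom)
    bp <- cyl$bp_count
    for (strand in 1:2) {
      s <- tpl[[strand]]
      idx <- at + seq_len(bp)
      nm$pos[idx, ] <- apply_transform(cyl$transform, s$pos)
      nm$a1[idx, ] <- apply_transform(cyl$transform, s$a1, w = 0)
      nm$a3[idx, ] <- apply_transform(cyl$transform, s$a3, w = 0)
      nm$cylinder[idx] <- cyl$id
      nm$cyl_strand[idx] <- strand
      nm$prev[idx[-1L]] <- idx[-bp]
      nm$nxt[idx[-bp]] <- idx[-1L]
      at <- at + bp
    }
    s1 <- at - 2L * bp + seq_len(bp)
    s2 <- at - bp + seq_len(bp)
    nm$pair[s1] <- rev(s2)
    nm$pair[s2] <- rev(s1)
  }
  nm
}

# nucleotide ids of a cylinder-strand pass (5'->3' order)
pass_ids <- function(nm, cyl, strand) {
  which(nm$cylinder == cyl & nm$cyl_strand == strand)
}

port_nucleotide <- function(nm, cyl, port, end) {
  strand <- if (port %in% c("first5", "first3")) 1L else 2L
  ids <- pass_ids(nm, cyl, strand)
  if (end == "5") ids[1L] else ids[length(ids)]
}

#' Connect strand ends with linker nucleotides
#'
#' Joins every linked 3'/5' end pair of the cylinder model.  When the gap
#' calls for linker nucleotides (by default `round(gap / 0.6 nm) - 1`,
#' capped at 5, or a fixed count from the design parameters) they are placed
#' by spherical linear interpolation of the two end positions about the
#' junction vertex, with orientation vectors interpolated the same way;
#' coincident or antipodal ends fall back to linear interpolation.  After
#' linking, the strands form the closed cycles dictated by the route.
#'
#' @param nm a `wf_nucleotide_model` from [instantiate_nucleotides()].
#' @param model the `wf_cylinder_model`.
#' @param linker_count fixed linker count, or `NA` to derive from the gap.
#' @return the connected `wf_nucleotide_model` (strand table populated).
#' @export
add_linkers <- function(nm, model, linker_count = NA_integer_) {
  for (i in seq_len(nrow(model$links))) {
    l <- model$links[i, ]
    a <- port_nucleotide(nm, l$cyl_from, l$port_from, "3")
    b <- port_nucleotide(nm, l$cyl_to, l$port_to, "5")
    pa <- nm$pos[a, ]; pb <- nm$pos[b, ]
    gap <- vnorm(pb - pa)
    k <- if (is.na(linker_count)) {
      max(0L, min(5L, as.integer(round(gap / 0.6)) - 1L))
    } else as.integer(linker_count)
    if (k > 0L) {
      center <- model$vertex_positions[l$vertex, ]
      newidx <- n_nucleotides(nm) + seq_len(k)
      nm <- grow_model(nm, k)
      for (j in seq_len(k)) {
        t <- j / (k + 1)
        id <- newidx[j]
        nm$pos[id, ] <- center + slerp_vec(pa - center, pb - center, t)
        a1 <- slerp_vec(nm$a1[a, ], nm$a1[b, ], t)
        a3 <- slerp_vec(nm$a3[a, ], nm$a3[b, ], t)
        nm$a1[id, ] <- safe_unit(a1, nm$a1[a, ])
        nm$a3[id, ] <- safe_unit(a3, nm$a3[a, ])
        nm$linker[id] <- TRUE
      }
      chain <- c(a, newidx, b)
    } else {
      chain <- c(a, b)
    }
    for (j in seq_len(length(chain) - 1L)) {
      nm$nxt[chain[j]] <- chain[j + 1L]
      nm$prev[chain[j + 1L]] <- chain[j]
    }
  }
  recompute_strands(nm, model$method)
}

safe_unit <- function(v, fallback) {
  n <- vnorm(v)
  if (n < 1e-9) fallback else v / n
}

grow_model <- function(nm, k) {
  nm$pos <- rbind(nm$pos, matrix(NA_real_, k, 3L))
  nm$a1 <- rbind(nm$a1, matrix(NA_real_, k, 3L))
  nm$a3 <- rbind(nm$a3, matrix(NA_real_, k, 3L))
  nm$base <- c(nm$base, rep("N", k))
  nm$prev <- c(nm$prev, rep(NA_integer_, k))
  nm$nxt <- c(nm$nxt, rep(NA_integer_, k))
  nm$pair <- c(nm$pair, rep(NA_integer_, k))
  nm$linker <- c(nm$linker, rep(FALSE, k))
  nm$kl <- c(nm$kl, rep(FALSE, k))
  nm$fixed <- c(nm$fixed, rep(FALSE, k))
  nm$cylinder <- c(nm$cylinder, rep(NA_integer_, k))
  nm$cyl_strand <- c(nm$cyl_strand, rep(NA_integer_, k))
  nm
}

# rebuild the strand table by following backbone pointers
recompute_strands <- function(nm, method = NULL) {
  n <- n_nucleotides(nm)
  seen <- logical(n)
  strands <- list()
  starts <- which(is.na(nm$prev))
  order_pool <- c(starts, seq_len(n))
  for (s0 in order_pool) {
    if (seen[s0]) next
    nts <- integer(0)
    cur <- s0
    repeat {
      nts <- c(nts, cur)
      seen[cur] <- TRUE
      cur <- nm$nxt[cur]
      if (is.na(cur) || cur == s0) break
      if (seen[cur]) break
    }
    circular <- !is.na(cur) && identical(cur, s0)
    strands[[length(strands) + 1L]] <- list(
      nts = nts, circular = circular, role = strand_role(nm, nts, method))
  }
  nm$strands <- strands
  nm
}

strand_role <- function(nm, nts, method) {
  if (is.null(method)) return("strand")
  if (method %in% c("st_rna", "xt_rna")) return("rna")
  if (method == "cc_dna") return("strand")
  if (any(nm$cyl_strand[nts] == 1L, na.rm = TRUE)) "scaffold" else "staple"
}

#' Reroute kissing-loop cylinders
#'
#' Rewires the mid-helix backbone of every kissing-loop-flagged cylinder so
#' that its two strand passes become two hairpins, one per endpoint,
#' meeting in the middle of the edge.  The central loop pairs (7 by
#' default) keep their pairing across the two hairpins - that retained
#' pairing is the 180-degree kissing-loop interaction - and are flagged
#' `kl`; the flanking bases (2 per side by default) are unpaired to give
#' the loops room.
#'
#' @param nm a `wf_nucleotide_model` (after [add_linkers()]).
#' @param model the `wf_cylinder_model`.
#' @param loop_pairs,flank kissing-loop motif dimensions (paired loop bases
#'   and unpaired flanking bases per hairpin).
#' @return the rewired model.
#' @export
reroute_kissing_loops <- function(nm, model, loop_pairs = 7L, flank = 2L) {
  kl_cyls <- which(vapply(model$cylinders, function(c) c$kissing_loop, logical(1L)))
  if (length(kl_cyls) == 0L) return(nm)
  min_bp <- loop_pairs + 2L * flank + 2L
  for (ci in kl_cyls) {
    bp <- model$cylinders[[ci]]$bp_count
    if (bp < min_bp) {
      stop(sprintf("kissing-loop cylinder %d has %d bp; the loop motif needs at least %d",
                   ci, bp, min_bp), call. = FALSE)
    }
    s1 <- pass_ids(nm, ci, 1L)
    s2 <- pass_ids(nm, ci, 2L)
    m <- bp %/% 2L
    # cut both passes at the middle and reconnect across: hairpin A keeps
    # the v-side halves, hairpin B the u-side halves
    nm$nxt[s1[m]] <- s2[m + 1L]
    nm$prev[s2[m + 1L]] <- s1[m]
    nm$nxt[s2[m]] <- s1[m + 1L]
    nm$prev[s1[m + 1L]] <- s2[m]
    # central loop pairs stay paired across the hairpins (the kissing
    # interaction); flanks are unpaired
    center <- (bp + 1) / 2
    lo <- ceiling(center - loop_pairs / 2)
    hi <- lo + loop_pairs - 1L
    lo <- max(1L, lo); hi <- min(bp, hi)
    kl_s1 <- s1[lo:hi]
    nm$kl[kl_s1] <- TRUE
    nm$kl[nm$pair[kl_s1]] <- TRUE
    for (f in c((lo - flank):(lo - 1L), (hi + 1L):(hi + flank))) {
      if (f < 1L || f > bp) next
      p <- nm$pair[s1[f]]
      nm$pair[s1[f]] <- NA_integer_
      if (!is.na(p)) nm$pair[p] <- NA_integer_
    }
  }
  recompute_strands(nm, model$method)
}

#' Nick cyclic strands into staples
#'
#' Breaks the long cyclic strands produced by linking into short linear
#' oligonucleotides.  Nicks are inserted at candidate bonds - helix ends at
#' the junctions for scaffolded methods, mid-helix (staggered) positions
#' for the scaffold-free cycle cover - maximising the nick count subject to
#' the stability rule: every contiguous binding domain of every resulting
#' strand against any one partner strand keeps at least `min_overlap`
#' paired bases.  Infeasible candidates are repaired greedily by removing
#' the nicks bounding the shortest illegal domain.  The scaffold strand is
#' never nicked; the single-stranded RNA methods instead receive exactly
#' one nick, at the 5' entry of the longest wireframe edge.  A cycle too
#' short to nick at all (shorter than twice `min_overlap`) is left circular
#' with a warning.
#'
#' @param nm a `wf_nucleotide_model` with its strand table populated.
#' @param model the `wf_cylinder_model` (provides method and nick edge).
#' @param min_overlap minimum binding-domain length in nt.
#' @return the nicked model; nucleotide count is conserved.
#' @export
nick_strands <- function(nm, model, min_overlap = 8L) {
  method <- model$method
  if (method %in% c("st_rna", "xt_rna")) {
    nick_e <- model$route$nick_edge
    cyl <- which(vapply(model$cylinders, function(c) c$edge == nick_e, logical(1L)))[1L]
    entry <- pass_ids(nm, cyl, 1L)[1L]
    p <- nm$prev[entry]
    if (!is.na(p)) {
      nm$nxt[p] <- NA_integer_
      nm$prev[entry] <- NA_integer_
    }
    return(recompute_strands(nm, method))
  }
  cuttable <- vapply(nm$strands, function(s) {
    s$circular && s$role != "scaffold"
  }, logical(1L))
  for (si in which(cuttable)) {
    nts <- nm$strands[[si]]$nts
    cands <- nick_candidates(nm, model, nts)
    if (length(nts) < 2L * min_overlap || length(cands) == 0L) {
      warning(sprintf("strand of %d nt left circular: no feasible nicking at min_overlap %d",
                      length(nts), min_overlap))
      next
    }
    keep <- repair_nicks(nm, nts, cands, min_overlap)
    for (b in keep) {
      j <- nm$nxt[b]
      nm$nxt[b] <- NA_integer_
      nm$prev[j] <- NA_integer_
    }
  }
  recompute_strands(nm, method)
}

# candidate bonds, as the 5'-side nucleotide id of each cut bond
nick_candidates <- function(nm, model, nts) {
  if (model$method == "cc_dna") {
    # staggered: middle of each strand pass through a cylinder
    cands <- integer(0)
    for (ci in unique(nm$cylinder[nts])) {
      if (is.na(ci)) next
      for (strand in 1:2) {
        ids <- intersect(pass_ids(nm, ci, strand), nts)
        if (length(ids) >= 2L) cands <- c(cands, ids[length(ids) %/% 2L])
      }
    }
    sort(cands)
  } else {
    # helix ends: the bond leaving the 3' end of each strand pass
    ends <- nts[!is.na(nm$cylinder[nts])]
    keep <- ends[vapply(ends, function(i) {
      j <- nm$nxt[i]
      is.na(nm$cylinder[j]) || nm$cylinder[j] != nm$cylinder[i] ||
        nm$cyl_strand[j] != nm$cyl_strand[i]
    }, logical(1L))]
    sort(keep)
  }
}

# greedy maximal nicking: start from all candidates, drop nicks bounding the
# shortest illegal binding domain until every domain is long enough
repair_nicks <- function(nm, nts, cands, min_overlap) {
  keep <- cands
  repeat {
    if (length(keep) <= 1L) return(integer(0))
    frag <- split_cycle(nts, keep)
    worst <- NULL; worst_len <- Inf
    for (f in frag) {
      doms <- binding_domains(nm, f$nts)
      bad <- doms[doms < min_overlap]
      if (length(bad) > 0L && min(bad) < worst_len) {
        worst_len <- min(bad); worst <- f
      }
      # a fragment with no pairing at all cannot bind its neighbours
      if (length(doms) == 0L && worst_len == Inf) worst <- f
    }
    if (is.null(worst)) return(keep)
    keep <- setdiff(keep, worst$bound_nick)
    if (length(keep) == 0L) return(integer(0))
  }
}

# fragments of the cycle `nts` cut at bonds after the ids in `keep`
split_cycle <- function(nts, keep) {
  n <- length(nts)
  cutpos <- sort(match(keep, nts))
  frags <- list()
  for (k in seq_along(cutpos)) {
    from <- cutpos[k] + 1L
    to <- if (k == length(cutpos)) cutpos[1L] + n else cutpos[k + 1L]
    ids <- nts[((seq(from, to) - 1L) %% n) + 1L]
    frags[[k]] <- list(nts = ids,
                       bound_nick = nts[cutpos[k]])
  }
  frags
}

# lengths of maximal consecutive paired runs of a strand fragment
binding_domains <- function(nm, ids) {
  doms <- integer(0)
  run <- 0L
  prev_pair <- NA_integer_
  for (i in ids) {
    p <- nm$pair[i]
    if (is.na(p)) {
      if (run > 0L) doms <- c(doms, run)
      run <- 0L
    } else if (run > 0L && !is.na(prev_pair) && abs(p - prev_pair) == 1L) {
      run <- run + 1L
    } else {
      if (run > 0L) doms <- c(doms, run)
      run <- 1L
    }
    prev_pair <- p
  }
  if (run > 0L) doms <- c(doms, run)
  doms
}
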