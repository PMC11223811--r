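# Primary-structure design: scaffold complementation, Focused Metropolis
# Search for scaffold-free designs, kissing-loop assignment, NUPACK export.

wc_complement <- function(bases, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  map <- if (alphabet == "DNA") {
    c(A = "T", T = "A", C = "G", G = "C", N = "N")
  } else {
    c(A = "U", U = "A", C = "G", G = "C", N = "N")
  }
  out <- map[bases]
  if (anyNA(out)) {
    stop("base(s) outside the ", alphabet, " alphabet: ",
         paste(unique(bases[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  unname(out)
}

model_alphabet <- function(nm, model = NULL) {
  if (!is.null(model) && model$geom$nucleic_acid == "RNA") "RNA" else "DNA"
}

strand_sequence <- function(nm, strand) {
  paste(nm$base[strand$nts], collapse = "")
}

#' Random nucleotide sequence
#'
#' @param n length in nt.
#' @param alphabet `"DNA"` or `"RNA"`.
#' @param gc expected GC fraction.
#' @return a character scalar.  Used to emulate a scaffold in tests and for
#'   the fully random RNA sequence mode; set the RNG seed beforehand for
#'   reproducibility.
#' @export
random_sequence <- function(n, alphabet = c("DNA", "RNA"), gc = 0.5) {
  alphabet <- match.arg(alphabet)
  letters4 <- if (alphabet == "DNA") c("A", "T", "G", "C") else c("A", "U", "G", "C")
  p <- c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)
  paste(sample(letters4, n, replace = TRUE, prob = p), collapse = "")
}

#' Assign a scaffold sequence and derive staples
#'
#' Writes the scaffold sequence 5'-to-3' along the scaffold strand
#' (commonly M13mp18 or a variant, or any user-supplied sequence), sets
#' every paired staple base to the Watson-Crick complement of its partner,
#' and fills unpaired staple linker bases with the linker policy base.
#'
#' @param nm a `wf_nucleotide_model` with a scaffold strand.
#' @param scaffold scaffold sequence (character scalar).
#' @param model the `wf_cylinder_model` (alphabet).
#' @param linker_base policy base for unpaired staple linkers.
#' @return the model with bases assigned.
#' @export
assign_scaffold <- function(nm, scaffold, model, linker_base = "T") {
  alpha <- model_alphabet(nm, model)
  roles <- vapply(nm$strands, function(s) s$role, character(1L))
  si <- which(roles == "scaffold")
  if (length(si) != 1L) stop("model has no unique scaffold strand", call. = FALSE)
  nts <- nm$strands[[si]]$nts
  sc <- strsplit(toupper(scaffold), "")[[1L]]
  if (length(sc) < length(nts)) {
    stop(sprintf("scaffold too short: %d nt supplied, %d required",
                 length(sc), length(nts)), call. = FALSE)
  }
  wc_complement(unique(sc), alpha)  # alphabet check
  nm$base[nts] <- sc[seq_along(nts)]
  paired <- nts[!is.na(nm$pair[nts])]
  nm$base[nm$pair[paired]] <- wc_complement(nm$base[paired], alpha)
  lk <- which(nm$linker & is.na(nm$pair) & nm$base == "N")
  nm$base[lk] <- linker_base
  nm
}

#' Longest repeated substring across a set of strands
#'
#' Length of the longest string that occurs at least twice, at distinct
#' positions, among the substrings of the given strands; only substrings
#' wholly inside one strand count (occurrences may sit in different
#' strands).  This is the objective the Focused Metropolis Search minimises
#' to suppress non-specific pairings.  Computed by binary search on the
#' length with a vectorised duplicate scan of all k-mers.
#'
#' @param strands character vector of sequences.
#' @return integer length (0 when nothing repeats).
#' @export
longest_repeated_substring <- function(strands) {
  strands <- strands[nchar(strands) > 0L]
  if (length(strands) == 0L) return(0L)
  has_repeat <- function(k) {
    km <- unlist(lapply(strands, function(s) {
      n <- nchar(s)
      if (n < k) return(character(0))
      substring(s, 1:(n - k + 1L), k:n)
    }))
    anyDuplicated(km) > 0L
  }
  lo <- 0L
  hi <- max(nchar(strands))
  while (lo < hi) {
    mid <- as.integer((lo + hi + 1L) %/% 2L)
    if (has_repeat(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

# positions (strand index, offset) of occurrences of some longest repeated
# substring; NULL when nothing repeats
lrs_occurrences <- function(strands, k) {
  if (k == 0L) return(NULL)
  si <- integer(0); off <- integer(0); km <- character(0)
  for (s in seq_along(strands)) {
    n <- nchar(strands[s])
    if (n < k) next
    kms <- substring(strands[s], 1:(n - k + 1L), k:n)
    si <- c(si, rep(s, length(kms)))
    off <- c(off, seq_along(kms))
    km <- c(km, kms)
  }
  dup <- unique(km[duplicated(km)])
  if (length(dup) == 0L) return(NULL)
  keep <- km %in% dup
  cbind(si[keep], off[keep])
}

gc_fraction <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(NA_real_)
  gc <- nchar(gsub("[^GC]", "", seq))
  gc / n
}

has_forbidden <- function(seqs, forbidden) {
  if (length(forbidden) == 0L) return(FALSE)
  any(vapply(forbidden, function(f) any(grepl(f, seqs, fixed = TRUE)),
             logical(1L)))
}

#' Focused Metropolis Search sequence design
#'
#' Designs the primary structure of a scaffold-free (cycle-cover) model by
#' local search: starting from a random complementarity-respecting
#' assignment, it repeatedly mutates one free base (with probability
#' `focus` choosing a position inside an occurrence of a current longest
#' repeated substring), propagates the Watson-Crick complement, rejects
#' moves that violate the hard constraints (GC bounds per strand, forbidden
#' subsequences, fixed bases), and accepts by the Metropolis rule on the
#' longest-repeated-substring objective at fixed temperature.  The
#' best-so-far assignment is returned, so the reported objective is
#' monotone non-increasing in the iteration count and runs are reproducible
#' under a fixed seed.
#'
#' @param nm a `wf_nucleotide_model` with strands and pairing fixed.
#' @param params a [design_parameters()] (GC bounds, forbidden
#'   subsequences, linker policy).
#' @param model the `wf_cylinder_model` (alphabet).
#' @param seed RNG seed.
#' @param max_iters Metropolis iterations.
#' @param temperature fixed Metropolis temperature.
#' @param focus probability of a focused (inside-a-repeat) move.
#' @return the model with designed bases; attribute `objective_trace` holds
#'   the best objective after each iteration.
#' @export
fms_optimize <- function(nm, params, model, seed = params$seed,
                         max_iters = 2000L, temperature = 0.5, focus = 0.9) {
  set.seed(seed)
  alpha <- model_alphabet(nm, model)
  letters4 <- if (alpha == "DNA") c("A", "T", "G", "C") else c("A", "U", "G", "C")
  n <- n_nucleotides(nm)
  fixed <- nm$fixed
  if (params$linker_policy != "N") {
    lk <- nm$linker & is.na(nm$pair) & !fixed
    nm$base[lk] <- params$linker_policy
    fixed[lk] <- TRUE
  }
  # representative = itself for unpaired, lower id of each pair
  free <- which(!fixed & (is.na(nm$pair) | seq_len(n) < nm$pair))
  free <- free[!fixed[free]]
  # initial assignment at the midpoint of the GC bounds
  gc0 <- mean(params$gc_bounds)
  p <- c((1 - gc0) / 2, (1 - gc0) / 2, gc0 / 2, gc0 / 2)
  init <- nm$base == "N"
  for (i in free) {
    if (!init[i]) next
    nm$base[i] <- sample(letters4, 1L, prob = p)
  }
  paired_free <- free[!is.na(nm$pair[free])]
  nm$base[nm$pair[paired_free]] <- wc_complement(nm$base[paired_free], alpha)
  stray <- which(nm$base == "N")
  nm$base[stray] <- sample(letters4, length(stray), replace = TRUE, prob = p)

  strand_of <- integer(n)
  for (si in seq_along(nm$strands)) strand_of[nm$strands[[si]]$nts] <- si
  pos_in_strand <- integer(n)
  for (si in seq_along(nm$strands)) {
    pos_in_strand[nm$strands[[si]]$nts] <- seq_along(nm$strands[[si]]$nts)
  }
  seqs <- vapply(nm$strands, function(s) strand_sequence(nm, s), character(1L))
  ok_hard <- function(seqs, strand_ids) {
    for (si in strand_ids) {
      g <- gc_fraction(seqs[si])
      if (!is.na(g) && (g < params$gc_bounds[1L] - 1e-9 ||
                        g > params$gc_bounds[2L] + 1e-9)) return(FALSE)
    }
    !has_forbidden(seqs[strand_ids], params$forbidden_subsequences)
  }
  # initial repair: mutate random positions of violating strands
  for (rep_try in seq_len(200L)) {
    bad <- which(!vapply(seq_along(seqs), function(si) ok_hard(seqs, si), logical(1L)))
    if (length(bad) == 0L) break
    for (si in bad) {
      cand <- intersect(nm$strands[[si]]$nts, c(free, nm$pair[free]))
      cand <- cand[!fixed[cand]]
      if (length(cand) == 0L) {
        stop("sequence constraints unsatisfiable for strand ", si, call. = FALSE)
      }
      i <- sample(cand, 1L)
      g <- gc_fraction(seqs[si])
      want_gc <- !is.na(g) && g < params$gc_bounds[1L]
      pool <- if (want_gc) c("G", "C") else setdiff(letters4, c("G", "C"))
      if (has_forbidden(seqs[si], params$forbidden_subsequences)) pool <- letters4
      newb <- sample(setdiff(pool, nm$base[i]), 1L)
      nm <- apply_base(nm, i, newb, alpha)
      seqs <- update_seqs(nm, seqs, strand_of, i)
    }
  }
  if (!all(vapply(seq_along(seqs), function(si) ok_hard(seqs, si), logical(1L)))) {
    stop("could not satisfy GC/forbidden-subsequence constraints at initialisation",
         call. = FALSE)
  }

  mutable <- c(free, stats::na.omit(nm$pair[free]))
  mutable <- unique(mutable[!fixed[mutable]])
  cur_obj <- longest_repeated_substring(seqs)
  best <- list(obj = cur_obj, base = nm$base)
  trace <- numeric(max_iters)
  occ <- lrs_occurrences(seqs, cur_obj)
  for (it in seq_len(max_iters)) {
    i <- NA_integer_
    if (!is.null(occ) && stats::runif(1L) < focus) {
      o <- occ[sample(nrow(occ), 1L), ]
      k <- cur_obj
      ids <- nm$strands[[o[1L]]]$nts[o[2L] + sample.int(k, 1L) - 1L]
      if (!fixed[ids]) i <- ids
    }
    if (is.na(i)) i <- mutable[sample.int(length(mutable), 1L)]
    oldb <- nm$base[i]
    newb <- sample(setdiff(letters4, oldb), 1L)
    nm2 <- apply_base(nm, i, newb, alpha)
    seqs2 <- update_seqs(nm2, seqs, strand_of, i)
    touched <- unique(c(strand_of[i],
                        if (!is.na(nm$pair[i])) strand_of[nm$pair[i]]))
    if (ok_hard(seqs2, touched)) {
      obj2 <- longest_repeated_substring(seqs2)
      d <- obj2 - cur_obj
      if (d <= 0 || stats::runif(1L) < exp(-d / temperature)) {
        nm <- nm2; seqs <- seqs2; cur_obj <- obj2
        occ <- lrs_occurrences(seqs, cur_obj)
        if (cur_obj < best$obj) best <- list(obj = cur_obj, base = nm$base)
      }
    }
    trace[it] <- best$obj
  }
  nm$base <- best$base
  attr(nm, "objective_trace") <- trace
  attr(nm, "objective") <- best$obj
  nm
}

apply_base <- function(nm, i, b, alpha) {
  nm$base[i] <- b
  p <- nm$pair[i]
  if (!is.na(p)) nm$base[p] <- wc_complement(b, alpha)
  nm
}

update_seqs <- function(nm, seqs, strand_of, i) {
  ids <- c(i, nm$pair[i])
  ids <- ids[!is.na(ids)]
  for (si in unique(strand_of[ids])) {
    seqs[si] <- strand_sequence(nm, nm$strands[[si]])
  }
  seqs
}

#' Kissing-loop sequence table
#'
#' Reads a table of mutually compatible 180-degree kissing-loop sequence
#' pairs (TSV with columns `id`, `seq_a`, `seq_b`).  The bundled table is a
#' synthetic, deterministic fixture of complementary 7-nt loop pairs; users
#' replace it with their own validated list.
#'
#' @param path TSV path; `NULL` loads the bundled synthetic table.
#' @return a data.frame with columns `id`, `seq_a`, `seq_b`.
#' @export
kissing_loop_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "kissing_loops_synthetic.tsv",
                        package = "wirefold", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("id", "seq_a", "seq_b") %in% names(tab)))
  tab
}

#' Assign kissing-loop sequences from a pre-generated table
#'
#' Gives each kissing-loop pair of the model a distinct entry from the
#' table: `seq_a` is written 5'-to-3' on the loop of one hairpin and the
#' paired loop bases of the partner hairpin receive the complementary
#' table sequence.  Assigned positions are pinned (`fixed`) so later
#' sequence design leaves them alone.
#'
#' @param nm a `wf_nucleotide_model` after [reroute_kissing_loops()].
#' @param model the `wf_cylinder_model`.
#' @param table a [kissing_loop_table()].
#' @return the model with kissing-loop bases set.
#' @export
assign_kissing_loops <- function(nm, model, table = kissing_loop_table()) {
  alpha <- model_alphabet(nm, model)
  kl_cyls <- which(vapply(model$cylinders, function(c) c$kissing_loop, logical(1L)))
  if (length(kl_cyls) == 0L) return(nm)
  if (length(kl_cyls) > nrow(table)) {
    stop(sprintf("%d kissing loops but the table has only %d pairs",
                 length(kl_cyls), nrow(table)), call. = FALSE)
  }
  for (k in seq_along(kl_cyls)) {
    ci <- kl_cyls[k]
    ids <- intersect(pass_ids(nm, ci, 1L), which(nm$kl))
    sq <- strsplit(toupper(table$seq_a[k]), "")[[1L]]
    if (length(ids) != length(sq)) {
      stop(sprintf("kissing-loop motif of cylinder %d has %d bases; table entry %s has %d",
                   ci, length(ids), table$id[k], length(sq)), call. = FALSE)
    }
    nm$base[ids] <- sq
    nm$fixed[ids] <- TRUE
    partners <- nm$pair[ids]
    nm$base[partners] <- wc_complement(sq, alpha)
    nm$fixed[partners] <- TRUE
  }
  nm
}

#' Fill remaining bases randomly, respecting complementarity
#'
#' Fully random primary structure (the default for Xuong-tree RNA designs
#' and an option for spanning-tree RNA): every unassigned base gets a
#' uniform random letter, paired partners the Watson-Crick complement;
#' fixed and already-assigned bases are untouched.
#'
#' @param nm a `wf_nucleotide_model`.
#' @param model the `wf_cylinder_model`.
#' @param seed RNG seed.
#' @param linker_base policy base for unpaired linkers (`"N"` leaves them
#'   random).
#' @return the model with all bases assigned.
#' @export
assign_random_sequences <- function(nm, model, seed = 1L, linker_base = "U") {
  set.seed(seed)
  alpha <- model_alphabet(nm, model)
  letters4 <- if (alpha == "DNA") c("A", "T", "G", "C") else c("A", "U", "G", "C")
  if (linker_base != "N") {
    lk <- which(nm$linker & is.na(nm$pair) & nm$base == "N")
    nm$base[lk] <- linker_base
  }
  todo <- which(nm$base == "N")
  for (i in todo) {
    if (nm$base[i] != "N") next
    nm$base[i] <- sample(letters4, 1L)
    p <- nm$pair[i]
    if (!is.na(p)) nm$base[p] <- wc_complement(nm$base[i], alpha)
  }
  nm
}

#' Export a NUPACK design specification
#'
#' Writes a NUPACK-4-style design text for the model: per strand, its
#' dot-paren secondary structure (nested within-strand pairs only;
#' kissing-loop interactions are expressed as fixed-letter domains, not
#' bracket pairs) and a per-position sequence constraint line with fixed
#' letters at pinned positions and `N` elsewhere.  Pairings that cannot be
#' written without pseudoknots raise an error listing the offending pairs.
#'
#' @param nm a `wf_nucleotide_model`.
#' @param path optional output file.
#' @return the design text (invisibly when written to a file).
#' @export
export_nupack <- function(nm, path = NULL) {
  lines <- c("# NUPACK design specification", "# material = rna")
  for (si in seq_along(nm$strands)) {
    s <- nm$strands[[si]]
    nts <- s$nts
    posmap <- integer(n_nucleotides(nm))
    posmap[nts] <- seq_along(nts)
    dp <- rep(".", length(nts))
    offending <- character(0)
    open <- integer(0)
    for (k in seq_along(nts)) {
      i <- nts[k]
      p <- nm$pair[i]
      if (is.na(p) || nm$kl[i]) next
      if (posmap[p] == 0L) {
        offending <- c(offending, sprintf("%d-%d (cross-strand)", i, p))
        next
      }
      if (posmap[p] > k) {
        dp[k] <- "("
        open <- c(open, posmap[p])
      } else {
        dp[k] <- ")"
        if (length(open) == 0L || open[length(open)] != k) {
          offending <- c(offending, sprintf("%d-%d (pseudoknot)", p, i))
        } else {
          open <- open[-length(open)]
        }
      }
    }
    if (length(offending) > 0L) {
      stop("pairings not expressible in dot-paren notation: ",
           paste(offending, collapse = ", "), call. = FALSE)
    }
    cons <- ifelse(nm$fixed[nts] & nm$base[nts] != "N", nm$base[nts], "N")
    lines <- c(lines,
               sprintf("structure strand%d = %s", si, paste(dp, collapse = "")),
               sprintf("sequence strand%d = %s", si, paste(cons, collapse = "")))
  }
  txt <- paste(c(lines, ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(txt))
  }
  txt
}

#' Import designed sequences (NUPACK output)
#'
#' Reads one sequence per strand - plain lines or `sequence <name> = <seq>`
#' records, `#` comments ignored - in the model's strand order and applies
#' them, erroring on a length mismatch.
#'
#' @param nm a `wf_nucleotide_model`.
#' @param text character scalar or vector of lines.
#' @return the model with bases replaced.
#' @export
import_nupack <- function(nm, text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  seqs <- toupper(sub("^.*=", "", lines))
  seqs <- gsub("[ \t]", "", seqs)
  if (length(seqs) != length(nm$strands)) {
    stop(sprintf("%d sequences supplied for %d strands", length(seqs),
                 length(nm$strands)), call. = FALSE)
  }
  for (si in seq_along(seqs)) {
    nts <- nm$strands[[si]]$nts
    if (nchar(seqs[si]) != length(nts)) {
      stop(sprintf("strand %d: sequence length %d != strand length %d",
                   si, nchar(seqs[si]), length(nts)), call. = FALSE)
    }
    nm$base[nts] <- strsplit(seqs[si], "")[[1L]]
  }
  nm
}
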