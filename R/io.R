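# Exporters: oxDNA legacy topology/configuration pair, UNF JSON, CSV strand
# list; plus small text readers (FASTA scaffolds, route edge lists).

#' Write a nucleotide model as an oxDNA topology/configuration pair
#'
#' Legacy two-file oxDNA format.  Nucleotides are written in strand order,
#' 5'-to-3' within each strand, with file indices 0-based.  Topology rows
#' are `strand base n3 n5` where `n3`/`n5` are the indices of the 3'- and
#' 5'-neighbours (-1 at linear strand ends; circular strands wrap their
#' index chain).  The configuration carries position, the backbone-to-base
#' versor `a1` and the 3'-to-5' axis versor `a3`, and zero velocities.
#' Coordinates are written in nanometres.
#'
#' @param nm a `wf_nucleotide_model`.
#' @param box_size cubic box edge (nm); default 1.5 x the bounding-box
#'   diagonal.  An error proposes a larger box if nucleotides fall outside.
#' @param top_path,dat_path optional output files.
#' @return list with `top` and `dat` character scalars.
#' @export
write_oxdna <- function(nm, box_size = NULL, top_path = NULL, dat_path = NULL) {
  ord <- unlist(lapply(nm$strands, function(s) s$nts))
  n <- length(ord)
  idx0 <- integer(n_nucleotides(nm))
  idx0[ord] <- seq_len(n) - 1L
  diag_len <- if (n == 0L) 0 else
    vnorm(apply(nm$pos[ord, , drop = FALSE], 2L, max) -
            apply(nm$pos[ord, , drop = FALSE], 2L, min))
  if (is.null(box_size)) box_size <- max(1, 1.5 * diag_len)
  ext <- if (n == 0L) 0 else
    max(apply(nm$pos[ord, , drop = FALSE], 2L, max) -
          apply(nm$pos[ord, , drop = FALSE], 2L, min))
  if (ext > box_size) {
    stop(sprintf("structure spans %.1f nm, outside the %.1f nm box; use box_size >= %.1f",
                 ext, box_size, 1.5 * diag_len), call. = FALSE)
  }
  top <- character(n + 1L)
  top[1L] <- sprintf("%d %d", n, length(nm$strands))
  dat <- character(n + 3L)
  dat[1L] <- "t = 0"
  dat[2L] <- sprintf("b = %.6f %.6f %.6f", box_size, box_size, box_size)
  dat[3L] <- "E = 0 0 0"
  row <- 1L
  for (si in seq_along(nm$strands)) {
    s <- nm$strands[[si]]
    for (k in seq_along(s$nts)) {
      i <- s$nts[k]
      n3 <- nm$nxt[i]   # neighbour toward the 3' end
      n5 <- nm$prev[i]
      top[row + 1L] <- sprintf("%d %s %d %d", si, nm$base[i],
                               if (is.na(n3)) -1L else idx0[n3],
                               if (is.na(n5)) -1L else idx0[n5])
      dat[row + 3L] <- paste(sprintf("%.8f", c(nm$pos[i, ], nm$a1[i, ],
                                               nm$a3[i, ],
                                               rep(0, 6))), collapse = " ")
      row <- row + 1L
    }
  }
  out <- list(top = paste(c(top, ""), collapse = "\n"),
              dat = paste(c(dat, ""), collapse = "\n"))
  if (!is.null(top_path)) writeLines(top, top_path)
  if (!is.null(dat_path)) writeLines(dat, dat_path)
  out
}

#' Read an oxDNA topology/configuration pair
#'
#' Inverse of [write_oxdna()]: returns a `wf_nucleotide_model` with bases,
#' backbone connectivity (including circular strands), positions and
#' orientation vectors; base pairing is not stored in the format and is
#' left unset.
#'
#' @param top,dat topology and configuration documents (text or file paths
#'   when `is_path`).
#' @param is_path treat inputs as file paths.
#' @return a `wf_nucleotide_model`.
#' @export
read_oxdna <- function(top, dat, is_path = FALSE) {
  tl <- if (is_path) readLines(top) else unlist(strsplit(top, "\n"))
  dl <- if (is_path) readLines(dat) else unlist(strsplit(dat, "\n"))
  tl <- tl[nzchar(trimws(tl))]
  dl <- dl[nzchar(trimws(dl))]
  hdr <- as.integer(strsplit(trimws(tl[1L]), "[ \t]+")[[1L]])
  n <- hdr[1L]
  if (length(tl) - 1L != n) stop("topology header count mismatch", call. = FALSE)
  nm <- new_nucleotide_model(n)
  strand_id <- integer(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(tl[i + 1L]), "[ \t]+")[[1L]]
    strand_id[i] <- as.integer(f[1L])
    nm$base[i] <- f[2L]
    n3 <- as.integer(f[3L]); n5 <- as.integer(f[4L])
    nm$nxt[i] <- if (n3 < 0L) NA_integer_ else n3 + 1L
    nm$prev[i] <- if (n5 < 0L) NA_integer_ else n5 + 1L
  }
  conf <- dl[-(1:3)]
  if (length(conf) != n) stop("configuration record count mismatch", call. = FALSE)
  for (i in seq_len(n)) {
    v <- as.numeric(strsplit(trimws(conf[i]), "[ \t]+")[[1L]])
    nm$pos[i, ] <- v[1:3]
    nm$a1[i, ] <- v[4:6]
    nm$a3[i, ] <- v[7:9]
  }
  recompute_strands(nm)
}

#' Write a nucleotide model as a UNF document
#'
#' Minimal documented subset of the Unified Nanotechnology Format: a JSON
#' document with format/version fields and one lattice-free structure whose
#' strands carry per-nucleotide geometry (position, `a1`, `a3` in nm),
#' connectivity and pairing.  Version is pinned to `"1.0.0"`.
#'
#' @param nm a `wf_nucleotide_model`.
#' @param name design name recorded in the document.
#' @param na_type `"DNA"` or `"RNA"`.
#' @param path optional output file.
#' @return the JSON text (invisibly when written to a file).
#' @export
write_unf <- function(nm, name = "wirefold design", na_type = "DNA",
                      path = NULL) {
  strands <- lapply(seq_along(nm$strands), function(si) {
    s <- nm$strands[[si]]
    list(
      id = si - 1L,
      name = sprintf("strand%d", si),
      naType = na_type,
      role = s$role,
      isCircular = s$circular,
      fivePrimeId = s$nts[1L] - 1L,
      threePrimeId = s$nts[length(s$nts)] - 1L,
      nucleotides = lapply(s$nts, function(i) {
        list(id = i - 1L,
             nbAbbrev = nm$base[i],
             pair = if (is.na(nm$pair[i])) -1L else nm$pair[i] - 1L,
             prev = if (is.na(nm$prev[i])) -1L else nm$prev[i] - 1L,
             next_ = if (is.na(nm$nxt[i])) -1L else nm$nxt[i] - 1L,
             altPositions = list(as.numeric(nm$pos[i, ])),
             altOrientations = list(list(a1 = as.numeric(nm$a1[i, ]),
                                         a3 = as.numeric(nm$a3[i, ]))))
      }))
  })
  doc <- list(format = "unf", version = "1.0.0", name = name,
              lengthUnits = "nm",
              idCounter = n_nucleotides(nm),
              structures = list(list(id = 0L, name = name,
                                     naStrands = strands)))
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' Write the strand sequences as CSV
#'
#' One row per strand with columns `name`, `length`, `sequence` (5'-to-3')
#' and `role` (`;circular` appended for cyclic strands); RFC 4180 quoting.
#' Unassigned (`N`) bases are an error unless `allow_N`.
#'
#' @param nm a `wf_nucleotide_model`.
#' @param path optional output file.
#' @param allow_N permit undesigned bases.
#' @return the CSV text (invisibly when written to a file).
#' @export
write_strand_csv <- function(nm, path = NULL, allow_N = FALSE) {
  seqs <- vapply(nm$strands, function(s) strand_sequence(nm, s), character(1L))
  if (!allow_N && any(grepl("N", seqs, fixed = TRUE))) {
    stop("model contains unassigned (N) bases; design sequences first or set allow_N = TRUE",
         call. = FALSE)
  }
  df <- data.frame(
    name = sprintf("strand%d", seq_along(nm$strands)),
    length = vapply(nm$strands, function(s) length(s$nts), integer(1L)),
    sequence = seqs,
    role = vapply(nm$strands, function(s) {
      paste0(s$role, if (s$circular) ";circular" else "")
    }, character(1L)),
    stringsAsFactors = FALSE)
  con <- textConnection("csvout", "w", local = TRUE)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  txt <- paste(c(csvout, ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(csvout, path)
    return(invisible(txt))
  }
  txt
}

#' Read the first sequence of a FASTA file
#'
#' @param path FASTA file; the first record's sequence is returned
#'   (scaffolds are single-record files in practice).
#' @return a character scalar, uppercase.
#' @export
read_fasta_sequence <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0L) {
    seq <- paste(lines, collapse = "")
  } else {
    to <- if (length(hdr) > 1L) hdr[2L] - 1L else length(lines)
    seq <- paste(lines[(hdr[1L] + 1L):to], collapse = "")
  }
  toupper(gsub("[^A-Za-z]", "", seq))
}

#' Export / import a route as a plain-text edge list
#'
#' One `u v` vertex pair per line in traversal order, `#` comments allowed;
#' the format used for manual A-trail import.
#'
#' @param route a `wf_route`.
#' @param graph its `wf_graph`.
#' @param path optional output file.
#' @return the text (invisibly when written to a file).
#' @export
write_route_txt <- function(route, graph, path = NULL) {
  tr <- route$traversals
  lines <- c(sprintf("# wirefold route, method %s", route$method),
             vapply(seq_len(nrow(tr)), function(i) {
               sprintf("%d %d", tr$from[i],
                       other_end(graph, tr$edge[i], tr$from[i]))
             }, character(1L)))
  txt <- paste(c(lines, ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(txt))
  }
  txt
}

#' @rdname write_route_txt
#' @param text route text (or a path when `is_path`).
#' @param is_path treat `text` as a file path.
#' @return `read_route_txt`: an m x 2 integer matrix of vertex pairs.
#' @export
read_route_txt <- function(text, is_path = FALSE) {
  lines <- if (is_path) readLines(text, warn = FALSE) else
    unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  do.call(rbind, lapply(lines, function(l) {
    as.integer(strsplit(l, "[ \t]+")[[1L]][1:2])
  }))
}
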