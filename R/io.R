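#' Read a counts file
#'
#' Parses the tab-separated counts-file dialect used by polymorphism-aware
#' tools: a header line `COUNTSFILE NPOP <n> NSITES <m>`, a column-header
#' line `CHROM POS <pop1> <pop2> ...`, then one row per site whose cells
#' are comma-separated allele counts in alphabet order (A,C,G,T for
#' nucleotides), e.g. `3,0,7,0`.  An all-zero cell (`0,0,0,0`) is a
#' missing observation, not an error — real resequencing data contain
#' failed sites.  A mismatch between the header's NSITES and the parsed
#' row count produces a warning and the parsed data are trusted.
#'
#' @param path Path to a counts file.
#' @param alphabet Allele symbols (default nucleotides).
#' @return A [pomo_counts()] alignment.
#' @export
read_counts <- function(path, alphabet = c("A", "C", "G", "T")) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L)
    stop("counts file too short: need header and column lines", call. = FALSE)
  hd <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(hd) < 5L || toupper(hd[1L]) != "COUNTSFILE" ||
      toupper(hd[2L]) != "NPOP" || toupper(hd[4L]) != "NSITES")
    stop("malformed counts header (line 1): expected ",
         "'COUNTSFILE NPOP <n> NSITES <m>'", call. = FALSE)
  npop <- suppressWarnings(as.integer(hd[3L]))
  nsites_hdr <- suppressWarnings(as.integer(hd[5L]))
  if (is.na(npop) || is.na(nsites_hdr))
    stop("malformed counts header (line 1): NPOP/NSITES not integers",
         call. = FALSE)
  cols <- strsplit(trimws(lines[[2L]]), "\\s+")[[1L]]
  if (length(cols) != npop + 2L)
    stop("column header (line 2) has ", length(cols),
         " fields; expected CHROM POS plus ", npop, " populations",
         call. = FALSE)
  pops <- cols[-(1:2)]

  body <- lines[-(1:2)]
  n <- length(body)
  A <- length(alphabet)
  counts <- lapply(pops, function(p) matrix(0L, n, A))
  names(counts) <- pops
  chrom <- character(n); pos <- integer(n)
  for (r in seq_len(n)) {
    fields <- strsplit(trimws(body[[r]]), "\\s+")[[1L]]
    if (length(fields) != npop + 2L)
      stop("ragged row at line ", r + 2L, ": ", length(fields),
           " fields, expected ", npop + 2L, call. = FALSE)
    chrom[r] <- fields[1L]
    pos[r] <- suppressWarnings(as.integer(fields[2L]))
    for (k in seq_len(npop)) {
      cell <- strsplit(fields[k + 2L], ",", fixed = TRUE)[[1L]]
      v <- suppressWarnings(as.integer(cell))
      if (length(v) != A || anyNA(v) || any(v < 0))
        stop("non-integer or malformed counts cell at line ", r + 2L,
             ", population '", pops[k], "': '", fields[k + 2L], "'",
             call. = FALSE)
      counts[[k]][r, ] <- v
    }
  }
  if (!is.na(nsites_hdr) && nsites_hdr != n)
    warning("header declares NSITES ", nsites_hdr, " but ", n,
            " site rows were parsed; trusting the parsed data",
            call. = FALSE)
  pomo_counts(counts, alphabet = alphabet, chrom = chrom, pos = pos)
}

#' Write a counts file
#'
#' Emits the canonical dialect read by [read_counts()]: header
#' `COUNTSFILE NPOP <n> NSITES <m>`, column-header line, tab-separated
#' site rows with comma-separated counts per population.
#'
#' @param aln A [pomo_counts()] alignment.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_counts <- function(aln, path) {
  stopifnot(inherits(aln, "pomo_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("COUNTSFILE NPOP %d NSITES %d",
                     length(aln$populations), aln$n_sites), con)
  writeLines(paste(c("CHROM", "POS", aln$populations), collapse = "\t"), con)
  if (aln$n_sites > 0L) {
    cells <- lapply(aln$counts, function(m)
      do.call(paste, c(asplit(m, 2L), sep = ",")))
    rows <- do.call(paste, c(list(aln$chrom, aln$pos), cells, sep = "\t"))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Convert per-population FASTA alignments to allele counts
#'
#' Each population is an aligned FASTA file of individual haplotypes; all
#' sequences (within and across populations) must have equal length.  At
#' each site the unambiguous nucleotides A, C, G, T are counted per
#' population; gaps and IUPAC ambiguity codes (including N) contribute
#' nothing, so an all-gap or all-ambiguous column becomes a missing
#' observation for that population.
#'
#' @param fasta_paths Named character vector: `population name = path`.
#' @return A [pomo_counts()] alignment.
#' @export
fasta_to_counts <- function(fasta_paths) {
  if (is.null(names(fasta_paths)) || any(names(fasta_paths) == ""))
    stop("'fasta_paths' must be named by population", call. = FALSE)
  alphabet <- c("A", "C", "G", "T")
  mats <- lapply(fasta_paths, function(p) {
    seqs <- as.character(ape::read.FASTA(p))
    lens <- lengths(seqs)
    if (length(unique(lens)) != 1L)
      stop("sequences in '", p, "' have unequal lengths", call. = FALSE)
    toupper(do.call(rbind, seqs))
  })
  lens <- vapply(mats, ncol, 1L)
  if (length(unique(lens)) != 1L)
    stop("aligned sequence lengths differ across populations: ",
         paste(lens, collapse = ", "), call. = FALSE)
  counts <- lapply(mats, function(ch) {
    sapply(alphabet, function(a) colSums(ch == a))
  })
  counts <- lapply(counts, function(m) {
    m <- matrix(as.integer(m), ncol = length(alphabet),
                dimnames = list(NULL, alphabet))
    m
  })
  pomo_counts(counts, alphabet = alphabet)
}

#' Read and write Newick trees
#'
#' Thin wrappers around the ape parser: `read_newick()` accepts a file
#' path or a literal Newick string (quoted labels and comments tolerated);
#' `write_newick()` emits branch lengths with 12 significant digits so
#' round-trips are lossless at working precision.  Edges without a branch
#' length are read as 0 with a warning.
#'
#' @param x Path or Newick string (`read_newick`); a `phylo` tree
#'   (`write_newick`).
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return A `phylo` tree, or a Newick string / path.
#' @export
read_newick <- function(x) {
  tr <- if (length(x) == 1L && grepl("\\(", x) && grepl(";", x))
    ape::read.tree(text = x)
  else
    ape::read.tree(x)
  if (is.null(tr))
    stop("Newick parse failed (unbalanced parentheses or empty input)",
         call. = FALSE)
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; using 0", call. = FALSE)
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    warning("missing branch lengths read as 0", call. = FALSE)
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  tr
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  s <- newick_string(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(path)
}

# recursive Newick serializer with %.12g branch lengths
newick_string <- function(tree) {
  root <- setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])[1L]
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  rec <- function(node) {
    es <- kids[[as.character(node)]]
    if (is.null(es)) return(tree$tip.label[node])
    parts <- vapply(es, function(e) {
      child <- tree$edge[e, 2L]
      sprintf("%s:%.12g", rec(child), tree$edge.length[e])
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(root), ";")
}
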