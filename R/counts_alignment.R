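#' Allele-count alignment
#'
#' Container for per-population, per-site nucleotide counts, the data `D`
#' of a polymorphism-aware analysis.  Sites are assumed independent
#' (composite likelihood, free recombination), so the likelihood engine
#' works on compressed site patterns.
#'
#' @param counts Named list, one element per population, each a
#'   `n_sites x |A|` matrix of nonnegative integer allele counts in
#'   alphabet order.  An all-zero row marks a missing observation.
#' @param alphabet Allele symbols (default nucleotides).
#' @param chrom,pos Optional per-site coordinates (recorded, not
#'   interpreted).
#' @return An object of class `pomo_counts` with fields `populations`,
#'   `counts`, `alphabet`, `n_sites`, `chrom`, `pos`.
#' @examples
#' a <- pomo_counts(list(p1 = rbind(c(10,0,0,0), c(9,1,0,0)),
#'                       p2 = rbind(c(10,0,0,0), c(0,10,0,0))))
#' a
#' @export
pomo_counts <- function(counts, alphabet = c("A", "C", "G", "T"),
                        chrom = NULL, pos = NULL) {
  if (!is.list(counts) || length(counts) == 0L)
    stop("'counts' must be a nonempty named list of matrices", call. = FALSE)
  pops <- names(counts)
  if (is.null(pops) || anyDuplicated(pops) || any(pops == ""))
    stop("populations must have unique nonempty names", call. = FALSE)
  counts <- lapply(counts, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    if (ncol(m) != length(alphabet))
      stop("each counts matrix needs one column per allele", call. = FALSE)
    if (any(m < 0 | is.na(m)))
      stop("allele counts must be nonnegative integers", call. = FALSE)
    dimnames(m) <- list(NULL, alphabet)
    m
  })
  ns <- vapply(counts, nrow, 1L)
  if (length(unique(ns)) != 1L)
    stop("all populations must cover the same sites", call. = FALSE)
  n_sites <- ns[[1L]]
  if (is.null(chrom)) chrom <- rep("NA", n_sites)
  if (is.null(pos)) pos <- seq_len(n_sites)
  structure(list(populations = pops, counts = counts,
                 alphabet = as.character(alphabet), n_sites = n_sites,
                 chrom = as.character(chrom), pos = as.integer(pos)),
            class = "pomo_counts")
}

#' @export
print.pomo_counts <- function(x, ...) {
  cat(sprintf("Allele-count alignment: %d populations, %d sites\n",
              length(x$populations), x$n_sites))
  cat("  populations:", paste(utils::head(x$populations, 8),
                              collapse = ", "),
      if (length(x$populations) > 8) "...", "\n")
  invisible(x)
}

#' Compress an alignment into unique site patterns
#'
#' Patterns are keyed on the full tuple of per-population count vectors;
#' the weights are the multiplicities, so weighted sums over patterns
#' reproduce sums over sites exactly.
#'
#' @param aln A [pomo_counts()] alignment.
#' @return List with `counts` (per-population matrices of unique
#'   patterns), `weights` (multiplicities summing to `n_sites`) and
#'   `pattern_of_site` (index of each original site's pattern).
#' @export
compress_patterns <- function(aln) {
  keys <- do.call(paste, c(lapply(aln$counts, function(m)
    do.call(paste, c(asplit(m, 2L), sep = ","))), sep = "|"))
  f <- factor(keys, levels = unique(keys))
  idx <- match(levels(f), keys)
  list(counts = lapply(aln$counts, function(m) m[idx, , drop = FALSE]),
       weights = as.numeric(tabulate(f)),
       pattern_of_site = as.integer(f))
}

#' Empirical allele frequencies of an alignment
#'
#' Pooled relative frequencies of each allele over all populations and
#' sites, used as the default stationary-frequency estimate.
#'
#' @param aln A [pomo_counts()] alignment.
#' @param pseudocount Added to each allele total to keep frequencies
#'   strictly positive (default 1).
#' @return Probability vector over the alphabet.
#' @export
empirical_frequencies <- function(aln, pseudocount = 1) {
  tot <- Reduce(`+`, lapply(aln$counts, colSums)) + pseudocount
  tot / sum(tot)
}
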