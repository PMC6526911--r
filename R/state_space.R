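#' PoMo state space
#'
#' Enumerates the states of the discrete multivariate boundary mutation
#' model for a virtual population of size `N` over an allele alphabet.
#' The population is either monomorphic, `{a}`, or polymorphic for exactly
#' two alleles, `{i a | (N - i) b}`, where `i` in `1..N-1` counts copies of
#' allele `a`.  The state count is `|A| + choose(|A|, 2) * (N - 1)`.
#'
#' States are ordered with the `|A|` monomorphic states first, in alphabet
#' order, followed by one block of `N - 1` polymorphic states per unordered
#' allele pair; pairs are taken in lexicographic alphabet order and within
#' a block `i` ascends from 1 to `N - 1` for the pair's first allele.  The
#' ordering is part of the package contract: all rate matrices, likelihood
#' vectors and serialized states index into it.
#'
#' `N` is a discretization parameter (the number of allele-frequency bins),
#' not an effective population size.
#'
#' @param N Virtual population size (integer, at least 2).
#' @param alphabet Character vector of allele symbols, default
#'   `c("A","C","G","T")`.  Must contain at least two unique symbols.
#'
#' @return An object of class `pomo_states`: a list with elements `N`,
#'   `alphabet`, `n_states`, `labels` (human-readable state names),
#'   `type` (`"mono"`/`"poly"`), `a1`, `a2` (allele indices; `a2` is `NA`
#'   for monomorphic states), `i` (copies of the first allele; `N` for
#'   monomorphic states), `pairs` (2-column matrix of allele-pair indices)
#'   and `poly_index` (lookup described below).
#'
#' @examples
#' s <- pomo_states(10)
#' s$n_states            # 58
#' head(s$labels)
#' @export
pomo_states <- function(N, alphabet = c("A", "C", "G", "T")) {
  if (length(N) != 1L || !is.finite(N) || N != round(N) || N < 2)
    stop("'N' must be a single integer >= 2", call. = FALSE)
  N <- as.integer(N)
  alphabet <- as.character(alphabet)
  if (length(alphabet) < 2L || anyDuplicated(alphabet))
    stop("'alphabet' must contain at least 2 unique symbols", call. = FALSE)
  A <- length(alphabet)
  pairs <- t(utils::combn(A, 2L))
  n_pairs <- nrow(pairs)
  n_states <- A + n_pairs * (N - 1L)

  type <- c(rep("mono", A), rep("poly", n_pairs * (N - 1L)))
  a1 <- c(seq_len(A), rep(pairs[, 1L], each = N - 1L))
  a2 <- c(rep(NA_integer_, A), rep(pairs[, 2L], each = N - 1L))
  i  <- c(rep(N, A), rep.int(seq_len(N - 1L), n_pairs))

  labels <- character(n_states)
  labels[seq_len(A)] <- sprintf("{%s}", alphabet)
  poly <- (A + 1L):n_states
  labels[poly] <- sprintf("{%d%s|%d%s}", i[poly], alphabet[a1[poly]],
                          N - i[poly], alphabet[a2[poly]])

  # poly_index[p, i] = state index of {i a_p | (N-i) b_p}; columns i = 1..N-1
  poly_index <- matrix(A + seq_len(n_pairs * (N - 1L)),
                       nrow = n_pairs, ncol = N - 1L, byrow = TRUE)

  structure(list(N = N, alphabet = alphabet, n_states = n_states,
                 labels = labels, type = type, a1 = a1, a2 = a2, i = i,
                 pairs = pairs, poly_index = poly_index),
            class = "pomo_states")
}

#' @export
print.pomo_states <- function(x, ...) {
  cat(sprintf("PoMo state space: N = %d, alphabet {%s}, %d states\n",
              x$N, paste(x$alphabet, collapse = ","), x$n_states))
  invisible(x)
}

#' Index of a state in a PoMo state space
#'
#' Maps a state description to its integer index under the package's fixed
#' state ordering.  For a monomorphic state pass `a` only; for a
#' polymorphic state `{i a | (N - i) b}` pass `a`, `b` and `i`.
#'
#' @param space A [pomo_states()] object.
#' @param a,b Allele symbols (single characters from the alphabet).
#' @param i Copies of allele `a` (1..N-1 for polymorphic states).
#' @return Integer state index.
#' @export
state_index <- function(space, a, b = NULL, i = NULL) {
  ia <- match(a, space$alphabet)
  if (is.na(ia)) stop("allele '", a, "' not in alphabet", call. = FALSE)
  if (is.null(b)) return(ia)
  ib <- match(b, space$alphabet)
  if (is.na(ib)) stop("allele '", b, "' not in alphabet", call. = FALSE)
  if (ia == ib) stop("polymorphic state needs two distinct alleles", call. = FALSE)
  if (is.null(i)) stop("'i' required for a polymorphic state", call. = FALSE)
  if (ia > ib) { tmp <- ia; ia <- ib; ib <- tmp; i <- space$N - i }
  if (i < 1L || i > space$N - 1L)
    stop("'i' must lie in 1..N-1", call. = FALSE)
  p <- which(space$pairs[, 1L] == ia & space$pairs[, 2L] == ib)
  space$poly_index[p, i]
}
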