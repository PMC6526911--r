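#' Leaf likelihood initialization from allele counts
#'
#' A population is observed at one site as a vector of allele counts
#' `{j c | (M - j) d}` with `M` sampled alleles, generally with `M != N`,
#' the number of allele-frequency bins of the state space.  Three
#' strategies map such an observation to a conditional likelihood vector
#' over the PoMo states:
#'
#' * `"sampled"` — binomially resample `N` alleles from the observed
#'   frequencies and put likelihood 1 on the single resulting state
#'   (stochastic; reproducible via the RNG seed of the enclosing analysis).
#' * `"wbinomial"` — weighted binomial: each compatible state
#'   `{i a | (N - i) b}` receives the probability that sampling `M`
#'   alleles *with* replacement from it yields the observation,
#'   `choose(M, j) (i/N)^j ((N-i)/N)^(M-j)`.  The package default.
#' * `"whypergeometric"` — weighted hypergeometric: sampling *without*
#'   replacement, `choose(i, j) choose(N-i, M-j) / choose(N, M)`; requires
#'   `M <= N` and reduces to an indicator when `M = N`.
#'
#' Monomorphic states are treated as the `i = N` (and `i = 0`) boundary of
#' every compatible pair, each counted once.  A missing observation (all
#' counts zero) yields the all-ones vector.  Observations with more than
#' two segregating alleles cannot be represented by the state space and
#' raise an error.
#'
#' @param counts Nonnegative integer vector of allele counts in alphabet
#'   order (length `|A|`).
#' @param space A [pomo_states()] object.
#' @param strategy One of `"wbinomial"`, `"whypergeometric"`, `"sampled"`.
#' @return Nonnegative likelihood vector indexed by PoMo state.
#' @examples
#' s <- pomo_states(10)
#' L <- leaf_likelihood(c(1, 1, 0, 0), s)         # 1 A, 1 C observed
#' L[state_index(s, "A", "C", i = 5)]              # 0.5
#' @export
leaf_likelihood <- function(counts, space,
                            strategy = c("wbinomial", "whypergeometric",
                                         "sampled")) {
  strategy <- match.arg(strategy)
  switch(strategy,
         wbinomial = init_weighted_binomial(counts, space),
         whypergeometric = init_weighted_hypergeometric(counts, space),
         sampled = init_sampled(counts, space))
}

check_obs <- function(counts, space) {
  counts <- as.numeric(counts)
  if (length(counts) != length(space$alphabet) || any(counts < 0) ||
      any(counts != round(counts)))
    stop("'counts' must be nonnegative integers, one per allele",
         call. = FALSE)
  nz <- which(counts > 0)
  if (length(nz) > 2L)
    stop("observation has ", length(nz), " segregating alleles; the ",
         "boundary mutation state space represents at most 2", call. = FALSE)
  list(counts = counts, nz = nz, M = sum(counts))
}

#' @rdname leaf_likelihood
#' @export
init_weighted_binomial <- function(counts, space) {
  ob <- check_obs(counts, space)
  L <- numeric(space$n_states)
  if (ob$M == 0) {
    warning("observation with zero sampled alleles treated as missing",
            call. = FALSE)
    return(L + 1)
  }
  N <- space$N
  if (length(ob$nz) == 1L) {
    c1 <- ob$nz
    L[c1] <- 1
    for (p in which(space$pairs[, 1L] == c1 | space$pairs[, 2L] == c1)) {
      i <- seq_len(N - 1L)
      f <- if (space$pairs[p, 1L] == c1) i / N else (N - i) / N
      L[space$poly_index[p, ]] <- f^ob$M
    }
  } else {
    c1 <- ob$nz[1L]; c2 <- ob$nz[2L]   # c1 < c2 in alphabet order
    j <- ob$counts[c1]
    p <- which(space$pairs[, 1L] == c1 & space$pairs[, 2L] == c2)
    i <- seq_len(N - 1L)
    L[space$poly_index[p, ]] <- stats::dbinom(j, ob$M, i / N)
    # boundaries i = N ({c1}) and i = 0 ({c2}) are 0 for a polymorphic
    # observation: dbinom(j, M, 1) = dbinom(j, M, 0) = 0 when 0 < j < M
  }
  L
}

#' @rdname leaf_likelihood
#' @export
init_weighted_hypergeometric <- function(counts, space) {
  ob <- check_obs(counts, space)
  L <- numeric(space$n_states)
  if (ob$M == 0) {
    warning("observation with zero sampled alleles treated as missing",
            call. = FALSE)
    return(L + 1)
  }
  N <- space$N
  if (ob$M > N)
    stop("weighted hypergeometric sampling is undefined for M = ", ob$M,
         " sampled alleles > N = ", N, " frequency bins", call. = FALSE)
  if (length(ob$nz) == 1L) {
    c1 <- ob$nz
    L[c1] <- 1
    for (p in which(space$pairs[, 1L] == c1 | space$pairs[, 2L] == c1)) {
      i <- seq_len(N - 1L)
      ic <- if (space$pairs[p, 1L] == c1) i else N - i
      L[space$poly_index[p, ]] <- stats::dhyper(ob$M, ic, N - ic, ob$M)
    }
  } else {
    c1 <- ob$nz[1L]; c2 <- ob$nz[2L]
    j <- ob$counts[c1]
    p <- which(space$pairs[, 1L] == c1 & space$pairs[, 2L] == c2)
    i <- seq_len(N - 1L)
    L[space$poly_index[p, ]] <- stats::dhyper(j, i, N - i, ob$M)
  }
  L
}

#' @rdname leaf_likelihood
#' @export
init_sampled <- function(counts, space) {
  ob <- check_obs(counts, space)
  L <- numeric(space$n_states)
  if (ob$M == 0) {
    warning("observation with zero sampled alleles treated as missing",
            call. = FALSE)
    return(L + 1)
  }
  N <- space$N
  if (length(ob$nz) == 1L) {
    L[ob$nz] <- 1
    return(L)
  }
  c1 <- ob$nz[1L]; c2 <- ob$nz[2L]
  i <- stats::rbinom(1L, N, ob$counts[c1] / ob$M)
  if (i == N) L[c1] <- 1
  else if (i == 0L) L[c2] <- 1
  else {
    p <- which(space$pairs[, 1L] == c1 & space$pairs[, 2L] == c2)
    L[space$poly_index[p, i]] <- 1
  }
  L
}
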