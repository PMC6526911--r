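# Pruning likelihood engine over the PoMo state space.
#
# The engine is an environment holding the tree in postorder, compressed
# site patterns, and per-leaf conditional likelihood matrices
# (n_states x n_patterns).  Per-category generators are eigendecomposed
# once and reused across branches; per-node column rescaling guards
# against underflow, with log scale factors accumulated per pattern.

make_engine <- function(tree, aln, space, strategy = "wbinomial",
                        seed = NULL) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object",
                                     call. = FALSE)
  if (!setequal(tree$tip.label, aln$populations))
    stop("tree tip labels do not match alignment populations",
         call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree needs branch lengths", call. = FALSE)
  if (any(tree$edge.length < 0))
    stop("negative branch lengths are not allowed", call. = FALSE)
  tree <- ape::reorder.phylo(tree, "postorder")

  pat <- compress_patterns(aln)
  P <- length(pat$weights)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode

  if (strategy == "sampled") {
    # one seeded draw per site (site order, populations in order), then
    # re-compress: the draw replaces the observation by a single state,
    # encoded as certainty counts with M = N
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    aln2 <- aln
    for (p in aln$populations) {
      m <- aln$counts[[p]]
      for (s in seq_len(nrow(m))) {
        if (sum(m[s, ]) > 0) {
          L <- init_sampled(m[s, ], space)
          st <- which(L == 1)
          v <- integer(length(aln$alphabet))
          if (space$type[st] == "mono") v[space$a1[st]] <- space$N
          else {
            v[space$a1[st]] <- space$i[st]
            v[space$a2[st]] <- space$N - space$i[st]
          }
          m[s, ] <- v
        }
      }
      aln2$counts[[p]] <- m
    }
    pat <- compress_patterns(aln2)
    P <- length(pat$weights)
    init_strategy <- "whypergeometric"  # M = N: exact indicator
  } else init_strategy <- strategy

  leafL <- vector("list", n_tip)
  for (tip in seq_len(n_tip)) {
    m <- pat$counts[[tree$tip.label[tip]]]
    LM <- matrix(0, space$n_states, P)
    for (r in seq_len(P)) {
      LM[, r] <- if (sum(m[r, ]) == 0) 1
      else leaf_likelihood(m[r, ], space, init_strategy)
    }
    if (any(colSums(LM) == 0))
      stop("unrepresentable observation: zero likelihood at leaf '",
           tree$tip.label[tip], "'", call. = FALSE)
    leafL[[tip]] <- LM
  }

  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  e <- new.env(parent = emptyenv())
  e$tree <- tree
  e$edge <- tree$edge
  e$edge_length <- tree$edge.length
  e$children <- children          # edges indexed by parent node
  e$n_tip <- n_tip
  e$n_node <- n_node
  e$root <- setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])[1L]
  e$weights <- pat$weights
  e$P <- P
  e$leafL <- leafL
  e$space <- space
  e$strategy <- strategy
  e
}

# Per-category generators: rate matrix sets plus cached eigendecompositions.
build_categories <- function(space, model, mix = NULL, QD = NULL) {
  if (is.null(QD)) QD <- build_drift_matrix(space)
  QM <- build_mutation_matrix(space, model)
  if (is.null(mix)) mix <- discretize_gamma(1, 1L)
  cats <- category_matrices(QM, QD, mix, space, model)
  lapply(cats, function(r) list(rates = r, decomp = decompose_rates(r),
                                stationary = r$stationary))
}

# Postorder conditional likelihoods for one category.
# Returns G (list over nodes of n_states x P matrices; tips reference the
# shared leaf matrices) and logs (per-node P-vectors of log scale factors).
postorder_partials <- function(eng, cat) {
  G <- vector("list", eng$n_node)
  logs <- vector("list", eng$n_node)
  for (tip in seq_len(eng$n_tip)) {
    G[[tip]] <- eng$leafL[[tip]]
    logs[[tip]] <- numeric(eng$P)
  }
  nodes <- unique(eng$edge[, 1L])  # postorder guarantees children first
  for (v in nodes) {
    prod <- NULL
    lg <- numeric(eng$P)
    for (eidx in eng$children[[as.character(v)]]) {
      c_node <- eng$edge[eidx, 2L]
      Pt <- expm_decomp(cat$decomp, eng$edge_length[eidx])
      flow <- Pt %*% G[[c_node]]
      prod <- if (is.null(prod)) flow else prod * flow
      lg <- lg + logs[[c_node]]
    }
    cs <- colSums(prod)
    cs[cs <= 0] <- 1e-300
    G[[v]] <- prod / rep(cs, each = nrow(prod))
    logs[[v]] <- lg + log(cs)
  }
  list(G = G, logs = logs)
}

# Per-pattern log likelihood for one category (stationary root closure).
category_pattern_loglik <- function(eng, cat) {
  pp <- postorder_partials(eng, cat)
  site <- colSums(cat$stationary * pp$G[[eng$root]])
  site[site <= 0] <- 1e-300
  log(site) + pp$logs[[eng$root]]
}

# Mixture log likelihood: per-pattern logsumexp over categories minus
# log K, weighted by pattern multiplicities.
engine_loglik <- function(eng, cats) {
  K <- length(cats)
  ll <- vapply(cats, function(cat) category_pattern_loglik(eng, cat),
               numeric(eng$P))
  if (K == 1L) lp <- drop(ll)
  else {
    m <- as.numeric(do.call(pmax, asplit(ll, 2L)))
    lp <- m + log(rowSums(exp(ll - m))) - log(K)
  }
  sum(eng$weights * lp)
}

#' Log likelihood of a counts alignment on a species tree
#'
#' Felsenstein pruning over the PoMo state space: per site pattern the
#' conditional likelihoods are propagated from the leaves (initialized by
#' the chosen sampling strategy) to the root, which is closed with the
#' stationary distribution; under rate heterogeneity the site likelihood
#' is the equally weighted mixture of the per-category pruning
#' likelihoods.  Sites are independent, so the total is the weighted sum
#' of per-pattern log likelihoods.  Branch lengths are interpreted in
#' normalized units (one expected event per site at stationarity).
#'
#' @param tree `phylo` tree whose tip labels match the alignment's
#'   populations, with branch lengths.
#' @param aln A [pomo_counts()] alignment.
#' @param model A [pomo_model()]; when `theta` is given its magnitude is
#'   recalibrated first.
#' @param N Virtual population size (frequency bins) of the state space.
#' @param mix Optional [discretize_gamma()] mixture; `NULL` for the
#'   homogeneous model.
#' @param strategy Leaf initialization strategy (see [leaf_likelihood()]);
#'   default weighted binomial.
#' @param theta Optional target heterozygosity; recalibrates `model`.
#' @param seed RNG seed consumed by the `"sampled"` strategy (one draw per
#'   site in site order).
#' @return Total log likelihood (scalar).
#' @examples
#' aln <- pomo_counts(list(a = rbind(c(10,0,0,0)), b = rbind(c(10,0,0,0))))
#' tr <- read_newick("(a:0.01,b:0.01);")
#' pomo_loglik(tr, aln, pomo_model("HKY", kappa = 2), theta = 0.005)
#' @export
pomo_loglik <- function(tree, aln, model, N = 10, mix = NULL,
                        strategy = c("wbinomial", "whypergeometric",
                                     "sampled"),
                        theta = NULL, seed = NULL) {
  strategy <- match.arg(strategy)
  space <- pomo_states(N, model$alphabet)
  if (!is.null(theta)) model <- calibrate_heterozygosity(model, space, theta)
  eng <- make_engine(tree, aln, space, strategy, seed)
  cats <- build_categories(space, model, mix)
  ll <- engine_loglik(eng, cats)
  if (!is.finite(ll))
    stop("non-finite log likelihood: check branch lengths and data",
         call. = FALSE)
  ll
}
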