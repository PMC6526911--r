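# Shared fixtures and independent oracles used across test files.

# random reversible mutation model (GTR with random rates/frequencies)
random_gtr <- function() {
  pi <- as.numeric(stats::runif(4, 0.1, 1)); pi <- pi / sum(pi)
  pomo_model("GTR", pi = pi, exchangeabilities = stats::runif(6, 0.2, 5),
             mu = stats::runif(1, 0.01, 2))
}

# random reversible model over an arbitrary alphabet (custom symmetric
# exchangeabilities)
random_reversible <- function(alphabet) {
  A <- length(alphabet)
  pi <- as.numeric(stats::runif(A, 0.1, 1)); pi <- pi / sum(pi)
  ex <- matrix(0, A, A)
  ex[upper.tri(ex)] <- stats::runif(A * (A - 1) / 2, 0.2, 5)
  ex <- ex + t(ex)
  pomo_model("custom", pi = pi, exchangeabilities = ex,
             mu = stats::runif(1, 0.05, 1), alphabet = alphabet)
}

# brute-force log likelihood: explicit sum over all internal-node state
# assignments (feasible only for tiny state spaces and 3-4 taxa)
brute_force_loglik <- function(tree, aln, model, space, mix = NULL,
                               strategy = "wbinomial") {
  tree <- ape::reorder.phylo(tree, "postorder")
  if (is.null(mix)) mix <- discretize_gamma(1, 1L)
  QM <- build_mutation_matrix(space, model)
  QD <- build_drift_matrix(space)
  cats <- category_matrices(QM, QD, mix, space, model)
  n_tip <- length(tree$tip.label)
  internal <- sort(unique(tree$edge[, 1L]))
  n_states <- space$n_states
  total <- 0
  for (site in seq_len(aln$n_sites)) {
    leafL <- lapply(tree$tip.label, function(p)
      leaf_likelihood(aln$counts[[p]][site, ], space, strategy))
    names(leafL) <- tree$tip.label
    site_lik_cats <- vapply(cats, function(cat) {
      Pt <- lapply(seq_len(nrow(tree$edge)), function(e)
        transition_probabilities(cat, tree$edge.length[e]))
      grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(n_states)),
                                                 length(internal))))
      lik <- 0
      for (g in seq_len(nrow(grid))) {
        assign_int <- grid[g, ]
        st <- function(node) {
          if (node <= n_tip) return(NULL)
          assign_int[match(node, internal)]
        }
        term <- cat$stationary[st(n_tip + 1L)]
        for (e in seq_len(nrow(tree$edge))) {
          u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
          term <- term * if (v <= n_tip)
            sum(Pt[[e]][st(u), ] * leafL[[tree$tip.label[v]]])
          else Pt[[e]][st(u), st(v)]
        }
        lik <- lik + term
      }
      lik
    }, 0)
    total <- total + log(mean(site_lik_cats))
  }
  total
}

# brute-force split dictionary of an unrooted tree: for every edge,
# the tip set below it, canonicalized against the alphabetically first tip
brute_force_splits <- function(tree, with_lengths = FALSE) {
  tree <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  n_tip <- length(tree$tip.label)
  below <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
    below[[u]] <- c(below[[u]], below[[v]])
  }
  anchor <- sort(tree$tip.label)[1L]
  keys <- character(0); lens <- numeric(0)
  for (e in seq_len(nrow(tree$edge))) {
    side <- below[[tree$edge[e, 2L]]]
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% keys) {       # same split seen from both directions
      lens[match(key, keys)] <- lens[match(key, keys)] +
        tree$edge.length[e]
    } else {
      keys <- c(keys, key); lens <- c(lens, tree$edge.length[e])
    }
  }
  stats::setNames(lens, keys)
}

# Kuhner-Felsenstein branch score from the split dictionaries
brute_force_bsd <- function(t1, t2) {
  s1 <- brute_force_splits(t1, TRUE); s2 <- brute_force_splits(t2, TRUE)
  keys <- union(names(s1), names(s2))
  d1 <- ifelse(keys %in% names(s1), s1[keys], 0)
  d2 <- ifelse(keys %in% names(s2), s2[keys], 0)
  sqrt(sum((d1 - d2)^2))
}

# non-trivial split count difference
brute_force_rf <- function(t1, t2) {
  nt <- function(tr) {
    ks <- names(brute_force_splits(tr))
    sz <- lengths(strsplit(ks, "|", fixed = TRUE))
    ks[sz >= 2 & sz <= length(tr$tip.label) - 2]
  }
  length(setdiff(nt(t1), nt(t2))) + length(setdiff(nt(t2), nt(t1)))
}
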