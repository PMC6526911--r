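#' Yule speciation rate for a target tree height
#'
#' The expected root (most recent common ancestor) age of a pure-birth
#' tree with `n` tips and speciation rate `lambda` is
#' \eqn{(\sum_{i=1}^{n} 1/i - 1)/\lambda}, so the rate producing height
#' `h` on average for `n` species is \eqn{\lambda = (\sum_{i=1}^n 1/i - 1)/h}.
#'
#' @param n Target species count (>= 2).
#' @param h Tree height in expected events per site (> 0).
#' @return Speciation rate `lambda`.
#' @examples
#' yule_rate(12, 0.01)  # ~210.3
#' @export
yule_rate <- function(n, h) {
  if (length(n) != 1L || !is.finite(n) || n < 2 || n != round(n))
    stop("'n' must be an integer >= 2", call. = FALSE)
  if (length(h) != 1L || !is.finite(h) || h <= 0)
    stop("'h' must be positive", call. = FALSE)
  (sum(1 / seq_len(n)) - 1) / h
}

#' Sample an ultrametric Yule species tree of fixed height
#'
#' Pure-birth simulation conditioned on the root split: two lineages
#' start at the root, each lineage branches at rate `lambda`, the process
#' is truncated at height `h`, and all surviving lineages become
#' contemporaneous tips (every root-to-tip distance equals `h` exactly).
#' The leaf count is random; `lambda` defaults to [yule_rate()]`(n, h)`,
#' which matches the expected root age of an `n`-tip Yule tree, so the
#' realized species number varies around the target.
#'
#' @param n Target species count (used to derive `lambda` when absent).
#' @param h Tree height.
#' @param lambda Optional explicit speciation rate.
#' @param seed Optional RNG seed (same seed, same Newick string).
#' @param tip_prefix Tip label prefix (default `"pop"`).
#' @return Ultrametric `phylo` tree of height `h`.
#' @export
sample_yule_tree <- function(n = 12, h = 0.01, lambda = NULL, seed = NULL,
                             tip_prefix = "pop") {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(lambda)) lambda <- yule_rate(n, h)
  # internal node records: parent id (0 for root) and time
  par_id <- 0L
  node_time <- 0
  active <- c(1L, 1L)   # parent internal id of each active lineage
  t <- 0
  repeat {
    dt <- stats::rexp(1L, rate = length(active) * lambda)
    if (t + dt >= h) break
    t <- t + dt
    j <- sample.int(length(active), 1L)
    par_id <- c(par_id, active[j])
    node_time <- c(node_time, t)
    new_id <- length(par_id)
    active <- c(active[-j], new_id, new_id)
  }
  n_tip <- length(active)
  n_int <- length(par_id)
  map <- n_tip + seq_len(n_int)    # internal id -> phylo node number
  edge <- matrix(0L, n_tip + n_int - 1L, 2L)
  elen <- numeric(nrow(edge))
  r <- 0L
  for (k in seq_len(n_int)[-1L]) {
    r <- r + 1L
    edge[r, ] <- c(map[par_id[k]], map[k])
    elen[r] <- node_time[k] - node_time[par_id[k]]
  }
  for (i in seq_len(n_tip)) {
    r <- r + 1L
    edge[r, ] <- c(map[active[i]], i)
    elen[r] <- h - node_time[active[i]]
  }
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = paste0(tip_prefix, seq_len(n_tip)),
                       Nnode = n_int),
                  class = "phylo")
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate a counts alignment under the boundary mutation model
#'
#' Generates allele-count data site by site on a species tree under the
#' discrete multivariate boundary mutation model with (optional) Gamma
#' mutation-rate heterogeneity — the same process the likelihood engine
#' assumes, enabling exact validation by parameter recovery.  Per site: a
#' mutation-rate category is drawn uniformly, the root state is drawn from
#' that category's stationary distribution, states evolve down the tree by
#' exact transition-probability sampling (matrix exponential rows, not
#' event-by-event simulation), and `M` alleles are observed per leaf by
#' binomial sampling from the leaf state's allele frequency `i/N`.
#'
#' @param tree Species tree (`phylo` with branch lengths in normalized
#'   event units), or `NULL` to sample a Yule tree from `n_species`/`height`.
#' @param model A [pomo_model()]; `theta` recalibrates its magnitude.
#' @param N Virtual population size.
#' @param theta Target heterozygosity (stationary polymorphic mass).
#' @param K,alpha Gamma mixture categories and shape (`K = 1` homogeneous).
#' @param n_sites Number of independent sites.
#' @param M Alleles sampled per population per site.
#' @param n_species,height Yule parameters used when `tree` is `NULL`;
#'   `height` is interpreted per `height_units`.
#' @param height_units `"substitutions"` (default; the customary unit for
#'   species-tree heights, converted to internal event units by the exact
#'   `N^2` factor of [events_per_substitution()]) or `"events"`.
#' @param seed RNG seed; a fixed seed makes the output bit-identical.
#' @return An object of class `pomo_sim`: list with `aln`
#'   ([pomo_counts()]), `tree`, `model` (calibrated), `mix`, `theta`,
#'   `N`, `M`, `seed`, and `categories` (true per-site category).
#' @examples
#' sim <- simulate_counts(tree = read_newick("(a:0.01,b:0.01);"),
#'                        model = pomo_model("HKY", kappa = 6.25),
#'                        theta = 0.005, n_sites = 100, seed = 1)
#' sim$aln
#' @export
simulate_counts <- function(tree = NULL, model = pomo_model("HKY"),
                            N = 10, theta = 0.0025, K = 1, alpha = 1,
                            n_sites, M = 10, n_species = 12,
                            height = 0.01,
                            height_units = c("substitutions", "events"),
                            seed = NULL) {
  height_units <- match.arg(height_units)
  if (!is.null(seed)) set.seed(seed)
  if (n_sites < 1) stop("'n_sites' must be >= 1", call. = FALSE)
  if (M < 1) stop("'M' must be >= 1", call. = FALSE)
  if (is.null(tree)) {
    h_ev <- if (height_units == "substitutions")
      height * events_per_substitution(N) else height
    tree <- sample_yule_tree(n_species, h_ev)
  }
  tree <- ape::reorder.phylo(tree, "cladewise")  # preorder edge traversal
  space <- pomo_states(N, model$alphabet)
  if (!is.null(theta)) model <- calibrate_heterozygosity(model, space, theta)
  mix <- discretize_gamma(if (K > 1) alpha else 1, K)
  cats <- build_categories(space, model, mix)

  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])[1L]
  cat_of_site <- sample.int(K, n_sites, replace = TRUE)

  states <- matrix(0L, n_node, n_sites)
  for (k in seq_len(K)) {
    sk <- which(cat_of_site == k)
    states[root, sk] <- sample.int(space$n_states, length(sk),
                                   replace = TRUE,
                                   prob = cats[[k]]$stationary)
  }
  for (e in seq_len(nrow(tree$edge))) {
    u <- tree$edge[e, 1L]; v <- tree$edge[e, 2L]
    t_e <- tree$edge.length[e]
    for (k in seq_len(K)) {
      sk <- which(cat_of_site == k)
      if (!length(sk)) next
      P <- expm_decomp(cats[[k]]$decomp, t_e)
      parent_states <- states[u, sk]
      for (s in unique(parent_states)) {
        idx <- sk[parent_states == s]
        states[v, idx] <- sample.int(space$n_states, length(idx),
                                     replace = TRUE, prob = P[s, ])
      }
    }
  }

  A <- length(space$alphabet)
  counts <- vector("list", n_tip)
  names(counts) <- tree$tip.label
  for (tip in seq_len(n_tip)) {
    st <- states[tip, ]
    m <- matrix(0L, n_sites, A, dimnames = list(NULL, space$alphabet))
    mono <- space$type[st] == "mono"
    if (any(mono))
      m[cbind(which(mono), space$a1[st[mono]])] <- M
    if (any(!mono)) {
      w <- which(!mono)
      j <- stats::rbinom(length(w), M, space$i[st[w]] / space$N)
      m[cbind(w, space$a1[st[w]])] <- j
      m[cbind(w, space$a2[st[w]])] <- M - j
    }
    counts[[tip]] <- m
  }
  aln <- pomo_counts(counts, alphabet = space$alphabet)
  structure(list(aln = aln, tree = tree, model = model, mix = mix,
                 theta = theta, N = N, M = M, seed = seed,
                 categories = cat_of_site,
                 leaf_states = states[seq_len(n_tip), , drop = FALSE]),
            class = "pomo_sim")
}

#' @export
print.pomo_sim <- function(x, ...) {
  cat(sprintf("PoMo simulation: %d populations, %d sites (%s, N = %d, theta = %g%s)\n",
              length(x$aln$populations), x$aln$n_sites, x$model$name, x$N,
              if (is.null(x$theta)) NA else x$theta,
              if (x$mix$K > 1) sprintf(", Gamma alpha = %g K = %d",
                                       x$mix$alpha, x$mix$K) else ""))
  invisible(x)
}

#' Event-by-event simulation along one branch
#'
#' Gillespie simulation of the boundary mutation model jump chain, used to
#' cross-validate the matrix-exponential branch sampling of
#' [simulate_counts()] at small scale.
#'
#' @param rates A `pomo_rates` object.
#' @param t Branch length.
#' @param state0 Starting state index.
#' @return Final state index after time `t`.
#' @export
simulate_branch_gillespie <- function(rates, t, state0) {
  Q <- rates$Q
  s <- state0
  tau <- 0
  repeat {
    rate <- -Q[s, s]
    if (rate <= 0) return(s)
    tau <- tau + stats::rexp(1L, rate)
    if (tau > t) return(s)
    p <- Q[s, ]; p[s] <- 0
    s <- sample.int(length(p), 1L, prob = p)
  }
}

#' Write a simulation's truth record
#'
#' Serializes the true tree, parameters and seed of a [simulate_counts()]
#' run as plain text (Newick plus `key = value` lines) for reproducible
#' recovery experiments.
#'
#' @param sim A `pomo_sim` object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth <- function(sim, path) {
  lines <- c(
    sprintf("tree = %s", write_newick(sim$tree)),
    sprintf("model = %s", sim$model$name),
    sprintf("pi = %s", paste(sim$model$pi, collapse = ",")),
    if (!is.null(sim$model$kappa)) sprintf("kappa = %g", sim$model$kappa),
    sprintf("mu = %.12g", sim$model$mu),
    sprintf("theta = %g", if (is.null(sim$theta)) NA else sim$theta),
    sprintf("N = %d", sim$N),
    sprintf("M = %d", sim$M),
    sprintf("K = %d", sim$mix$K),
    sprintf("alpha = %g", sim$mix$alpha),
    sprintf("n_sites = %d", sim$aln$n_sites),
    sprintf("seed = %s", if (is.null(sim$seed)) "NA" else sim$seed))
  writeLines(lines, path)
  invisible(path)
}
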