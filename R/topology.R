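#' Search for the maximum likelihood species tree topology
#'
#' Two modes: `"exhaustive"` fits every unrooted binary topology (only
#' feasible for small numbers of populations; hard-capped at 8) and is
#' guaranteed to return the maximum likelihood topology among them;
#' `"nni"` hill-climbs from a starting tree through nearest neighbor
#' interchange rearrangements, accepting a move only when it improves the
#' log likelihood, so the reported likelihood never decreases.
#'
#' Model parameters may be fixed (the default here, useful when they were
#' estimated once on a fixed topology or are known) or re-optimized for
#' every candidate via `optimize_model`.
#'
#' @param aln A [pomo_counts()] alignment.
#' @param model A [pomo_model()] (with magnitude calibrated via `theta`).
#' @param N,K,alpha,theta,strategy As in [pomo_fit()].
#' @param mode `"exhaustive"` (<= 8 populations) or `"nni"`.
#' @param start Starting tree for NNI mode (default: a random topology).
#' @param optimize_model Re-optimize model parameters for each candidate
#'   topology (default `FALSE`: branch lengths only).
#' @param init_branch Starting branch length for candidate topologies.
#' @param control Passed to [pomo_fit()].
#' @param seed RNG seed (random starting topology, sampled strategy).
#' @return List with `tree` (best tree, fitted branch lengths), `fit`
#'   (its [pomo_fit()] result) and `n_evaluated`.
#' @export
search_topology <- function(aln, model = pomo_model("HKY"), N = 10,
                            K = 1, alpha = 1, theta = 0.005,
                            strategy = "wbinomial",
                            mode = c("exhaustive", "nni"), start = NULL,
                            optimize_model = FALSE, init_branch = 0.01,
                            control = list(), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  pops <- aln$populations
  fr <- if (optimize_model) list()
  else list(kappa = FALSE, exch = FALSE, theta = FALSE, alpha = FALSE)
  fit1 <- function(tr) {
    if (is.null(tr$edge.length)) tr$edge.length <- rep(init_branch,
                                                       nrow(tr$edge))
    # canonicalize node numbering (rearrangement code may renumber)
    tr <- read_newick(write_newick(tr))
    pomo_fit(tr, aln, model, N = N, K = K, alpha = alpha, theta = theta,
             strategy = strategy, free = fr, control = control)
  }

  if (mode == "exhaustive") {
    if (length(pops) > 8L)
      stop("exhaustive search is capped at 8 populations; use mode = 'nni'",
           call. = FALSE)
    topos <- phangorn::allTrees(length(pops), rooted = FALSE,
                                tip.label = pops)
    fits <- lapply(topos, fit1)
    lls <- vapply(fits, function(f) f$log_likelihood, 0)
    best <- which.max(lls)
    return(list(tree = fits[[best]]$tree, fit = fits[[best]],
                n_evaluated = length(topos)))
  }

  if (is.null(start)) start <- ape::rtree(length(pops), tip.label = sample(pops))
  cur_fit <- fit1(ape::unroot(start))
  n_eval <- 1L
  repeat {
    cw <- ape::reorder.phylo(cur_fit$tree, "cladewise")
    nbs <- phangorn::nni(cw)
    improved <- FALSE
    for (nb in nbs) {
      # nni keeps tip indices but may drop the labels
      if (is.null(nb$tip.label)) nb$tip.label <- cw$tip.label
      nb$edge.length <- rep(init_branch, nrow(nb$edge))
      f <- fit1(nb)
      n_eval <- n_eval + 1L
      if (f$log_likelihood > cur_fit$log_likelihood + 1e-8) {
        cur_fit <- f
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  list(tree = cur_fit$tree, fit = cur_fit, n_evaluated = n_eval)
}
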