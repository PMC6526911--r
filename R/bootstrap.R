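#' Nonparametric bootstrap support for tree splits
#'
#' Standard nonparametric bootstrap: site patterns are resampled with
#' replacement (a multinomial draw on the pattern weights — identical in
#' distribution to resampling raw columns, but faster), the analysis is
#' repeated on each replicate, and every split of the input tree is
#' scored by the percentage of replicate trees containing it.
#'
#' By default each replicate refits branch lengths on the input topology
#' with fixed model parameters; with `search = TRUE` the topology is
#' re-searched (NNI from the input tree), which is what makes support
#' values informative about topological uncertainty.
#'
#' @param tree Input tree (`phylo`, with branch lengths).
#' @param aln A [pomo_counts()] alignment.
#' @param model A [pomo_model()].
#' @param B Number of bootstrap replicates (>= 1).
#' @param seed RNG seed; replicates are reproducible given the seed.
#' @param N,K,alpha,theta,strategy As in [pomo_fit()].
#' @param search Re-search the topology per replicate (NNI) instead of
#'   refitting branch lengths only.
#' @param optimize_model Re-optimize model parameters per replicate.
#' @param control Passed to [pomo_fit()].
#' @return A data frame with one row per non-trivial split of `tree`:
#'   `split` (tip set on the far side of the alphabetically first tip)
#'   and `support` (percentage of replicates, in [0, 100]).
#' @export
pomo_bootstrap <- function(tree, aln, model = pomo_model("HKY"), B = 100,
                           seed = NULL, N = 10, K = 1, alpha = 1,
                           theta = 0.005, strategy = "wbinomial",
                           search = FALSE, optimize_model = FALSE,
                           control = list()) {
  if (B < 1) stop("'B' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pat <- compress_patterns(aln)
  n_pat <- length(pat$weights)
  splits <- tree_splits(tree)
  if (length(splits) == 0L)
    return(data.frame(split = character(), support = numeric()))
  hits <- setNames(numeric(length(splits)), splits)
  fr <- if (optimize_model) list()
  else list(kappa = FALSE, exch = FALSE, theta = FALSE, alpha = FALSE)

  for (b in seq_len(B)) {
    w <- as.vector(stats::rmultinom(1L, aln$n_sites,
                                    pat$weights / sum(pat$weights)))
    keep <- w > 0
    rep_counts <- lapply(pat$counts, function(m) {
      m[rep(which(keep), w[keep]), , drop = FALSE]
    })
    rep_aln <- pomo_counts(rep_counts, alphabet = aln$alphabet)
    rep_tree <- if (search) {
      search_topology(rep_aln, model, N = N, K = K, alpha = alpha,
                      theta = theta, strategy = strategy, mode = "nni",
                      start = tree, optimize_model = optimize_model,
                      control = control)$tree
    } else {
      pomo_fit(tree, rep_aln, model, N = N, K = K, alpha = alpha,
               theta = theta, strategy = strategy, free = fr,
               control = control)$tree
    }
    rep_splits <- tree_splits(rep_tree)
    hits[splits %in% rep_splits] <- hits[splits %in% rep_splits] + 1
  }
  data.frame(split = splits, support = 100 * hits / B,
             row.names = NULL, stringsAsFactors = FALSE)
}
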