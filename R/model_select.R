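#' Rank candidate mutation models by information criteria
#'
#' Fits each candidate (a mutation model, optionally with Gamma
#' mutation-rate heterogeneity) on the given topology and scores it with
#' the Akaike and Bayesian information criteria,
#' `AIC = 2k - 2 lnL` and `BIC = k ln(n_sites) - 2 lnL`,
#' where `k` counts the candidate's free parameters and `n_sites` the
#' (uncompressed) alignment length.  Candidates are returned sorted by
#' the chosen criterion; ties preserve input order (stable sort).
#' Candidates whose fit fails are excluded with a warning.
#'
#' @param aln A [pomo_counts()] alignment.
#' @param tree Tree topology with starting branch lengths.
#' @param candidates List of candidate specifications; each a list with
#'   elements `model` (a [pomo_model()] or model name string), optional
#'   `K` (categories, default 1), `alpha` (starting shape), and `label`.
#' @param criterion `"BIC"` (default) or `"AIC"`.
#' @param N,theta,strategy,control Passed to [pomo_fit()].
#' @return A data frame sorted by the criterion: `label`, `log_likelihood`,
#'   `k`, `AIC`, `BIC`, plus a `fits` attribute with the full
#'   [pomo_fit()] objects in input order.
#' @export
rank_models <- function(aln, tree, candidates, criterion = c("BIC", "AIC"),
                        N = 10, theta = 0.005, strategy = "wbinomial",
                        control = list()) {
  criterion <- match.arg(criterion)
  if (length(candidates) < 2L)
    stop("need at least 2 candidate models to rank", call. = FALSE)
  rows <- list()
  fits <- list()
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    m <- cand$model
    if (is.character(m)) m <- pomo_model(m, exchangeabilities =
                                           if (m == "GTR") rep(1, 6))
    K <- if (is.null(cand$K)) 1L else cand$K
    alpha <- if (is.null(cand$alpha)) 1 else cand$alpha
    label <- if (!is.null(cand$label)) cand$label
    else paste0(m$name, if (K > 1) sprintf("+G%d", K))
    fit <- tryCatch(
      pomo_fit(tree, aln, m, N = N, K = K, alpha = alpha, theta = theta,
               strategy = strategy, control = control),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning("candidate '", label, "' failed to fit and was excluded: ",
              conditionMessage(fit), call. = FALSE)
      next
    }
    k <- fit$n_free_parameters
    rows[[length(rows) + 1L]] <- data.frame(
      label = label, log_likelihood = fit$log_likelihood, k = k,
      AIC = 2 * k - 2 * fit$log_likelihood,
      BIC = k * log(aln$n_sites) - 2 * fit$log_likelihood,
      stringsAsFactors = FALSE)
    fits[[label]] <- fit
  }
  if (!length(rows)) stop("all candidate fits failed", call. = FALSE)
  tab <- do.call(rbind, rows)
  ord <- order(tab[[criterion]])  # order() is a stable sort
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  attr(tab, "criterion") <- criterion
  tab
}
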