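# Maximum likelihood fitting: coordinate-wise bounded optimization of
# model parameters (Brent line searches on transformed scales) alternating
# with per-edge branch length optimization.
#
# Branch lengths use the standard two-pass trick: after a postorder pass
# computing downward partials G, a preorder (root-to-tip) traversal keeps
# the "rest of tree" partial for each edge, so the likelihood as a
# function of one branch length reduces to
#   L(t) = sum_s exp(lambda_s t) * (U' D^-1 M)_s . (U' D G)_s
# per pattern and category, making Brent iterations nearly free.

default_bounds <- function() list(
  branch = c(1e-8, 10), kappa = c(0.2, 100), exch = c(1e-3, 1e3),
  theta = c(1e-6, 0.25), alpha = c(0.01, 1e6), pi = c(1e-4, 1))

# One full sweep of per-edge optimization (Gauss-Seidel in preorder,
# partials refreshed along the root-to-tip path).
optimize_edges_pass <- function(eng, cats, lower, upper, tol = 1e-3) {
  K <- length(cats)
  n <- eng$space$n_states
  G_all <- lapply(cats, function(cat) postorder_partials(eng, cat))
  logK <- log(K)
  w <- eng$weights

  edge_negll <- function(ab, base, lambdas, lt) {
    t <- exp(lt)
    lp <- matrix(0, eng$P, K)
    for (k in seq_len(K)) {
      Lp <- drop(exp(lambdas[[k]] * t) %*% ab[[k]])
      Lp[Lp <= 0] <- 1e-300
      lp[, k] <- log(Lp) + base[[k]]
    }
    tot <- if (K == 1L) lp[, 1L] else {
      m <- as.numeric(do.call(pmax, asplit(lp, 2L)))
      m + log(rowSums(exp(lp - m))) - logK
    }
    -sum(w * tot)
  }

  dfs <- function(v, H, logsH) {
    eidxs <- eng$children[[as.character(v)]]
    if (is.null(eidxs)) return(invisible())
    for (j in seq_along(eidxs)) {
      eidx <- eidxs[[j]]
      child <- eng$edge[eidx, 2L]
      M <- vector("list", K); logsM <- vector("list", K)
      for (k in seq_len(K)) {
        prod <- H[[k]]; lg <- logsH[[k]]
        for (l in seq_along(eidxs)) if (l != j) {
          sib_e <- eidxs[[l]]; sib <- eng$edge[sib_e, 2L]
          Pt <- expm_decomp(cats[[k]]$decomp, eng$edge_length[sib_e])
          prod <- prod * (Pt %*% G_all[[k]]$G[[sib]])
          lg <- lg + G_all[[k]]$logs[[sib]]
        }
        cs <- colSums(prod); cs[cs <= 0] <- 1e-300
        M[[k]] <- prod / rep(cs, each = n)
        logsM[[k]] <- lg + log(cs)
      }
      ab <- vector("list", K); base <- vector("list", K)
      lambdas <- vector("list", K)
      for (k in seq_len(K)) {
        d <- cats[[k]]$decomp
        ab[[k]] <- crossprod(d$U, M[[k]] * d$inv_d) *
          crossprod(d$U, G_all[[k]]$G[[child]] * d$d)
        base[[k]] <- logsM[[k]] + G_all[[k]]$logs[[child]]
        lambdas[[k]] <- d$lambda
      }
      f <- function(lt) edge_negll(ab, base, lambdas, lt)
      cur <- max(eng$edge_length[eidx], lower)
      opt <- stats::optimize(f, interval = log(c(lower, upper)), tol = tol)
      if (opt$objective < f(log(cur)))
        eng$edge_length[eidx] <- exp(opt$minimum)
      # descend with the child's upward partial under the new length
      Hc <- vector("list", K); logsHc <- vector("list", K)
      for (k in seq_len(K)) {
        Pt <- expm_decomp(cats[[k]]$decomp, eng$edge_length[eidx])
        Hc[[k]] <- crossprod(Pt, M[[k]])
        logsHc[[k]] <- logsM[[k]]
      }
      dfs(child, Hc, logsHc)
    }
    invisible()
  }

  H0 <- lapply(cats, function(cat) matrix(cat$stationary, n, eng$P))
  l0 <- lapply(seq_len(K), function(k) numeric(eng$P))
  dfs(eng$root, H0, l0)
  invisible(eng)
}

#' Maximum likelihood fit of the PoMo model on a fixed topology
#'
#' Maximizes the pruning log likelihood by coordinate-wise bounded
#' optimization: Brent line searches for each free model parameter
#' (kappa or GTR exchangeabilities, heterozygosity theta, Gamma shape
#' alpha, optionally stationary frequencies), alternating with per-edge
#' branch length optimization, until the relative log-likelihood
#' improvement falls below `rel_tol` or `max_sweeps` is reached.
#'
#' Any subset of parameters may be frozen through `free`; frozen
#' parameters are returned exactly as supplied.  If nothing is free the
#' fit degenerates to a single likelihood evaluation with a warning.
#'
#' Stationary frequencies default to the pooled empirical allele
#' frequencies of the counts (`pi_mode = "empirical"`); `"ml"` optimizes
#' them, `"fixed"` keeps the model's values.  Empirical and ML
#' frequencies contribute `|A| - 1` free parameters to the information
#' criteria; fixed frequencies contribute none.
#'
#' @param tree `phylo` tree with branch lengths (used as starting values).
#' @param aln A [pomo_counts()] alignment.
#' @param model A [pomo_model()]; starting values for kappa /
#'   exchangeabilities.
#' @param N Virtual population size of the state space.
#' @param K Number of Gamma mixture categories (1 = homogeneous).
#' @param alpha Starting Gamma shape (used when `K > 1`).
#' @param theta Starting heterozygosity.
#' @param strategy Leaf initialization strategy.
#' @param pi_mode `"empirical"` (default), `"ml"` or `"fixed"`.
#' @param free Named logical list; defaults to all of `branch_lengths`,
#'   `kappa`, `exch`, `theta`, `alpha` free (as applicable to the model).
#' @param seed RNG seed (consumed by the `"sampled"` strategy).
#' @param control List: `max_sweeps` (default 100), `rel_tol` (1e-6),
#'   `branch_passes` (2), `param_tol` (1e-3, Brent tolerance on the log
#'   scale), `bounds` (see `default_bounds`), `trace` (FALSE).
#' @return An object of class `pomo_fit`: `log_likelihood`, `model`
#'   (calibrated), `theta`, `alpha`, `K`, `mix`, `tree` (optimized branch
#'   lengths), `n_free_parameters`, `converged`, `n_sweeps`, `n_sites`,
#'   `strategy`, `N`.
#' @export
pomo_fit <- function(tree, aln, model = pomo_model("HKY"), N = 10,
                     K = 1, alpha = 1, theta = 0.005,
                     strategy = c("wbinomial", "whypergeometric",
                                  "sampled"),
                     pi_mode = c("empirical", "ml", "fixed"),
                     free = list(), seed = NULL, control = list()) {
  strategy <- match.arg(strategy)
  pi_mode <- match.arg(pi_mode)
  ctrl <- utils::modifyList(list(max_sweeps = 100L, rel_tol = 1e-6,
                                 branch_passes = 2L, param_tol = 1e-3,
                                 bounds = default_bounds(), trace = FALSE),
                            control)
  fr <- utils::modifyList(list(branch_lengths = TRUE, kappa = TRUE,
                               exch = TRUE, theta = TRUE, alpha = TRUE,
                               pi = (pi_mode == "ml")),
                          free)
  space <- pomo_states(N, model$alphabet)
  if (pi_mode == "empirical") {
    emp <- empirical_frequencies(aln)
    model <- pomo_model(model$name, pi = emp, kappa = model$kappa,
                        exchangeabilities = exch_full(model, free_exch(model)),
                        mu = model$mu, alphabet = model$alphabet)
  }
  eng <- make_engine(tree, aln, space, strategy, seed)
  QD <- build_drift_matrix(space)

  par <- list(kappa = model$kappa, exch = free_exch(model),
              theta = theta, alpha = alpha, pi = model$pi)
  has_kappa <- model$name == "HKY"
  has_exch <- model$name == "GTR"
  use_alpha <- K > 1L

  mk_model <- function(par) {
    m <- pomo_model(model$name, pi = par$pi, kappa = par$kappa,
                    exchangeabilities = exch_full(model, par$exch),
                    alphabet = model$alphabet)
    # line searches legitimately probe theta > 0.1; the model-validity
    # advisory is re-issued once for the final estimate instead
    suppressWarnings(calibrate_heterozygosity(m, space, par$theta))
  }
  mk_cats <- function(par) {
    mix <- if (use_alpha) discretize_gamma(par$alpha, K)
    else discretize_gamma(1, 1L)
    build_categories(space, mk_model(par), mix, QD)
  }
  eval_ll <- function(par) engine_loglik(eng, mk_cats(par))

  any_free <- fr$branch_lengths || (fr$kappa && has_kappa) ||
    (fr$exch && has_exch) || fr$theta || (fr$alpha && use_alpha) || fr$pi
  if (!any_free)
    warning("no free parameters: returning a likelihood evaluation only",
            call. = FALSE)

  # Brent on a transformed scalar inside `par`
  opt_scalar <- function(par, get, set, bounds, cur_ll) {
    f <- function(lx) { p <- set(par, exp(lx)); -eval_ll(p) }
    cur <- min(max(get(par), bounds[1L]), bounds[2L])
    # narrow the bracket around the current value after the first sweep
    opt <- stats::optimize(f, interval = log(bounds), tol = ctrl$param_tol)
    if (-opt$objective > cur_ll) {
      par <- set(par, exp(opt$minimum))
      cur_ll <- -opt$objective
    }
    list(par = par, ll = cur_ll)
  }

  ll <- suppressWarnings(eval_ll(par))
  converged <- FALSE
  sweeps <- 0L
  bounds <- ctrl$bounds
  while (any_free && sweeps < ctrl$max_sweeps) {
    sweeps <- sweeps + 1L
    ll_prev <- ll
    if (fr$theta) {
      r <- opt_scalar(par, function(p) p$theta,
                      function(p, x) { p$theta <- x; p },
                      bounds$theta, ll)
      par <- r$par; ll <- r$ll
    }
    if (fr$kappa && has_kappa) {
      r <- opt_scalar(par, function(p) p$kappa,
                      function(p, x) { p$kappa <- x; p },
                      bounds$kappa, ll)
      par <- r$par; ll <- r$ll
    }
    if (fr$exch && has_exch) {
      for (j in 1:5) {  # GT exchangeability fixed at 1 for identifiability
        r <- opt_scalar(par, function(p) p$exch[j],
                        function(p, x) { p$exch[j] <- x; p },
                        bounds$exch, ll)
        par <- r$par; ll <- r$ll
      }
    }
    if (fr$alpha && use_alpha) {
      r <- opt_scalar(par, function(p) p$alpha,
                      function(p, x) { p$alpha <- x; p },
                      bounds$alpha, ll)
      par <- r$par; ll <- r$ll
    }
    if (fr$pi) {
      for (j in seq_len(length(par$pi) - 1L)) {
        r <- opt_scalar(par, function(p) p$pi[j],
                        function(p, x) { p$pi[j] <- x; p$pi <- p$pi / sum(p$pi); p },
                        bounds$pi, ll)
        par <- r$par; ll <- r$ll
      }
    }
    if (fr$branch_lengths) {
      cats <- mk_cats(par)
      for (bp in seq_len(ctrl$branch_passes))
        optimize_edges_pass(eng, cats, bounds$branch[1L],
                            bounds$branch[2L], tol = ctrl$param_tol)
      ll <- engine_loglik(eng, cats)
    }
    if (ctrl$trace)
      message(sprintf("sweep %d: lnL = %.6f", sweeps, ll))
    if (is.finite(ll_prev) && abs(ll - ll_prev) <=
        ctrl$rel_tol * abs(ll)) { converged <- TRUE; break }
    # after the first sweep the bracket can tighten around the optimum
    bounds <- tighten_bounds(bounds, par, ctrl$bounds, has_kappa, has_exch)
  }
  if (!any_free) converged <- TRUE

  if (par$theta > 0.1)
    warning("fitted theta = ", signif(par$theta, 4), " exceeds 0.1; the ",
            "boundary mutation approximation becomes unreliable",
            call. = FALSE)
  fitted_tree <- eng$tree
  fitted_tree$edge.length <- eng$edge_length
  fitted_model <- mk_model(par)
  k_free <- (if (fr$branch_lengths) nrow(eng$edge) else 0L) +
    (if (fr$kappa && has_kappa) 1L else 0L) +
    (if (fr$exch && has_exch) 5L else 0L) +
    (if (fr$theta) 1L else 0L) +
    (if (fr$alpha && use_alpha) 1L else 0L) +
    (if (pi_mode != "fixed") length(model$pi) - 1L else 0L)

  structure(list(log_likelihood = ll, model = fitted_model,
                 theta = par$theta, alpha = if (use_alpha) par$alpha,
                 K = K, mix = if (use_alpha) discretize_gamma(par$alpha, K),
                 kappa = par$kappa, exch = par$exch, pi = fitted_model$pi,
                 tree = fitted_tree, n_free_parameters = k_free,
                 converged = converged, n_sweeps = sweeps,
                 n_sites = aln$n_sites, strategy = strategy, N = N,
                 pi_mode = pi_mode),
            class = "pomo_fit")
}

free_exch <- function(model) {
  if (model$name != "GTR") return(NULL)
  e <- model$exch
  c(e[1, 2], e[1, 3], e[1, 4], e[2, 3], e[2, 4]) / e[3, 4]
}

# 5 free GTR exchangeabilities -> the full 6-vector (GT pinned to 1)
exch_full <- function(model, free) {
  if (model$name != "GTR") return(if (model$name == "custom") model$exch)
  c(free, 1)
}

tighten_bounds <- function(bounds, par, full, has_kappa, has_exch) {
  shrink <- function(x, b, factor = 4) {
    c(max(b[1L], x / factor), min(b[2L], x * factor))
  }
  bounds$theta <- shrink(par$theta, full$theta)
  if (has_kappa && !is.null(par$kappa))
    bounds$kappa <- shrink(par$kappa, full$kappa)
  if (!is.null(par$alpha)) bounds$alpha <- shrink(par$alpha, full$alpha)
  bounds
}

#' @export
print.pomo_fit <- function(x, ...) {
  cat(sprintf("PoMo fit (%s, N = %d%s, %s sampling)\n", x$model$name, x$N,
              if (x$K > 1) sprintf(", Gamma K = %d", x$K) else "",
              x$strategy))
  cat(sprintf("  lnL = %.4f  (%d free parameters, %d sites, %s)\n",
              x$log_likelihood, x$n_free_parameters, x$n_sites,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  theta = %.6g", x$theta))
  if (!is.null(x$kappa)) cat(sprintf("  kappa = %.4g", x$kappa))
  if (!is.null(x$alpha)) cat(sprintf("  alpha = %.4g", x$alpha))
  cat("\n  pi:", paste(sprintf("%.4g", x$pi), collapse = " "), "\n")
  invisible(x)
}
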