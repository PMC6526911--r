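#' Discretized Gamma mutation-rate heterogeneity
#'
#' Splits a mean-one Gamma(shape = alpha, rate = alpha) distribution into
#' `K` equal-probability slices and uses the mean of each slice as a
#' mutation rate modifier `r_k`, with category weights `1/K`.  Slice means
#' come from the incomplete-gamma identity
#' \eqn{E[X \mid a < X \le b] \cdot 1/K = F_{\alpha+1}(b) - F_{\alpha+1}(a)}
#' for the mean-one parameterization.  A final renormalization pins the
#' weighted mean to exactly one so branch-length units do not drift with
#' quadrature error.
#'
#' Only the mutation part of the generator is scaled by `r_k`
#' (see [category_matrices()]); drift is shared by all categories.
#'
#' Shapes below 0.01 are rejected as numerically degenerate; shapes at or
#' above 1e6 collapse to the homogeneous model (all modifiers 1).
#'
#' @param alpha Gamma shape parameter (> 0); the mean is fixed at 1.
#' @param K Number of categories (integer >= 1).
#' @return An object of class `gamma_mixture`: list with `alpha`, `K`,
#'   `rates` (increasing modifiers) and `weights` (all `1/K`).
#' @examples
#' discretize_gamma(0.5, 4)$rates
#' @export
discretize_gamma <- function(alpha, K) {
  if (!is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be positive", call. = FALSE)
  if (alpha < 0.01)
    stop("'alpha' below 0.01 is numerically degenerate", call. = FALSE)
  if (length(K) != 1L || !is.finite(K) || K != round(K) || K < 1)
    stop("'K' must be a single integer >= 1", call. = FALSE)
  K <- as.integer(K)
  if (K == 1L || alpha >= 1e6) {
    rates <- rep(1, K)
  } else {
    breaks <- stats::qgamma(seq_len(K - 1L) / K, shape = alpha, rate = alpha)
    edges <- c(0, breaks, Inf)
    cdf1 <- stats::pgamma(edges, shape = alpha + 1, rate = alpha)
    rates <- K * diff(cdf1)
    rates <- rates / mean(rates)
  }
  structure(list(alpha = alpha, K = K, rates = rates,
                 weights = rep(1 / K, K)),
            class = "gamma_mixture")
}

#' @export
print.gamma_mixture <- function(x, ...) {
  cat(sprintf("Gamma mixture: alpha = %g, K = %d\n  rates: %s\n",
              x$alpha, x$K, paste(signif(x$rates, 5), collapse = " ")))
  invisible(x)
}

#' Per-category rate matrices Q_k = r_k Q_M + Q_D
#'
#' Each category scales only the mutation part of the generator; the drift
#' part is identical across categories.  All categories share a single
#' normalization constant, taken from the weighted-average generator
#' (which equals `Q_M + Q_D` because the modifiers have mean one), so one
#' branch-length unit has the same meaning in every category.
#'
#' @param QM,QD Mutation and drift matrices from the homogeneous model.
#' @param mix A [discretize_gamma()] mixture.
#' @param space,model Optional; enables closed-form per-category
#'   stationary distributions.
#' @return List of `pomo_rates`, one per category, sharing `$scale`.
#' @export
category_matrices <- function(QM, QD, mix, space = NULL, model = NULL) {
  base <- assemble_rate_matrix(QM, QD, normalize = FALSE,
                               space = space, model = model)
  scale <- base$scale
  lapply(seq_len(mix$K), function(k) {
    r <- mix$rates[k]
    model_k <- if (!is.null(model)) { m <- model; m$mu <- m$mu * r; m }
    Qk <- r * QM + QD
    stat <- if (!is.null(space) && !is.null(model_k))
      stationary_closed_form(space, model_k)
    else
      stationary_numeric(Qk)
    structure(list(Q = Qk / scale, QM = QM, QD = QD, stationary = stat,
                   scale = scale, normalized = TRUE, rate_modifier = r),
              class = "pomo_rates")
  })
}

#' Mixture site likelihood over mutation-rate categories
#'
#' The site likelihood under rate heterogeneity is the equally weighted
#' mean of the per-category likelihoods.
#'
#' @param per_category_likelihoods Nonnegative numeric vector of length K.
#' @return The mixture likelihood (their mean).
#' @export
mixture_site_likelihood <- function(per_category_likelihoods) {
  x <- per_category_likelihoods
  if (length(x) == 0L)
    stop("need at least one per-category likelihood", call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("per-category likelihoods must be finite and nonnegative",
         call. = FALSE)
  mean(x)
}
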