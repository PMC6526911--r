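#' Mutation part of the boundary mutation model generator
#'
#' Builds `Q_M`, whose only nonzero off-diagonal entries are mutations away
#' from monomorphic states, `{a} -> {(N-1)a | 1b}` at rate `q_ab`.
#' Mutations are disallowed once more than one allele segregates, which is
#' a good approximation while heterozygosity stays below about 0.1.
#' Diagonal entries are set so every row sums to zero.
#'
#' @param space A [pomo_states()] object.
#' @param model A [pomo_model()] over the same alphabet.
#' @return Square rate matrix over the state space.
#' @export
build_mutation_matrix <- function(space, model) {
  if (!identical(space$alphabet, model$alphabet))
    stop("state space and mutation model use different alphabets",
         call. = FALSE)
  n <- space$n_states
  q <- mutation_rates(model)
  QM <- matrix(0, n, n, dimnames = list(space$labels, space$labels))
  N <- space$N
  for (p in seq_len(nrow(space$pairs))) {
    a <- space$pairs[p, 1L]; b <- space$pairs[p, 2L]
    # {a} -> {(N-1)a|1b}: first allele of the pair at count N-1
    QM[a, space$poly_index[p, N - 1L]] <- q[a, b]
    # {b} -> {1a|(N-1)b}
    QM[b, space$poly_index[p, 1L]] <- q[b, a]
  }
  diag(QM) <- -rowSums(QM)
  QM
}

#' Drift part of the boundary mutation model generator
#'
#' Moran-process frequency shifts between neighboring polymorphic states:
#' `{i a | (N-i) b}` moves to `i + 1` or `i - 1` at equal rate
#' `i (N - i) / N`, including into the monomorphic boundaries at
#' `i = N - 1` (absorbing toward `{a}`) and `i = 1` (toward `{b}`).
#' Monomorphic rows are zero: drift acts only on polymorphic states.
#'
#' @param space A [pomo_states()] object.
#' @return Square rate matrix over the state space with zero row sums.
#' @export
build_drift_matrix <- function(space) {
  n <- space$n_states
  N <- space$N
  QD <- matrix(0, n, n, dimnames = list(space$labels, space$labels))
  for (p in seq_len(nrow(space$pairs))) {
    a <- space$pairs[p, 1L]; b <- space$pairs[p, 2L]
    idx <- space$poly_index[p, ]            # i = 1..N-1
    for (i in seq_len(N - 1L)) {
      r <- i * (N - i) / N
      up   <- if (i == N - 1L) a else idx[i + 1L]
      down <- if (i == 1L)     b else idx[i - 1L]
      QD[idx[i], up]   <- QD[idx[i], up] + r
      QD[idx[i], down] <- QD[idx[i], down] + r
    }
  }
  diag(QD) <- -rowSums(QD)
  QD
}

#' Assemble the full PoMo rate matrix Q = Q_M + Q_D
#'
#' Adds the mutation and drift generators, computes the stationary
#' distribution, and (by default) rescales `Q` so that the expected total
#' event rate at stationarity, \eqn{-\sum_s \pi_s Q_{ss}}, equals one.
#' Branch lengths are then measured in expected events (mutations plus
#' frequency shifts) per site.  The pre-normalization rate is kept in
#' `$scale` so users can convert units.
#'
#' @param QM,QD Conformable matrices from [build_mutation_matrix()] and
#'   [build_drift_matrix()].
#' @param normalize Rescale to one expected event per site per unit branch
#'   length (default `TRUE`).
#' @param space,model Optional; when both are supplied the stationary
#'   distribution uses the closed form for reversible models (exact and
#'   fast), otherwise a null-left-eigenvector solve.
#' @return An object of class `pomo_rates`: list with `Q`, `QM`, `QD`
#'   (unscaled parts), `stationary`, `scale` and `normalized`.
#' @export
assemble_rate_matrix <- function(QM, QD, normalize = TRUE,
                                 space = NULL, model = NULL) {
  if (!all(dim(QM) == dim(QD)))
    stop("'QM' and 'QD' are not conformable", call. = FALSE)
  Q <- QM + QD
  stat <- if (!is.null(space) && !is.null(model))
    stationary_closed_form(space, model)
  else
    stationary_numeric(Q)
  scale <- -sum(stat * diag(Q))
  if (normalize) Q <- Q / scale
  structure(list(Q = Q, QM = QM, QD = QD, stationary = stat,
                 scale = scale, normalized = normalize),
            class = "pomo_rates")
}

#' One-call constructor for the assembled PoMo rate matrix
#'
#' Convenience wrapper: builds `Q_M` and `Q_D` and assembles them with the
#' closed-form stationary distribution.
#'
#' @inheritParams build_mutation_matrix
#' @inheritParams assemble_rate_matrix
#' @return A `pomo_rates` object.
#' @export
pomo_rate_matrix <- function(space, model, normalize = TRUE) {
  assemble_rate_matrix(build_mutation_matrix(space, model),
                       build_drift_matrix(space),
                       normalize = normalize, space = space, model = model)
}

#' Closed-form stationary distribution of the boundary mutation model
#'
#' For reversible mutation models detailed balance gives the stationary
#' law directly: monomorphic mass proportional to \eqn{\pi_a}, polymorphic
#' mass of `{i a | (N-i) b}` proportional to
#' \eqn{\mu \rho_{ab} \pi_a \pi_b N / (i (N - i))}.
#'
#' @param space A [pomo_states()] object.
#' @param model A [pomo_model()] over the same alphabet.
#' @return Probability vector over the state space.
#' @export
stationary_closed_form <- function(space, model) {
  if (!identical(space$alphabet, model$alphabet))
    stop("state space and mutation model use different alphabets",
         call. = FALSE)
  N <- space$N
  w <- numeric(space$n_states)
  w[seq_along(space$alphabet)] <- model$pi
  q <- mutation_rates(model)
  for (p in seq_len(nrow(space$pairs))) {
    a <- space$pairs[p, 1L]; b <- space$pairs[p, 2L]
    i <- seq_len(N - 1L)
    # pi_a * q_ab = mu rho_ab pi_a pi_b, symmetric in (a, b)
    w[space$poly_index[p, ]] <- model$pi[a] * q[a, b] * N / (i * (N - i))
  }
  w / sum(w)
}

#' Numeric stationary distribution (null left eigenvector)
#'
#' Solves `stationary %*% Q = 0` by eigendecomposition of `t(Q)`, falling
#' back to an augmented linear system if the eigensolve is ill-conditioned.
#' Entries are clamped at zero and renormalized.
#'
#' @param Q Square rate matrix (zero row sums).
#' @return Probability vector.
#' @export
stationary_numeric <- function(Q) {
  n <- nrow(Q)
  e <- eigen(t(Q))
  k <- which.min(abs(e$values))
  v <- Re(e$vectors[, k])
  if (abs(Re(e$values[k])) > 1e-6 * max(abs(Q))) {
    # fall back: solve the augmented system [t(Q); 1] x = [0; 1]
    Aug <- rbind(t(Q), rep(1, n))
    v <- qr.solve(Aug, c(rep(0, n), 1))
  }
  v <- Re(v)
  if (sum(v) < 0) v <- -v     # eigenvectors are defined up to sign
  v <- pmax(v, 0)
  if (sum(v) <= 0)
    stop("stationary solve failed: null eigenvector is degenerate",
         call. = FALSE)
  v / sum(v)
}

#' Total stationary polymorphic probability mass
#'
#' @param space A [pomo_states()] object.
#' @param model A [pomo_model()].
#' @return Probability that a site is in a polymorphic state at
#'   stationarity (the package's operational heterozygosity).
#' @export
stationary_polymorphic_mass <- function(space, model) {
  stat <- stationary_closed_form(space, model)
  sum(stat[space$type == "poly"])
}

#' Calibrate the mutation magnitude to a target heterozygosity
#'
#' Heterozygosity is operationalized as the total stationary probability
#' of the polymorphic states.  This quantity is strictly increasing in the
#' mutation magnitude `mu`, so a one-dimensional monotone root solve
#' (on log `mu`) recovers the magnitude matching any attainable target.
#' The boundary mutation approximation degrades above theta = 0.1, so a
#' warning is emitted for larger targets.
#'
#' @param model A [pomo_model()]; its `mu` is replaced.
#' @param space A [pomo_states()] object.
#' @param theta Target heterozygosity, 0 < theta < 1.
#' @return The model with `mu` set so the stationary polymorphic mass
#'   equals `theta` (to ~1e-12).
#' @examples
#' s <- pomo_states(10)
#' m <- calibrate_heterozygosity(pomo_model("HKY", pi = c(.3,.2,.2,.3),
#'                                          kappa = 6.25), s, 0.005)
#' stationary_polymorphic_mass(s, m)  # 0.005
#' @export
calibrate_heterozygosity <- function(model, space, theta) {
  if (!is.finite(theta) || theta <= 0 || theta >= 1)
    stop("'theta' must lie strictly between 0 and 1 ",
         "(attainable range is (0, 1))", call. = FALSE)
  if (theta > 0.1)
    warning("theta = ", theta, " exceeds 0.1; the boundary mutation ",
            "approximation (no mutation in polymorphic states) becomes ",
            "unreliable", call. = FALSE)
  f <- function(log_mu) {
    m <- model; m$mu <- exp(log_mu)
    stationary_polymorphic_mass(space, m) - theta
  }
  lo <- log(1e-12); hi <- log(1e8)
  if (f(lo) > 0 || f(hi) < 0)
    stop("theta = ", theta, " is outside the attainable range for this ",
         "model/space", call. = FALSE)
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
  model$mu <- exp(root)
  model
}

#' Conversion between event and substitution branch-length units
#'
#' The package measures branch lengths in expected events (mutations plus
#' drift frequency shifts) per site.  Classical substitution models
#' measure them in expected substitutions (allele fixations) per site.
#' At stationarity of the reversible boundary mutation model the total
#' event rate is exactly `N` times the mutation flux out of monomorphic
#' states (each mutation triggers on average `N - 1` drift events), while
#' the substitution rate is the mutation flux times the Moran fixation
#' probability `1/N` of a novel allele at frequency `1/N`.  One expected
#' substitution per site therefore corresponds to exactly `N^2` expected
#' events per site, independent of the mutation parameters.
#'
#' @param space A [pomo_states()] object (only `N` is used).
#' @return The scalar `N^2`.
#' @export
events_per_substitution <- function(space) {
  N <- if (inherits(space, "pomo_states")) space$N else space
  if (!is.finite(N) || N < 2) stop("invalid 'space'", call. = FALSE)
  N^2
}

#' Symmetrized eigendecomposition of a reversible rate matrix
#'
#' A reversible `Q` with stationary law `pi` satisfies
#' `D Q D^-1` symmetric for `D = diag(sqrt(pi))`, so a real symmetric
#' eigensolve yields `Q = D^-1 U L U' D` and
#' `expm(Q t) = D^-1 U exp(L t) U' D`.  The decomposition is cached per
#' rate matrix and reused for every branch.
#'
#' @param rates A `pomo_rates` object.
#' @return List with `U`, `lambda`, `d` (= sqrt stationary) and
#'   `inv_d`.
#' @export
decompose_rates <- function(rates) {
  stat <- pmax(rates$stationary, 1e-300)
  d <- sqrt(stat)
  # (diag(d) %*% Q %*% diag(1/d))[i, j] = d_i Q_ij / d_j
  S <- sweep(sweep(rates$Q, 1L, d, `*`), 2L, d, `/`)
  S <- (S + t(S)) / 2   # enforce exact symmetry against rounding
  e <- eigen(S, symmetric = TRUE)
  list(U = e$vectors, lambda = e$values, d = d, inv_d = 1 / d)
}

#' Transition probability matrix exp(Q t)
#'
#' Computed from the symmetrized eigendecomposition of the reversible
#' generator; tiny negative entries produced by rounding are clamped at
#' zero and rows renormalized.
#'
#' @param rates A `pomo_rates` object (or a cached [decompose_rates()]
#'   result via `decomp`).
#' @param t Nonnegative branch length.
#' @param decomp Optional precomputed decomposition.
#' @return Stochastic matrix `exp(Q t)`.
#' @export
transition_probabilities <- function(rates, t, decomp = NULL) {
  if (!is.finite(t) || t < 0)
    stop("branch length 't' must be nonnegative", call. = FALSE)
  if (is.null(decomp)) decomp <- decompose_rates(rates)
  P <- expm_decomp(decomp, t)
  P
}

# exp(Q t) from a cached decomposition; clamps at -1e-12 then renormalizes
expm_decomp <- function(decomp, t) {
  E <- decomp$U %*% (exp(decomp$lambda * t) * t(decomp$U))
  P <- sweep(sweep(E, 1L, decomp$inv_d, `*`), 2L, decomp$d, `*`)
  P[P < 0] <- 0
  P / rowSums(P)
}
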