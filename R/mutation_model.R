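#' Reversible nucleotide mutation model
#'
#' Parameterizes the mutation rates \eqn{q_{ab}} that feed the boundary
#' mutation model.  All supported models are time-reversible:
#' \eqn{q_{ab} = \mu \, \rho_{ab} \, \pi_b} with symmetric exchangeabilities
#' \eqn{\rho_{ab}}, stationary allele frequencies \eqn{\pi} and an overall
#' magnitude \eqn{\mu}, so that \eqn{\pi_a q_{ab} = \pi_b q_{ba}}.
#'
#' * `"JC"` — all exchangeabilities equal, uniform \eqn{\pi}.
#' * `"HKY"` — \eqn{\rho_{ab} = \kappa} for transitions (A<->G, C<->T),
#'   1 for transversions; free \eqn{\pi}.
#' * `"GTR"` — six free exchangeabilities (order AC, AG, AT, CG, CT, GT
#'   for the nucleotide alphabet), free \eqn{\pi}.
#' * `"custom"` — any symmetric nonnegative exchangeability matrix over an
#'   arbitrary alphabet.
#'
#' The magnitude \eqn{\mu} is usually not set directly but calibrated to a
#' target heterozygosity with [calibrate_heterozygosity()].
#'
#' @param name One of `"JC"`, `"HKY"`, `"GTR"`, `"custom"`.
#' @param pi Stationary allele frequencies (strictly positive, summed to 1;
#'   defaults to uniform).  Ignored for `"JC"` (forced uniform).
#' @param kappa Transition/transversion rate ratio (HKY only).
#' @param exchangeabilities For `"GTR"`, the six upper-triangle rates in
#'   the order AC, AG, AT, CG, CT, GT; for `"custom"`, a full symmetric
#'   matrix.
#' @param mu Overall mutation magnitude (default 1).
#' @param alphabet Allele symbols; default nucleotides.
#'
#' @return An object of class `pomo_model` with fields `name`, `alphabet`,
#'   `pi`, `kappa`, `exch` (full symmetric exchangeability matrix) and `mu`.
#' @examples
#' m <- pomo_model("HKY", pi = c(0.3, 0.2, 0.2, 0.3), kappa = 6.25)
#' mutation_rate(m, "A", "G") / mutation_rate(m, "A", "C")  # 6.25
#' @export
pomo_model <- function(name = c("HKY", "JC", "GTR", "custom"),
                       pi = NULL, kappa = NULL, exchangeabilities = NULL,
                       mu = 1, alphabet = c("A", "C", "G", "T")) {
  name <- match.arg(name)
  A <- length(alphabet)
  if (A < 2L) stop("alphabet must have at least 2 symbols", call. = FALSE)
  if (is.null(pi)) pi <- rep(1 / A, A)
  if (name == "JC") pi <- rep(1 / A, A)
  if (length(pi) != A || any(!is.finite(pi)) || any(pi <= 0))
    stop("'pi' must be strictly positive with one entry per allele",
         call. = FALSE)
  pi <- pi / sum(pi)
  if (!is.finite(mu) || mu <= 0) stop("'mu' must be positive", call. = FALSE)

  exch <- matrix(1, A, A)
  if (name == "HKY") {
    if (A != 4L) stop("HKY requires the 4-letter nucleotide alphabet",
                      call. = FALSE)
    if (is.null(kappa)) kappa <- 1
    if (!is.finite(kappa) || kappa <= 0)
      stop("'kappa' must be positive", call. = FALSE)
    exch[1L, 3L] <- exch[3L, 1L] <- kappa   # A <-> G
    exch[2L, 4L] <- exch[4L, 2L] <- kappa   # C <-> T
  } else if (name == "GTR") {
    if (A != 4L) stop("GTR requires the 4-letter nucleotide alphabet",
                      call. = FALSE)
    r <- exchangeabilities
    if (is.null(r) || length(r) != 6L || any(!is.finite(r)) || any(r <= 0))
      stop("GTR needs 6 positive exchangeabilities (AC, AG, AT, CG, CT, GT)",
           call. = FALSE)
    exch[1L, 2L] <- exch[2L, 1L] <- r[1L]
    exch[1L, 3L] <- exch[3L, 1L] <- r[2L]
    exch[1L, 4L] <- exch[4L, 1L] <- r[3L]
    exch[2L, 3L] <- exch[3L, 2L] <- r[4L]
    exch[2L, 4L] <- exch[4L, 2L] <- r[5L]
    exch[3L, 4L] <- exch[4L, 3L] <- r[6L]
    kappa <- NULL
  } else if (name == "custom") {
    exch <- as.matrix(exchangeabilities)
    if (is.null(exchangeabilities) || !isSymmetric(unname(exch)) ||
        nrow(exch) != A || any(exch[upper.tri(exch)] < 0))
      stop("custom model needs a symmetric nonnegative exchangeability ",
           "matrix matching the alphabet", call. = FALSE)
    kappa <- NULL
  } else {
    kappa <- NULL
  }
  diag(exch) <- 0

  structure(list(name = name, alphabet = as.character(alphabet), pi = pi,
                 kappa = kappa, exch = exch, mu = mu),
            class = "pomo_model")
}

#' @export
print.pomo_model <- function(x, ...) {
  cat(sprintf("%s mutation model (mu = %g)\n", x$name, x$mu))
  cat("  pi:", paste(sprintf("%s=%.4g", x$alphabet, x$pi), collapse = " "), "\n")
  if (!is.null(x$kappa)) cat(sprintf("  kappa: %g\n", x$kappa))
  invisible(x)
}

#' Full matrix of mutation rates q_ab
#'
#' @param model A [pomo_model()].
#' @return `|A| x |A|` matrix with `q[a, b] = mu * rho_ab * pi_b` and zero
#'   diagonal.
#' @export
mutation_rates <- function(model) {
  q <- model$mu * model$exch * rep(model$pi, each = length(model$pi))
  dimnames(q) <- list(model$alphabet, model$alphabet)
  q
}

#' Single mutation rate q_ab
#'
#' @param model A [pomo_model()].
#' @param a,b Distinct allele symbols.
#' @return The rate \eqn{q_{ab}}.
#' @export
mutation_rate <- function(model, a, b) {
  ia <- match(a, model$alphabet); ib <- match(b, model$alphabet)
  if (is.na(ia) || is.na(ib))
    stop("allele not in model alphabet", call. = FALSE)
  if (ia == ib) stop("'a' and 'b' must be distinct alleles", call. = FALSE)
  mutation_rates(model)[ia, ib]
}
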