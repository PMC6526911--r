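test_that("degenerate mixtures collapse to unit rate modifiers", {
  expect_equal(discretize_gamma(0.7, 1)$rates, 1)
  expect_equal(discretize_gamma(5, 1)$rates, 1)
  g <- discretize_gamma(1e6, 4)
  expect_true(all(abs(g$rates - 1) < 1e-2))
})

test_that("category rates are the slice means of the mean-one Gamma", {
  # independent oracle: adaptive quadrature over each equal-probability slice
  quad_rates <- function(alpha, K) {
    br <- c(0, stats::qgamma(seq_len(K - 1) / K, alpha, rate = alpha), Inf)
    vapply(seq_len(K), function(k) {
      stats::integrate(function(x) x * stats::dgamma(x, alpha, rate = alpha),
                       br[k], br[k + 1], rel.tol = 1e-12)$value * K
    }, 0)
  }
  for (alpha in c(0.3, 1, 5)) {
    g <- discretize_gamma(alpha, 4)
    expect_equal(g$rates, quad_rates(alpha, 4), tolerance = 1e-8)
  }
  # cross-check against an established independent implementation
  expect_equal(discretize_gamma(0.5, 4)$rates,
               as.numeric(phangorn::discrete.gamma(0.5, 4)),
               tolerance = 1e-10)
})

test_that("mixture invariants: mean one, strictly increasing, weights 1/K", {
  set.seed(404)
  for (rep in 1:20) {
    alpha <- exp(stats::runif(1, log(0.02), log(50)))
    K <- sample(2:8, 1)
    g <- discretize_gamma(alpha, K)
    expect_equal(sum(g$weights * g$rates), 1, tolerance = 1e-10)
    expect_true(all(diff(g$rates) > 0))
    expect_equal(g$weights, rep(1 / K, K))
  }
  expect_error(discretize_gamma(-1, 4), "alpha")
  expect_error(discretize_gamma(0.001, 4), "degenerate")
  expect_error(discretize_gamma(1, 0), "K")
})

test_that("category matrices scale only the mutation part with a shared scale", {
  space <- pomo_states(6)
  model <- calibrate_heterozygosity(
    pomo_model("HKY", pi = c(.3, .2, .2, .3), kappa = 6.25), space, 0.01)
  QM <- build_mutation_matrix(space, model)
  QD <- build_drift_matrix(space)
  g <- discretize_gamma(0.5, 4)
  cats <- category_matrices(QM, QD, g, space, model)
  scale <- cats[[1]]$scale
  # unit modifiers reproduce the homogeneous matrix
  g1 <- discretize_gamma(1e7, 4)
  hom <- category_matrices(QM, QD, g1, space, model)
  base <- assemble_rate_matrix(QM, QD, space = space, model = model)
  expect_equal(hom[[2]]$Q, base$Q, tolerance = 1e-9)
  # Q2 - Q1 = (r2 - r1) QM (on the shared scale)
  expect_equal(cats[[2]]$Q - cats[[1]]$Q,
               (g$rates[2] - g$rates[1]) * QM / scale, tolerance = 1e-12)
  # drift entries identical across categories
  poly <- which(space$type == "poly")
  for (k in 2:4)
    expect_equal(cats[[k]]$Q[poly, ], cats[[1]]$Q[poly, ])
})

test_that("mixture site likelihood is the category mean", {
  expect_equal(mixture_site_likelihood(0.42), 0.42)
  expect_equal(mixture_site_likelihood(rep(0.7, 5)), 0.7)
  expect_equal(mixture_site_likelihood(c(0.1, 0.3)), 0.2)
  expect_error(mixture_site_likelihood(numeric(0)), "at least one")
  expect_error(mixture_site_likelihood(c(0.1, -0.2)), "nonnegative")
})

test_that("degenerate-Gamma mixture log likelihood matches the homogeneous model", {
  set.seed(11)
  tr <- read_newick("((a:0.3,b:0.5):0.2,c:0.6);")
  m <- pomo_model("HKY", pi = c(.3, .2, .2, .3), kappa = 6.25)
  sim <- simulate_counts(tree = tr, model = m, N = 6, theta = 0.01,
                         n_sites = 400, M = 8, seed = 5)
  ll_hom <- pomo_loglik(tr, sim$aln, m, N = 6, theta = 0.01)
  ll_mix <- pomo_loglik(tr, sim$aln, m, N = 6, theta = 0.01,
                        mix = discretize_gamma(1e6, 4))
  expect_lt(abs(ll_hom - ll_mix) / 400, 1e-4)
  # permutation invariance of the categories
  mix <- discretize_gamma(0.8, 4)
  perm <- mix; perm$rates <- rev(perm$rates)
  expect_equal(pomo_loglik(tr, sim$aln, m, N = 6, theta = 0.01, mix = mix),
               pomo_loglik(tr, sim$aln, m, N = 6, theta = 0.01, mix = perm))
})

test_that("cached eigendecompositions agree with fresh recomputation", {
  space <- pomo_states(5)
  model <- calibrate_heterozygosity(pomo_model("JC"), space, 0.01)
  cats <- pomotree:::build_categories(space, model, discretize_gamma(0.5, 3))
  for (cat in cats) {
    fresh <- decompose_rates(cat$rates)
    expect_equal(pomotree:::expm_decomp(cat$decomp, 0.2), pomotree:::expm_decomp(fresh, 0.2),
                 tolerance = 1e-12)
  }
})
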