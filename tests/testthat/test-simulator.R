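test_that("Yule rate follows the harmonic-number formula", {
  expect_equal(yule_rate(12, 0.01), (sum(1 / (1:12)) - 1) / 0.01)
  expect_equal(yule_rate(12, 0.01), 210.321, tolerance = 1e-3)
  expect_equal(yule_rate(2, 1), 0.5)
  expect_equal(yule_rate(40, 0.005), 2 * yule_rate(40, 0.01))
  expect_error(yule_rate(1, 1), "n")
  expect_error(yule_rate(5, 0), "h")
})

test_that("Yule trees are ultrametric at exactly height h and seed-reproducible", {
  tr <- sample_yule_tree(12, 0.01, seed = 71)
  depths <- ape::node.depth.edgelength(tr)
  tip_depths <- depths[seq_along(tr$tip.label)]
  expect_true(all(abs(tip_depths - 0.01) < 1e-14))
  expect_identical(write_newick(sample_yule_tree(12, 0.01, seed = 72)),
                   write_newick(sample_yule_tree(12, 0.01, seed = 72)))
  # mean leaf count matches the pure-birth expectation 2 exp(lambda h)
  lam <- yule_rate(12, 0.01)
  set.seed(73)
  sizes <- replicate(2000, length(sample_yule_tree(12, 0.01)$tip.label))
  expect_lt(abs(mean(sizes) - 2 * exp(lam * 0.01)) / (2 * exp(lam * 0.01)),
            0.1)
})

test_that("complete sampling of a star tip reproduces the stationary distribution", {
  space <- pomo_states(10)
  m <- calibrate_heterozygosity(
    pomo_model("HKY", pi = c(.3, .2, .2, .3), kappa = 6.25), space, 0.05)
  tr <- read_newick("(a:0,b:0);")
  sim <- simulate_counts(tree = tr, model = m, N = 10, theta = 0.05,
                         n_sites = 2e5, M = 10, seed = 79)
  # M = N with branch length 0: leaf states are stationary draws
  st <- sim$leaf_states[1, ]
  obs <- tabulate(st, nbins = space$n_states)
  r <- pomo_rate_matrix(space, m)
  expected <- r$stationary * length(st)
  keep <- expected >= 5   # chi-square validity
  chi <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  expect_lt(chi, stats::qchisq(0.99, df = sum(keep) - 1))
})

test_that("simulated polymorphism matches the calibrated heterozygosity", {
  space <- pomo_states(10)
  m <- pomo_model("HKY", pi = c(.3, .2, .2, .3), kappa = 6.25)
  sim <- simulate_counts(tree = read_newick("(a:0,b:0);"), model = m,
                         N = 10, theta = 0.005, n_sites = 2e5, M = 10,
                         seed = 83)
  frac <- mean(space$type[sim$leaf_states[1, ]] == "poly")
  se <- sqrt(0.005 * 0.995 / 2e5)
  expect_lt(abs(frac - 0.005), 3 * se)
})

test_that("a fixed seed reproduces the counts file bit for bit", {
  m <- pomo_model("HKY", pi = c(.3, .2, .2, .3), kappa = 6.25)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  s1 <- simulate_counts(model = m, N = 5, theta = 0.01, n_sites = 300,
                        M = 6, n_species = 5, height = 0.005, seed = 89)
  s2 <- simulate_counts(model = m, N = 5, theta = 0.01, n_sites = 300,
                        M = 6, n_species = 5, height = 0.005, seed = 89)
  write_counts(s1$aln, f1); write_counts(s2$aln, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(write_newick(s1$tree), write_newick(s2$tree))
})

test_that("site categories are uniform over K", {
  m <- pomo_model("JC")
  sim <- simulate_counts(tree = read_newick("(a:0.1,b:0.1);"), model = m,
                         N = 4, theta = 0.01, K = 4, alpha = 0.5,
                         n_sites = 2e4, M = 4, seed = 97)
  obs <- tabulate(sim$categories, 4)
  chi <- sum((obs - 5e3)^2 / 5e3)
  expect_lt(chi, stats::qchisq(0.99, df = 3))
})

test_that("matrix-exponential branch sampling agrees with Gillespie simulation", {
  space <- pomo_states(4, c("A", "C"))
  m <- calibrate_heterozygosity(pomo_model("JC", alphabet = c("A", "C")),
                                space, 0.1)
  r <- pomo_rate_matrix(space, m)
  t_br <- 0.8
  P <- transition_probabilities(r, t_br)
  start <- 1L
  set.seed(101)
  draws <- replicate(4000, simulate_branch_gillespie(r, t_br, start))
  obs <- tabulate(draws, space$n_states)
  expected <- P[start, ] * 4000
  keep <- expected >= 5
  chi <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  expect_lt(chi, stats::qchisq(0.99, df = sum(keep) - 1))
})

test_that("longer branches produce more observable divergence between sisters", {
  m <- pomo_model("HKY", pi = c(.3, .2, .2, .3), kappa = 6.25)
  diverg <- function(scale, seed) {
    tr <- read_newick(sprintf("(a:%g,b:%g);", scale, scale))
    sim <- simulate_counts(tree = tr, model = m, N = 5, theta = 0.005,
                           n_sites = 5000, M = 10, seed = seed)
    mean(sim$leaf_states[1, ] != sim$leaf_states[2, ])
  }
  for (seed in c(1, 2, 3))
    expect_gt(diverg(1.0, seed), diverg(0.25, seed))
})
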