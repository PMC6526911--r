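test_that("a single population at a zero-length star reduces to a stationary dot product", {
  space <- pomo_states(6)
  m <- calibrate_heterozygosity(pomo_model("HKY", pi = c(.3, .2, .2, .3),
                                           kappa = 6.25), space, 0.01)
  aln <- pomo_counts(list(a = rbind(c(4L, 0L, 0L, 0L)),
                          b = rbind(c(4L, 0L, 0L, 0L))))
  tr <- read_newick("(a:0,b:0);")
  ll <- pomo_loglik(tr, aln, m, N = 6)
  r <- pomo_rate_matrix(space, m)
  La <- init_weighted_binomial(c(4, 0, 0, 0), space)
  expect_equal(ll, log(sum(r$stationary * La * La)), tolerance = 1e-10)
})

test_that("pruning equals exhaustive state-assignment enumeration (small instances)", {
  set.seed(606)
  for (rep in 1:6) {
    nA <- sample(2:3, 1)
    N <- sample(2:4, 1)
    alphabet <- c("A", "C", "G", "T")[seq_len(nA)]
    space <- pomo_states(N, alphabet)
    model <- random_reversible(alphabet)
    n_taxa <- sample(3:4, 1)
    nw <- if (n_taxa == 3) "((a:%g,b:%g):%g,c:%g);"
    else "((a:%g,b:%g):%g,(c:%g,d:%g):%g);"
    lens <- stats::runif(if (n_taxa == 3) 4 else 6, 0.02, 0.8)
    tr <- read_newick(do.call(sprintf, c(list(nw), as.list(lens))))
    sim <- simulate_counts(tree = tr, model = model, N = N, theta = NULL,
                           n_sites = 5, M = 5, seed = rep)
    mix <- if (rep %% 2 == 0) discretize_gamma(0.7, 2)
    ll <- pomo_loglik(tr, sim$aln, model, N = N, mix = mix)
    oracle <- brute_force_loglik(tr, sim$aln, model, space, mix)
    expect_equal(ll, oracle, tolerance = 1e-8)
  }
})

test_that("pattern weights are linear: duplicating sites doubles the log likelihood", {
  tr <- read_newick("((a:0.2,b:0.4):0.3,c:0.5);")
  m <- pomo_model("HKY", pi = c(.3, .2, .2, .3), kappa = 6.25)
  sim <- simulate_counts(tree = tr, model = m, N = 5, theta = 0.01,
                         n_sites = 60, M = 6, seed = 8)
  ll <- pomo_loglik(tr, sim$aln, m, N = 5, theta = 0.01)
  doubled <- pomo_counts(lapply(sim$aln$counts, function(x) rbind(x, x)))
  expect_equal(pomo_loglik(tr, doubled, m, N = 5, theta = 0.01), 2 * ll)
})

test_that("likelihood is invariant to site order (pattern compression)", {
  tr <- read_newick("((a:0.2,b:0.4):0.3,c:0.5);")
  m <- pomo_model("HKY", pi = c(.3, .2, .2, .3), kappa = 6.25)
  sim <- simulate_counts(tree = tr, model = m, N = 5, theta = 0.01,
                         n_sites = 80, M = 6, seed = 13)
  perm <- sample(80)
  shuffled <- pomo_counts(lapply(sim$aln$counts,
                                 function(x) x[perm, , drop = FALSE]))
  expect_equal(pomo_loglik(tr, shuffled, m, N = 5, theta = 0.01),
               pomo_loglik(tr, sim$aln, m, N = 5, theta = 0.01))
})

test_that("root placement is immaterial for reversible models (pulley principle)", {
  m <- pomo_model("HKY", pi = c(.3, .2, .2, .3), kappa = 6.25)
  sim <- simulate_counts(tree = read_newick("((a:0.3,b:0.5):0.2,c:0.6);"),
                         model = m, N = 5, theta = 0.01, n_sites = 50,
                         M = 6, seed = 17)
  # the same unrooted tree rooted at different points along the c branch
  vals <- vapply(c(0.05, 0.3, 0.55), function(x) {
    tr <- read_newick(sprintf("((a:0.3,b:0.5):%g,c:%g);", 0.2 + x, 0.6 - x))
    pomo_loglik(tr, sim$aln, m, N = 5, theta = 0.01)
  }, 0)
  expect_lt(max(vals) - min(vals), 1e-8)
})

test_that("label mismatches and invalid trees are rejected", {
  m <- pomo_model("JC")
  aln <- pomo_counts(list(a = rbind(c(2L, 0L, 0L, 0L)),
                          b = rbind(c(2L, 0L, 0L, 0L))))
  expect_error(pomo_loglik(read_newick("(a:1,x:1);"), aln, m), "match")
  expect_error(pomo_loglik(read_newick("(a:-1,b:1);"), aln, m), "negative")
})
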