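space10 <- pomo_states(10)

test_that("weighted binomial values follow the sampling-with-replacement formula", {
  L <- init_weighted_binomial(c(1, 1, 0, 0), space10)  # {1A|1C}, M=2, j=1
  expect_equal(L[state_index(space10, "A", "C", 5)], 0.5)
  expect_equal(L[state_index(space10, "A", "C", 2)], 2 * 0.2 * 0.8)
  # polymorphic observation excludes monomorphic states
  expect_equal(L[1:4], rep(0, 4))
  # monomorphic observation {2A}
  L2 <- init_weighted_binomial(c(2, 0, 0, 0), space10)
  expect_equal(L2[state_index(space10, "A")], 1)
  expect_equal(L2[state_index(space10, "C")], 0)
  expect_equal(L2[state_index(space10, "A", "C", 5)], 0.25)
  expect_equal(L2[state_index(space10, "A", "G", 3)], 0.09)
  # states not containing an observed allele stay zero
  expect_equal(L2[state_index(space10, "C", "G", 4)], 0)
})

test_that("weighted hypergeometric values follow sampling without replacement", {
  L <- init_weighted_hypergeometric(c(1, 1, 0, 0), space10)
  expect_equal(L[state_index(space10, "A", "C", 5)], 25 / 45)
  expect_equal(L[state_index(space10, "A", "C", 1)],
               choose(1, 1) * choose(9, 1) / choose(10, 2))
  # M = N makes it an exact indicator of the observed frequencies
  L2 <- init_weighted_hypergeometric(c(3, 7, 0, 0), space10)
  expect_equal(sum(L2), 1)
  expect_equal(L2[state_index(space10, "A", "C", 3)], 1)
  # M > N is undefined
  expect_error(init_weighted_hypergeometric(c(5, 6, 0, 0), space10),
               "undefined")
})

test_that("observation-side sums recover the binomial and hypergeometric pmfs", {
  s <- pomo_states(12)
  for (M in c(1, 5, 12)) for (i in c(1, 4, 11)) {
    bin_sum <- 0; hyp_sum <- 0
    for (j in 0:M) {
      obs <- c(j, M - j, 0, 0)
      idx <- state_index(s, "A", "C", i)
      Lb <- suppressWarnings(init_weighted_binomial(obs, s))
      Lh <- suppressWarnings(init_weighted_hypergeometric(obs, s))
      bin_sum <- bin_sum + Lb[idx]
      hyp_sum <- hyp_sum + Lh[idx]
    }
    expect_equal(bin_sum, 1, tolerance = 1e-12)
    expect_equal(hyp_sum, 1, tolerance = 1e-12)
  }
})

test_that("hypergeometric converges to binomial for large N at fixed i/N", {
  s <- pomo_states(200)
  obs <- c(3, 2, 0, 0)   # M = 5
  Lb <- init_weighted_binomial(obs, s)
  Lh <- init_weighted_hypergeometric(obs, s)
  idx <- state_index(s, "A", "C", 120)  # i/N = 0.6
  expect_lt(abs(Lh[idx] - Lb[idx]) / Lb[idx], 0.02)
})

test_that("missing and unrepresentable observations are handled per contract", {
  expect_warning(L <- init_weighted_binomial(c(0, 0, 0, 0), space10),
                 "missing")
  expect_equal(L, rep(1, space10$n_states))
  expect_error(init_weighted_binomial(c(1, 1, 1, 0), space10),
               "segregating")
  expect_error(init_weighted_hypergeometric(c(1, 1, 1, 1), space10),
               "segregating")
  expect_error(init_sampled(c(1, 1, 1, 0), space10), "segregating")
})

test_that("sampled strategy is deterministic for monomorphic input and binomial otherwise", {
  L <- init_sampled(c(0, 7, 0, 0), space10)
  expect_equal(L[state_index(space10, "C")], 1)
  expect_equal(sum(L), 1)
  # empirical distribution of the sampled allele-A count follows
  # Binomial(N, 1/2) for a balanced {1A|1C} observation
  set.seed(55)
  n_draw <- 1e5
  counts <- integer(space10$N + 1)
  pA <- state_index(space10, "A")
  for (d in seq_len(n_draw)) {
    L <- init_sampled(c(1, 1, 0, 0), space10)
    st <- which(L == 1)
    i <- if (st == pA) space10$N
    else if (space10$type[st] == "mono") 0L
    else space10$i[st]
    counts[i + 1] <- counts[i + 1] + 1L
  }
  expected <- stats::dbinom(0:10, 10, 0.5) * n_draw
  chi <- sum((counts - expected)^2 / expected)
  expect_lt(chi, stats::qchisq(0.99, df = 10))
})
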