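test_that("coin-flip neuron honours its selection probabilities", {
  rng <- rng_stream(101L)
  # b = 0 forces the first input
  for (i in 1:25) expect_identical(coin_flip_select(5, 0, rng), 1L)
  for (i in 1:25) expect_identical(coin_flip_select(0, 2, rng), 2L)
  # a/(a+b) = 1/4
  n <- 20000L
  hits <- sum(vapply(seq_len(n), function(i)
    coin_flip_select(1, 3, rng) == 1L, logical(1)))
  expect_lt(abs(hits / n - 0.25), 3 * sqrt(0.25 * 0.75 / n))
  expect_error(coin_flip_select(-1, 0, rng), "contract violation")
  expect_error(coin_flip_select(Inf, 0, rng), "contract violation")
})

test_that("local competitions merge by summation and keep the winner's identity", {
  g <- gist("left", tags = "vision")
  l <- chunk(0L, 2L, g, 2)
  r <- chunk(1L, 2L, gist("right", tags = "vision"), -1)
  rng <- rng_stream(5L)
  f <- competition_function(0)
  n <- 3000L
  lwins <- 0L
  for (i in seq_len(n)) {
    m <- local_compete(l, r, f, rng)
    expect_equal(m$intensity, 3)
    expect_equal(m$mood, 1)
    expect_true(m$address %in% c(0L, 1L))
    if (m$address == 0L) {
      lwins <- lwins + 1L
      expect_true(gist_equal(m$gist, g))
      expect_identical(m$weight, 2)
    }
  }
  p <- 2 / 3
  expect_lt(abs(lwins / n - p), 3 * sqrt(p * (1 - p) / n))
  # a positive-f chunk always beats the null chunk
  for (i in 1:20) {
    m <- local_compete(l, null_chunk(), f, rng)
    expect_identical(m$address, 0L)
    expect_equal(m$intensity, l$intensity)
  }
  # all-zero pair: either side, merged sums are zero
  m0 <- local_compete(null_chunk(2L, 0L), null_chunk(3L, 0L), f, rng)
  expect_equal(m0$intensity, 0)
  expect_equal(m0$mood, 0)
})

test_that("tournament conserves intensity and mood and preserves identity", {
  rng <- rng_stream(33L)
  f <- competition_function(0.5)
  for (i in 1:40) {
    n <- 4L + as.integer(floor(9 * rng_unif(rng, 1L)))  # 4..12 leaves, exercises padding
    w <- round(10 * (rng_unif(rng, n) - 0.4), 3)
    leaves <- make_leaves(w)
    root <- run_competition(leaves, f, rng)
    expect_equal(root$intensity, sum(abs(w)), tolerance = 1e-9)
    expect_equal(root$mood, sum(w), tolerance = 1e-9)
    src <- leaves[[root$address + 1L]]
    expect_identical(root$weight, src$weight)
    expect_identical(root$t, src$t)
    expect_true(gist_equal(root$gist, src$gist))
  }
})

test_that("exact oracle equals f/sum(f) for additive f and is uniform at all-zero", {
  lv <- c(3, 1, 2, 2, 0, 4, 1, 3)
  leaves <- make_leaves(lv)
  for (cc in c(0, 0.5, -0.5, 1)) {
    f <- competition_function(cc)
    fv <- vapply(leaves, function(ch) evaluate_f(f, ch), numeric(1))
    tab <- exact_win_probabilities(leaves, f)
    expect_lt(max(abs(tab$probability - fv / sum(fv))), 1e-12)
    expect_lt(abs(sum(tab$probability) - 1), 1e-12)
  }
  zero <- exact_win_probabilities(make_leaves(rep(0, 8)), competition_function(0))
  expect_lt(max(abs(zero$probability - 1 / 8)), 1e-12)
  # positivity: every leaf with positive f-value has positive win probability
  tab <- exact_win_probabilities(leaves, competition_function(0))
  expect_true(all(tab$probability[tab$f_value > 0] > 0))
  expect_equal(tab$probability[5L], 0)   # the zero-weight leaf under f = intensity
})

test_that("Monte-Carlo frequencies agree with the oracle", {
  lv <- c(3, 1, 2, 2, 0, 4, 1, 3)
  leaves <- make_leaves(lv)
  f <- competition_function(0)
  tab <- exact_win_probabilities(leaves, f)
  runs <- 2e4L
  counts <- simulate_win_counts(leaves, f, runs, rng_stream(77L))
  for (k in seq_along(lv)) {
    p <- tab$probability[k]
    se <- sqrt(p * (1 - p) / runs)
    expect_lt(abs(counts[k] / runs - p), 3 * se + 1e-12)
  }
  # and the per-call tournament path agrees with the vectorised sampler
  slow <- integer(length(lv))
  rng <- rng_stream(78L)
  for (r in 1:2000) {
    root <- run_competition(leaves, f, rng)
    slow[root$address + 1L] <- slow[root$address + 1L] + 1L
  }
  for (k in seq_along(lv)) {
    p <- tab$probability[k]
    expect_lt(abs(slow[k] / 2000 - p), 4 * sqrt(p * (1 - p) / 2000) + 0.01)
  }
})

test_that("leaf permutation is irrelevant for additive f but not in general", {
  lv <- c(3, 1, 2, 2, 0, 4, 1, 3)
  leaves <- make_leaves(lv)
  f <- competition_function(0.25)
  base <- exact_win_probabilities(leaves, f)
  by_addr <- function(tab) tab$probability[order(tab$address)]
  rng <- rng_stream(9L)
  for (i in 1:5) {
    perm <- order(rng_unif(rng, length(lv)))
    tab <- exact_win_probabilities(assign_leaves(leaves, perm), f)
    expect_lt(max(abs(by_addr(tab) - by_addr(base))), 1e-12)
  }
  # non-additive counterexample: f = |mood|, moods (+1, -1, +2, -2)
  f_abs <- custom_competition_function(function(ch) abs(ch$mood), "|mood|")
  quad <- make_leaves(c(1, -1, 2, -2))
  t1 <- exact_win_probabilities(quad, f_abs)
  # adjacent pairs cancel: both semifinal chunks carry mood 0, so the final is
  # a fair coin and the table is uniform
  expect_lt(max(abs(t1$probability - 0.25)), 1e-12)
  t2 <- exact_win_probabilities(assign_leaves(quad, c(1L, 3L, 2L, 4L)), f_abs)
  expect_gt(max(abs(by_addr(t2) - by_addr(t1))), 1e-3)
})

test_that("assign_leaves rejects non-bijective orderings", {
  leaves <- make_leaves(c(1, 2, 3, 4))
  expect_error(assign_leaves(leaves, c(1L, 1L, 2L, 3L)), "bijection")
  expect_error(assign_leaves(leaves, c(1L, 2L, 3L)), "bijection")
  ident <- assign_leaves(leaves, 1:4)
  expect_identical(vapply(ident, `[[`, integer(1), "address"), 0:3)
})

test_that("run_competition rejects an empty submission set", {
  expect_error(run_competition(list(), competition_function(0), rng_stream(1)),
               "at least one")
})
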