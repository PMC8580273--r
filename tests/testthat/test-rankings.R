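test_that("full ranking labels order occasions by ascending weight", {
  expect_equal(format(full_rank_label(c(0.2, 0.7, 0.1))), "3|1|2")
  expect_equal(format(full_rank_label(c(0.1, 0.2, 0.7))), "1|2|3")
  expect_error(full_rank_label(c(0.1, NA, 0.2)), "finite")
  expect_error(full_rank_label(0.5), "length")
})

test_that("exact ties merge into one block", {
  expect_equal(format(full_rank_label(c(0, 0, 1))), "1,2|3")
  expect_equal(format(full_rank_label(c(0.75, 0.2, 0.05, 0, 0))), "4,5|3|2|1")
  expect_equal(format(full_rank_label(rep(1 / 4, 4))), "1,2,3,4")
})

test_that("ranking strings canonicalize and validate", {
  expect_equal(format(as_ranking("3,1|2")), "1,3|2")
  expect_equal(format(as_ranking(" 2 | 3 , 1 ")), "2|1,3")
  expect_equal(n_distinctions("1,2,3"), 0L)
  expect_equal(n_distinctions("1|2|3|4"), 3L)
  expect_true(as_ranking("3,1|2") == as_ranking("1,3|2"))
  expect_error(as_ranking("1|1,2"), "partition")
  expect_error(as_ranking("1|3"), "partition")
  expect_error(as_ranking(list(1:2, integer(0), 3), periods = 3), "non-empty")
})

test_that("satisfies applies strict cross-block inequalities", {
  expect_true(satisfies(c(0.1, 0.05, 0.85), "1,2|3"))
  expect_false(satisfies(c(0.5, 0.1, 0.4), "1,2|3"))
  expect_true(satisfies(c(0.2, 0.7, 0.1), "3|1|2"))
  # exact cross-block tie fails
  expect_false(satisfies(c(0.3, 0.3, 0.4), "1|2|3"))
  expect_true(satisfies(c(0.3, 0.3, 0.4), "1,2|3"))
  expect_error(satisfies(c(0.5, 0.5), "1,2|3"), "length")
})

test_that("ranking probability is the satisfying fraction of draws", {
  d <- rbind(c(0.1, 0.2, 0.7), c(0.2, 0.1, 0.7),
             c(0.5, 0.1, 0.4), c(0.25, 0.05, 0.7))
  expect_equal(ranking_probability(d, "1,2|3"), 0.75)
  expect_equal(ranking_probability(d, "1,2,3"), 1)
  one <- matrix(rep(c(0.2, 0.7, 0.1), 50), ncol = 3, byrow = TRUE)
  expect_equal(ranking_probability(one, "3|1|2"), 1)
  expect_error(ranking_probability(d[, 1:2], "1,2|3"), "occasions")
})

test_that("coarsenings merge exactly one adjacent block pair", {
  expect_setequal(vapply(coarsenings("3|1|2"), format, ""), c("1,3|2", "3|1,2"))
  expect_setequal(vapply(coarsenings("1,2|3,4|5"), format, ""),
                  c("1,2,3,4|5", "1,2|3,4,5"))
  expect_length(coarsenings("1,2,3"), 0L)
  # k blocks -> k - 1 candidates, each with one fewer distinction
  p <- as_ranking("1|2|3,4|5,6,7")
  cs <- coarsenings(p)
  expect_length(cs, 3L)
  expect_true(all(vapply(cs, n_distinctions, 0L) == n_distinctions(p) - 1L))
})

test_that("brute-force oracle agrees with ranking_probability", {
  set.seed(42)
  for (k in 3:5) {
    for (rep in 1:5) {
      draws <- random_simplex_draws(200, k)
      blocks <- random_blocks(k)
      p <- as_ranking(blocks, periods = k)
      expect_equal(ranking_probability(draws, p),
                   brute_force_ranking_probability(draws, p$blocks))
    }
  }
})

test_that("full-ranking frequencies partition the draws", {
  set.seed(7)
  draws <- random_simplex_draws(500, 4)
  perms <- all_permutations(4)
  freqs <- apply(perms, 1L, function(perm) {
    ranking_probability(draws, as_ranking(as.list(perm), periods = 4))
  })
  expect_equal(sum(freqs), 1)
})

test_that("coarsening can only increase the probability", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(3:6, 1L)
    draws <- random_simplex_draws(300, k)
    p <- as_ranking(random_blocks(k), periods = k)
    p_base <- ranking_probability(draws, p)
    for (cc in coarsenings(p)) {
      expect_gte(ranking_probability(draws, cc), p_base)
    }
  }
})

test_that("FCR of a degenerate posterior is the point's full ranking", {
  draws <- matrix(rep(c(0.1, 0.2, 0.7), 1000), ncol = 3, byrow = TRUE)
  f <- finest_credible_rank(draws, beta = 0.9)
  expect_equal(format(f$fcr), "1|2|3")
  expect_equal(f$probabilities[1L], 1)
  expect_true(f$conclusive)
})

test_that("FCR coarsens a split posterior until credible", {
  draws <- rbind(matrix(rep(c(0.1, 0.2, 0.7), 600), ncol = 3, byrow = TRUE),
                 matrix(rep(c(0.2, 0.1, 0.7), 400), ncol = 3, byrow = TRUE))
  f <- finest_credible_rank(draws, beta = 0.9)
  expect_equal(format(f$chain[[1L]]), "1|2|3")
  expect_equal(f$probabilities[1L], 0.6)
  expect_equal(format(f$fcr), "1,2|3")
  expect_equal(ranking_probability(draws, f$fcr), 1)
})

test_that("FCR chain is nested, monotone and ends at the vacuous ranking", {
  set.seed(99)
  for (rep in 1:10) {
    k <- sample(3:7, 1L)
    draws <- random_simplex_draws(400, k)
    f <- finest_credible_rank(draws, beta = 0.9)
    expect_length(f$chain, k)  # full ranking down to vacuous
    expect_true(all(diff(f$probabilities) >= 0))
    expect_equal(f$probabilities[k], 1)
    expect_equal(n_distinctions(f$chain[[k]]), 0L)
    # each element merges exactly one adjacent pair of its predecessor
    for (i in seq_len(k - 1L)) {
      expect_true(format(f$chain[[i + 1L]]) %in%
                    vapply(coarsenings(f$chain[[i]]), format, ""))
    }
    # the FCR is the first chain element reaching beta
    first <- which(f$probabilities >= f$beta)[1L]
    expect_equal(format(f$fcr), format(f$chain[[first]]))
  }
  expect_error(finest_credible_rank(matrix(numeric(0), 0, 3)), "non-empty")
  expect_error(finest_credible_rank(random_simplex_draws(10, 3), beta = 1.2),
               "between 0 and 1")
})

test_that("q counts the fraction of preserved distinctions", {
  expect_equal(q_metric("1,2|3,4|5,6|7", "1|2|3|4|5|6|7"), 0.5)
  expect_equal(q_metric("1|2|3", "1|2|3"), 1)
  expect_equal(q_metric("1,2,3", "1|2|3"), 0)
  expect_error(q_metric("1|2|3", "1,2,3"), "undefined")
})

test_that("consistency compares asserted orderings with the truth", {
  expect_false(is_consistent("2|1,3", c(0.2, 0.3, 0.5)))
  expect_true(is_consistent("1,2,3", c(0.9, 0.05, 0.05)))
  expect_true(is_consistent("1,2|3", c(0.1, 0.2, 0.7)))
  # asserting an order between truly tied components is a violation
  expect_false(is_consistent("1|2|3", c(0, 0, 1)))
  expect_true(is_consistent("1,2|3", c(0, 0, 1)))
  # non-adjacent blocks are compared too
  expect_false(is_consistent("1|2|3", c(0.2, 0.5, 0.3)))
  expect_error(is_consistent("1|2|3", c(0.5, 0.5)), "length")
})
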