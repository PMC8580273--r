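test_that("range statistic spans accumulation to critical", {
  expect_equal(range_statistic(rep(1 / 3, 3)), 0)
  expect_equal(range_statistic(c(0, 0, 1)), 1)
  expect_equal(range_statistic(c(0.2, 0.7, 0.1)), 0.6)
  expect_error(range_statistic(c(0.5, Inf)), "finite")
})

test_that("phi classification assigns closed outer intervals", {
  cfg <- rope_config()
  expect_equal(classify_phi(0.10, cfg), "accumulation")
  expect_equal(classify_phi(0.90, cfg), "critical")
  expect_equal(classify_phi(0.50, cfg), "sensitive")
  # boundaries belong to the outer models
  expect_equal(classify_phi(c(0.15, 0.85), cfg),
               c("accumulation", "critical"))
  expect_error(classify_phi(1.2, cfg), "\\[0, 1\\]")
  expect_error(rope_config(a = 0.9, b = 0.1))
})

# simplex rows with a prescribed range t: ((1-t)/3, (1-t)/3, (1-t)/3 + t)
rows_with_phi <- function(t, times) {
  matrix(rep(c((1 - t) / 3, (1 - t) / 3, (1 - t) / 3 + t), times),
         ncol = 3, byrow = TRUE)
}

test_that("rope test counts draws per interval and decides", {
  even <- rbind(rows_with_phi(0.1, 1), rows_with_phi(0.5, 1),
                rows_with_phi(0.9, 1))
  r <- rope_test(even)
  expect_equal(c(r$p_accumulation, r$p_sensitive, r$p_critical),
               rep(1 / 3, 3))
  expect_equal(r$decision, "inconclusive")

  conc <- matrix(rep(1 / 3, 3 * 100), ncol = 3)
  expect_equal(rope_test(conc)$decision, "accumulation")
  expect_equal(rope_test(conc)$p_accumulation, 1)

  # posterior mass split as in a strongly sensitive dataset
  sens <- rbind(rows_with_phi(0.1, 4), rows_with_phi(0.5, 9973),
                rows_with_phi(0.9, 23))
  r2 <- rope_test(sens)
  expect_equal(r2$p_accumulation, 0.0004)
  expect_equal(r2$p_sensitive, 0.9973)
  expect_equal(r2$p_critical, 0.0023)
  expect_equal(r2$decision, "sensitive")

  expect_error(rope_test(matrix(c(0.5, 0.4, 0.5, 0.4), 2, 2)), "simplex")
})

test_that("the three ROPE probabilities are exhaustive", {
  set.seed(3)
  for (k in c(3, 5, 7)) {
    draws <- random_simplex_draws(400, k)
    r <- rope_test(draws)
    expect_identical(r$p_accumulation + r$p_sensitive + r$p_critical, 1)
  }
})

test_that("prior ROPE probabilities match the T = 2 closed form", {
  # for T = 2 under Dirichlet(1,1), phi = |2 w1 - 1| is uniform on [0, 1]
  p <- prior_rope_probabilities(2, rope_config(), alpha = 1, seed = 42)
  expect_equal(sum(p), 1)
  expect_equal(unname(p["accumulation"]), 0.15, tolerance = 0.03)
  expect_equal(unname(p["sensitive"]), 0.70, tolerance = 0.02)
  expect_equal(unname(p["critical"]), 0.15, tolerance = 0.03)
})

test_that("Dirichlet concentration biases the prior as expected", {
  cfg <- rope_config()
  p_conc <- prior_rope_probabilities(5, cfg, alpha = 200, seed = 1)
  expect_gt(p_conc[["accumulation"]], 0.99)
  p_sparse <- prior_rope_probabilities(5, cfg, alpha = 0.05, seed = 1)
  expect_gt(p_sparse[["critical"]], p_sparse[["accumulation"]])
  # with ROPE thresholds pushed to the ends, the sensitive model takes
  # essentially all uniform-prior mass
  wide <- rope_config(a = 1e-9, b = 1 - 1e-9)
  p_wide <- prior_rope_probabilities(4, wide, alpha = 1, seed = 1)
  expect_equal(p_wide[["sensitive"]], 1)
})

test_that("Bayes factors compare posterior to prior odds", {
  expect_equal(bayes_factor(0.5, 0.5)$bf, 1)
  expect_equal(bayes_factor(0.9, 0.5)$bf, 9)
  expect_equal(bayes_factor(0.9, 0.5)$log_bf, log(9))
  expect_true(bayes_factor(0.9, 0.1)$decisive)
  expect_false(bayes_factor(0.5, 0.5)$decisive)
  expect_warning(b <- bayes_factor(1, 0.5), "Inf")
  expect_identical(b$bf, Inf)
  expect_error(bayes_factor(0.5, 0), "undefined")
  expect_error(bayes_factor(0.5, 1), "undefined")
})

test_that("rope test attaches Bayes factors when priors are given", {
  draws <- matrix(rep(1 / 3, 300), ncol = 3)
  pri <- c(accumulation = 0.2, sensitive = 0.6, critical = 0.2)
  r <- suppressWarnings(rope_test(draws, prior_probs = pri))
  expect_named(r$bayes_factors, c("accumulation", "sensitive", "critical"))
  expect_identical(r$bayes_factors$accumulation$bf, Inf)
})

test_that("sign coherence counts strictly one-signed draws", {
  expect_equal(sign_coherence_probability(matrix(rep(1:3, 10), ncol = 3,
                                                 byrow = TRUE))$p_coherent, 1)
  r <- sign_coherence_probability(rbind(c(1, 1), c(-1, 1)))
  expect_equal(r$p_coherent, 0.5)
  expect_equal(r$p_positive, 0.5)
  expect_equal(r$p_negative, 0)
  # a zero component lands in neither orthant
  expect_equal(sign_coherence_probability(rbind(c(0, 1, 1)))$p_coherent, 0)
  neg <- sign_coherence_probability(rbind(c(-1, -2), c(-3, -4)))
  expect_equal(neg$p_negative, 1)
})
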