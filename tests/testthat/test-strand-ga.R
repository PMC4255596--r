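test_that("semiconservative replication flips bits per strand channel", {
  set.seed(1)
  parent <- sample(0:1, 50, replace = TRUE)
  r <- replicate_semiconservative(parent, mu_leading = 0, mu_lagging = 0.5)
  expect_identical(r$leading, as.integer(parent))
  r <- replicate_semiconservative(parent, mu_leading = 0.2, mu_lagging = 1)
  expect_identical(r$lagging, 1L - as.integer(parent))  # full complement
  expect_error(replicate_semiconservative(c(0, 2), 0, 0.1), "binary")
})

test_that("lagging-strand flip counts are binomial on average", {
  n <- 100
  mu <- 0.08
  reps <- 1e4
  set.seed(123)
  flips <- replicate(reps, {
    d <- replicate_semiconservative(rep(0L, n), 0, mu)$lagging
    sum(d)
  })
  se <- sqrt(n * mu * (1 - mu) / reps)
  expect_lt(abs(mean(flips) - n * mu), 3 * se)
})

test_that("an error-free run from the optimal founder stays solved", {
  inst <- generate_instance(12, seed = 5)
  best_genome <- brute_force_argmax(inst)
  run <- run_ga(inst, pop_size = 20, generations = 30, mu_leading = 0,
                mu_lagging = 0, founder = best_genome, seed = 1)
  expect_true(run$solved)
  expect_equal(run$generation_solved, 0L)
  expect_equal(run$trajectory$best, rep(run$dp_optimum, 31))
})

test_that("with a faithful leading strand the best fitness never decreases", {
  inst <- generate_instance(20, seed = 2)
  for (seed in 1:5) {
    run <- run_ga(inst, pop_size = 60, generations = 150, mu_leading = 0,
                  mu_lagging = 0.1, seed = seed)
    expect_true(all(diff(run$trajectory$best) >= 0))
    expect_lte(max(run$trajectory$best), run$dp_optimum)
  }
})

test_that("runs are bit-reproducible given instance and run seeds", {
  inst <- generate_instance(15, seed = 9)
  a <- run_ga(inst, pop_size = 40, generations = 50, mu_leading = 0.02,
              mu_lagging = 0.06, seed = 4)
  b <- run_ga(inst, pop_size = 40, generations = 50, mu_leading = 0.02,
              mu_lagging = 0.06, seed = 4)
  expect_identical(a$trajectory, b$trajectory)
  c <- run_ga(inst, pop_size = 40, generations = 50, mu_leading = 0.02,
              mu_lagging = 0.06, seed = 5)
  expect_false(identical(a$trajectory, c$trajectory))
})

test_that("mode is derived from the two strand rates", {
  inst <- generate_instance(10, seed = 1)
  expect_equal(run_ga(inst, 10, 1, 0.02, 0.02, seed = 1)$params$mode,
               "parity")
  expect_equal(run_ga(inst, 10, 1, 0, 0.08, seed = 1)$params$mode,
               "disparity")
  expect_equal(run_ga(inst, 10, 1, 0, 0.08, seed = 1)$params$total_rate,
               0.04)
})

test_that("a permanently infeasible population is declared extinct", {
  inst <- generate_instance(10, seed = 6)  # capacity is half total weight
  run <- run_ga(inst, pop_size = 10, generations = 100, mu_leading = 0,
                mu_lagging = 0, founder = rep(1L, 10), seed = 1)
  expect_true(run$extinct)
  expect_false(run$solved)
  # generations 0..9 are ten consecutive all-infeasible generations
  expect_equal(max(run$trajectory$generation), 9)
  expect_true(all(run$trajectory$feasible_fraction == 0))
})

test_that("degenerate parameters are rejected", {
  inst <- generate_instance(10, seed = 1)
  expect_error(run_ga(inst, pop_size = 1, generations = 10, 0, 0.1,
                      seed = 1), "pop_size")
  expect_error(run_ga(inst, pop_size = 11, generations = 10, 0, 0.1,
                      seed = 1), "even")
  expect_error(run_ga(inst, pop_size = 10, generations = 10, 0, 0.6,
                      seed = 1), "mu_lagging")
})

test_that("disparity outperforms parity at a high matched mutation load", {
  # average per-bit rate 0.08: parity copies both strands at 0.08, disparity
  # keeps the leading strand error-free and doubles the lagging rate
  wins <- 0L
  n_seeds <- 10L
  for (seed in seq_len(n_seeds)) {
    inst <- generate_instance(20, seed = seed)
    dis <- run_ga(inst, pop_size = 100, generations = 150, mu_leading = 0,
                  mu_lagging = 0.16, seed = seed, stop_when_solved = TRUE)
    par <- run_ga(inst, pop_size = 100, generations = 150,
                  mu_leading = 0.08, mu_lagging = 0.08, seed = seed)
    if (dis$final_best >= par$final_best) wins <- wins + 1L
  }
  # one-sided sign test against even odds
  expect_lt(binom.test(wins, n_seeds, alternative = "greater")$p.value, 0.05)
})
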