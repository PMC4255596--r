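test_that("instance generation is deterministic and respects its ranges", {
  a <- generate_instance(20, seed = 1)
  b <- generate_instance(20, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, generate_instance(20, seed = 2)))
  expect_true(all(a$weights >= 1 & a$weights <= 100))
  expect_equal(a$capacity, round(0.5 * sum(a$weights)))
  expect_gt(dp_optimum(a), 0)

  full <- generate_instance(10, seed = 3, capacity_fraction = 1)
  expect_equal(knapsack_fitness(rep(1L, 10), full), sum(full$values))

  expect_error(generate_instance(5, seed = 1, weight_range = c(10, 2)),
               "weight_range")
  expect_error(generate_instance(5, seed = 1, capacity_fraction = 0),
               "capacity_fraction")
})

test_that("instance generation leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_instance(50, seed = 7))
  expect_identical(runif(1), before)
})

test_that("knapsack fitness scores values under capacity and zero above", {
  inst <- knapsack_instance(c(2, 3, 4), c(3, 4, 5), capacity = 5)
  expect_equal(knapsack_fitness(c(0, 0, 0), inst), 0L)
  expect_equal(knapsack_fitness(c(1, 1, 0), inst), 7L)
  expect_equal(knapsack_fitness(c(1, 1, 1), inst), 0L)  # weight 9 > 5
  expect_error(knapsack_fitness(c(1, 0), inst), "length")
  expect_error(knapsack_fitness(c(1, 2, 0), inst), "binary")
})

test_that("dynamic program reproduces exhaustive enumeration", {
  inst <- knapsack_instance(c(2, 3, 4), c(3, 4, 5), capacity = 5)
  expect_equal(dp_optimum(inst), 7L)
  expect_equal(dp_optimum(inst), brute_force_optimum(inst))

  zero_cap <- knapsack_instance(c(2, 3), c(5, 5), capacity = 1)
  expect_equal(dp_optimum(zero_cap), 0L)

  for (seed in 1:10) {
    n <- 3 + (seed %% 13)
    inst <- generate_instance(n, seed = seed)
    expect_equal(dp_optimum(inst), brute_force_optimum(inst))
  }
  big <- generate_instance(2000, seed = 1, weight_range = c(50, 100))
  expect_error(dp_optimum(big), "budget")
})

test_that("fitness never exceeds the DP optimum", {
  inst <- generate_instance(15, seed = 4)
  opt <- dp_optimum(inst)
  set.seed(11)
  for (i in 1:50) {
    g <- sample(0:1, 15, replace = TRUE)
    expect_lte(knapsack_fitness(g, inst), opt)
  }
})
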