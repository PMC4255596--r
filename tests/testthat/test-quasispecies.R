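test_that("class-transition matrix matches closed forms and is stochastic", {
  expect_equal(class_transition_matrix(2, 0), diag(3))
  expect_equal(class_transition_matrix(1, 0.1),
               matrix(c(0.9, 0.1, 0.1, 0.9), 2))
  M <- class_transition_matrix(20, 0.05)
  expect_equal(M[1, 1], 0.95^20)
  for (mu in c(0, 0.01, 0.3)) {
    for (p in c(0, 0.4)) {
      M <- class_transition_matrix(30, mu, p)
      expect_equal(colSums(M), rep(1, 31))
      expect_true(all(M >= 0))
    }
  }
  # mixture kernel is exactly p*I + (1-p)*B
  B <- class_transition_matrix(15, 0.1, p = 0)
  expect_equal(class_transition_matrix(15, 0.1, p = 0.3),
               0.3 * diag(16) + 0.7 * B)
  expect_error(class_transition_matrix(10, 1), "mu")
  expect_error(class_transition_matrix(10, -0.1), "mu")
})

test_that("one mutation-selection step preserves normalization and fixed points", {
  L <- 10
  M0 <- class_transition_matrix(L, 0)
  x <- c(1, rep(0, L))
  expect_equal(qs_iterate(x, sigma = 2, M0), x)  # error-free: master stays

  x <- rep(1 / (L + 1), L + 1)
  for (i in 1:5) {
    y <- qs_iterate(x, sigma = 2, M0)
    expect_gt(y[1], x[1])  # selection alone grows the master class
    x <- y
  }
  M <- class_transition_matrix(L, 0.07, 0.2)
  set.seed(7)
  for (i in 1:10) {
    x <- runif(L + 1)
    x <- x / sum(x)
    expect_equal(sum(qs_iterate(x, sigma = 3, M)), 1, tolerance = 1e-12)
  }
  expect_error(qs_iterate(c(0.7, 0.7), 2, class_transition_matrix(1, 0.1)),
               "normalized")
})

test_that("stationary solution matches the no-back-mutation closed form", {
  expect_equal(solve_stationary(sigma = 2, L = 20, mu = 0)$master, 1)
  st <- solve_stationary(sigma = 2, L = 20, mu = 0.005)
  expect_equal(st$master, oracle_master_freq(2, 20, 0.005), tolerance = 0.02)
  # mixture lower bound: Q_eff = p + (1-p)(1-mu)^L keeps the master alive
  st <- solve_stationary(sigma = 4, L = 50, mu = 0.2, p = 0.5)
  expect_gte(st$master, (4 * 0.5 - 1) / (4 - 1) - 0.02)
  # the returned state is a fixed point of the iteration map
  M <- class_transition_matrix(50, 0.2, 0.5)
  expect_equal(qs_iterate(st$x, 4, M), st$x, tolerance = 1e-10)
})

test_that("eigen and power-iteration solvers agree", {
  for (mu in c(0.002, 0.02, 0.1)) {
    a <- solve_stationary(sigma = 3, L = 40, mu = mu, method = "eigen")
    b <- solve_stationary(sigma = 3, L = 40, mu = mu, method = "power",
                          tol = 1e-13)
    expect_equal(a$x, b$x, tolerance = 1e-8)
  }
  expect_error(solve_stationary(sigma = 3, L = 40, mu = 0.01,
                                method = "power", max_iter = 3),
               "converge")
})

test_that("master frequency is monotone in mu and in p", {
  mus <- c(0.001, 0.005, 0.01, 0.02, 0.05)
  m <- vapply(mus, function(mu) solve_stationary(2, 60, mu)$master, 0)
  # non-increasing everywhere (beyond the threshold it flattens out near 0)
  expect_true(all(diff(m) <= 1e-12))
  expect_true(all(diff(m[mus <= 0.01]) < 0))
  ps <- c(0, 0.2, 0.4, 0.6)
  m <- vapply(ps, function(p) solve_stationary(2, 60, 0.02, p)$master, 0)
  expect_true(all(diff(m) > 0))
})

test_that("bisection locates the error threshold where sigma (1-mu)^L = 1", {
  th <- find_error_threshold(sigma = 2, L = 50)
  expect_true(th$exists)
  expect_equal(th$mu_critical, 1 - 2^(-1 / 50), tolerance = 0.1)
  # threshold bracketing violated -> informative error
  expect_error(find_error_threshold(sigma = 2, L = 50,
                                    mu_range = c(0.2, 0.5)),
               "does not bracket")
  expect_error(find_error_threshold(sigma = 2, L = 50,
                                    mu_range = c(-0.1, 0.6)), "mu_range")
})

test_that("an error-free polymerase fraction p > 1/sigma abolishes the threshold", {
  th <- find_error_threshold(sigma = 10, L = 100, p = 0.2)
  expect_false(th$exists)
  expect_true(is.na(th$mu_critical))
})

test_that("phase table is consistent with bisection and monotone in p", {
  tab <- threshold_phase_table(sigma_grid = 2, p_grid = c(0, 0.4, 0.6),
                               L = 50)
  ref <- find_error_threshold(sigma = 2, L = 50, p = 0)
  expect_equal(tab$mu_critical[tab$p == 0], ref$mu_critical)
  expect_true(all(tab$exists[tab$p %in% c(0, 0.4)]))
  expect_false(tab$exists[tab$p == 0.6])  # sigma * p > 1: no threshold
  existing <- tab$mu_critical[tab$exists]
  expect_true(all(diff(existing) >= 0))
})
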