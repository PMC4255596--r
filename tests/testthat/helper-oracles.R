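# Independent oracles used across the suite.

# Exhaustive 0/1-knapsack optimum by subset enumeration (n <= 20 or so).
brute_force_optimum <- function(instance) {
  n <- instance$n_items
  subsets <- as.matrix(expand.grid(rep(list(0:1), n)))
  w <- subsets %*% instance$weights
  v <- subsets %*% instance$values
  max(v[w <= instance$capacity])
}

# The genome attaining the exhaustive optimum (first one in enumeration order).
brute_force_argmax <- function(instance) {
  n <- instance$n_items
  subsets <- as.matrix(expand.grid(rep(list(0:1), n)))
  w <- subsets %*% instance$weights
  v <- subsets %*% instance$values
  v[w > instance$capacity] <- -1
  as.integer(subsets[which.max(v), ])
}

# Mutation-count census at generation g by enumerating all 2^g root-to-leaf
# strand-choice paths (0 = leading, 1 = lagging).
enumerate_census <- function(mode, d, g) {
  if (g == 0L) return(c(`0` = 1L))
  paths <- as.matrix(expand.grid(rep(list(0:1), g)))
  counts <- if (mode == "disparity") {
    rowSums(paths) * d
  } else {
    rep((d %/% 2L) * g, nrow(paths))
  }
  table(counts)
}

# No-back-mutation stationary master frequency (independent closed form,
# recomputed here rather than calling the package's helper).
oracle_master_freq <- function(sigma, L, mu, p = 0) {
  q <- p + (1 - p) * (1 - mu)^L
  max(0, (sigma * q - 1) / (sigma - 1))
}
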