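# 0/1 knapsack instances and the exact dynamic-programming optimum used as
# the GA's ground truth.

#' Construct a 0/1 knapsack instance from explicit items
#'
#' @param weights,values positive integer vectors of equal length.
#' @param capacity positive integer weight limit.
#' @return object of class `knapsack_instance`.
#' @examples
#' knapsack_instance(c(2, 3, 4), c(3, 4, 5), capacity = 5)
#' @seealso [generate_instance()] for random instances.
#' @export
knapsack_instance <- function(weights, values, capacity) {
  if (length(weights) != length(values) || length(weights) == 0L) {
    stop("`weights` and `values` must be nonempty vectors of equal length",
         call. = FALSE)
  }
  if (any(weights < 1) || any(values < 1) ||
      any(weights != as.integer(weights)) ||
      any(values != as.integer(values))) {
    stop("`weights` and `values` must be positive integers", call. = FALSE)
  }
  stop_if_not_scalar_number(capacity, "capacity", min = 1, integer = TRUE)
  structure(list(n_items = length(weights), weights = as.integer(weights),
                 values = as.integer(values),
                 capacity = as.integer(capacity), seed = NA_integer_,
                 weight_range = range(as.integer(weights)),
                 value_range = range(as.integer(values)),
                 capacity_fraction = capacity / sum(weights)),
            class = "knapsack_instance")
}

#' Generate a random 0/1 knapsack instance
#'
#' Draws item weights and values uniformly from integer ranges and sets the
#' capacity to a fraction of the total weight, so roughly that fraction of
#' the items can be packed.  Genomes are binary inclusion vectors: each
#' object may be taken at most once.
#'
#' @param n_items number of objects (>= 1).
#' @param seed RNG seed for the instance; the caller's random stream is left
#'   untouched.
#' @param weight_range,value_range integer ranges `c(min, max)` with
#'   `1 <= min <= max`.
#' @param capacity_fraction capacity as a fraction of total weight, in
#'   `(0, 1]`.
#' @return object of class `knapsack_instance`: list with `n_items`,
#'   `weights`, `values`, `capacity` and the generating parameters.
#' @examples
#' inst <- generate_instance(20, seed = 1)
#' dp_optimum(inst)
#' @export
generate_instance <- function(n_items, seed, weight_range = c(1L, 100L),
                              value_range = c(1L, 100L),
                              capacity_fraction = 0.5) {
  stop_if_not_scalar_number(n_items, "n_items", min = 1, integer = TRUE)
  stop_if_not_scalar_number(seed, "seed", integer = TRUE)
  stop_if_not_scalar_number(capacity_fraction, "capacity_fraction",
                            min = 0, max = 1, max_open = FALSE)
  if (capacity_fraction <= 0) {
    stop("`capacity_fraction` must be in (0, 1]", call. = FALSE)
  }
  for (nm in c("weight_range", "value_range")) {
    r <- get(nm)
    if (length(r) != 2L || any(r < 1) || r[1] > r[2] ||
        any(r != as.integer(r))) {
      stop(sprintf("`%s` must be an integer range c(min, max) with 1 <= min <= max",
                   nm), call. = FALSE)
    }
  }
  n <- as.integer(n_items)
  draw <- function(r) {
    if (r[1] == r[2]) rep(as.integer(r[1]), n)
    else sample(seq.int(r[1], r[2]), n, replace = TRUE)
  }
  wv <- local_seed(seed, list(w = draw(weight_range), v = draw(value_range)))
  structure(list(n_items = n, weights = as.integer(wv$w),
                 values = as.integer(wv$v),
                 capacity = as.integer(round(capacity_fraction * sum(wv$w))),
                 seed = as.integer(seed),
                 weight_range = as.integer(weight_range),
                 value_range = as.integer(value_range),
                 capacity_fraction = capacity_fraction),
            class = "knapsack_instance")
}

#' @export
print.knapsack_instance <- function(x, ...) {
  cat(sprintf("0/1 knapsack instance: %d items, capacity %d (%.0f%% of total weight %d), seed %d\n",
              x$n_items, x$capacity, 100 * x$capacity_fraction,
              sum(x$weights), x$seed))
  invisible(x)
}

#' Fitness of a genome on a knapsack instance
#'
#' The total value of the selected objects if their total weight fits the
#' capacity, and 0 otherwise.  The hard zero for overweight genomes makes
#' population extinction (no feasible genome left) well-defined.
#'
#' @param bits binary inclusion vector of length `n_items`.
#' @param instance a `knapsack_instance`.
#' @return integer fitness.
#' @export
knapsack_fitness <- function(bits, instance) {
  stopifnot(inherits(instance, "knapsack_instance"))
  if (length(bits) != instance$n_items) {
    stop(sprintf("genome length %d does not match the instance's %d items",
                 length(bits), instance$n_items), call. = FALSE)
  }
  if (!all(bits %in% c(0, 1))) {
    stop("`bits` must be a binary 0/1 vector", call. = FALSE)
  }
  w <- sum(instance$weights[bits == 1])
  if (w > instance$capacity) 0L else sum(instance$values[bits == 1])
}

# Vectorized fitness for a population matrix (rows = genomes).
fitness_matrix <- function(pop, instance) {
  w <- as.vector(pop %*% instance$weights)
  v <- as.vector(pop %*% instance$values)
  ifelse(w > instance$capacity, 0L, v)
}

#' Exact knapsack optimum by dynamic programming
#'
#' Standard 0/1-knapsack value table over capacities `0..capacity`; exact,
#' used as the ground truth the genetic algorithm is scored against.
#'
#' @param instance a `knapsack_instance`.
#' @param max_cells guard on the DP table size `n_items * (capacity + 1)`.
#' @return the exact optimal total value (integer).
#' @examples
#' inst <- generate_instance(15, seed = 7)
#' dp_optimum(inst)
#' @export
dp_optimum <- function(instance, max_cells = 1e7) {
  stopifnot(inherits(instance, "knapsack_instance"))
  cells <- as.numeric(instance$n_items) * (instance$capacity + 1)
  if (cells > max_cells) {
    stop(sprintf("DP table would need %.3g cells, over the budget of %.3g; raise `max_cells` explicitly if you mean it",
                 cells, max_cells), call. = FALSE)
  }
  best <- numeric(instance$capacity + 1L)
  for (i in seq_len(instance$n_items)) {
    w <- instance$weights[i]
    v <- instance$values[i]
    if (w > instance$capacity) next
    idx <- (w + 1L):(instance$capacity + 1L)
    best[idx] <- pmax(best[idx], best[idx - w] + v)
  }
  as.integer(max(best))
}
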