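# Genetic algorithm with semiconservative, strand-asymmetric replication.
#
# Every surviving genome produces two daughters per generation: a
# leading-strand copy mutated at rate mu_leading per bit and a lagging-strand
# copy mutated at rate mu_lagging.  Parity means equal rates; disparity means
# a low-fidelity lagging channel and a high-fidelity (here often error-free)
# leading channel.  Selection is truncation on knapsack fitness.

#' Replicate one genome through the two strand channels
#'
#' Each bit of the leading-strand daughter flips independently with
#' probability `mu_leading`, each bit of the lagging-strand daughter with
#' probability `mu_lagging`.  Uses the caller's RNG stream (seed before
#' calling for reproducibility).
#'
#' @param bits binary parent genome.
#' @param mu_leading,mu_lagging per-bit flip probabilities in `[0, 1]`.
#' @return list with binary vectors `leading` and `lagging`.
#' @examples
#' set.seed(1)
#' replicate_semiconservative(rep(0L, 10), mu_leading = 0, mu_lagging = 0.2)
#' @export
replicate_semiconservative <- function(bits, mu_leading, mu_lagging) {
  if (!all(bits %in% c(0, 1))) {
    stop("`bits` must be a binary 0/1 vector", call. = FALSE)
  }
  stop_if_not_scalar_number(mu_leading, "mu_leading", min = 0, max = 1)
  stop_if_not_scalar_number(mu_lagging, "mu_lagging", min = 0, max = 1)
  n <- length(bits)
  flip <- function(mu) {
    if (mu == 0) return(as.integer(bits))
    as.integer(xor(bits == 1L, stats::runif(n) < mu))
  }
  list(leading = flip(mu_leading), lagging = flip(mu_lagging))
}

#' Run the strand-asymmetric genetic algorithm on a knapsack instance
#'
#' Generational loop: every genome in the population of size `pop_size`
#' produces a leading and a lagging daughter; truncation selection keeps the
#' top `keep_fraction` of the `2 * pop_size` daughters (ties broken stably by
#' parent index, then leading before lagging) and the population is refilled
#' to `pop_size` by cycling the survivors.  With `mu_leading = 0` the
#' faithful leading daughter of the current best genome always survives
#' truncation, so the best fitness is monotone non-decreasing -- diversity
#' with a guarantee of principal.  The run is bit-reproducible given the
#' instance seed and `seed`.
#'
#' The replication mode is derived from the rates: `parity` when
#' `mu_leading == mu_lagging`, `disparity` when `mu_leading < mu_lagging`,
#' `leading_biased` otherwise.  The scalar "total mutation rate" reported in
#' the run metadata is the per-bit rate averaged over the two daughters,
#' `(mu_leading + mu_lagging) / 2`.
#'
#' @param instance a [generate_instance()] knapsack instance.
#' @param pop_size population size `N` (even, >= 2).
#' @param generations number of replication rounds `G`.
#' @param mu_leading,mu_lagging per-bit flip probabilities in `[0, 0.5]`.
#' @param keep_fraction fraction of the `2N` daughters kept by truncation
#'   (default 0.5, i.e. exactly `N` survivors).
#' @param seed RNG seed for the run; the caller's stream is left untouched.
#' @param founder starting population: `NULL` (default) for all-zero genomes
#'   (the empty knapsack -- feasible and deterministic), a single binary
#'   vector recycled to `N` rows, or an `N x n_items` binary matrix.
#' @param extinct_after the run is declared extinct and stopped when the
#'   feasible fraction has been 0 for this many consecutive generations.
#' @param stop_when_solved stop as soon as the best fitness reaches the DP
#'   optimum (the trajectory then ends at `generation_solved`).
#' @return object of class `ga_run`: list with `trajectory` (data frame
#'   `generation`, `best`, `mean`, `feasible_fraction`), `solved`, `extinct`,
#'   `generation_solved`, `dp_optimum`, `final_best`, `params`, `instance`.
#' @examples
#' inst <- generate_instance(20, seed = 1)
#' run <- run_ga(inst, pop_size = 100, generations = 100,
#'               mu_leading = 0, mu_lagging = 0.08, seed = 1)
#' run
#' @export
run_ga <- function(instance, pop_size = 200L, generations = 500L,
                   mu_leading, mu_lagging, keep_fraction = 0.5, seed = 1L,
                   founder = NULL, extinct_after = 10L,
                   stop_when_solved = FALSE) {
  stopifnot(inherits(instance, "knapsack_instance"))
  stop_if_not_scalar_number(pop_size, "pop_size", min = 2, integer = TRUE)
  if (pop_size %% 2L != 0L) stop("`pop_size` must be even", call. = FALSE)
  stop_if_not_scalar_number(generations, "generations", min = 0,
                            integer = TRUE)
  stop_if_not_scalar_number(mu_leading, "mu_leading", min = 0, max = 0.5)
  stop_if_not_scalar_number(mu_lagging, "mu_lagging", min = 0, max = 0.5)
  stop_if_not_scalar_number(keep_fraction, "keep_fraction", min = 0, max = 1)
  if (keep_fraction <= 0) stop("`keep_fraction` must be positive",
                               call. = FALSE)
  stop_if_not_scalar_number(seed, "seed", integer = TRUE)
  stop_if_not_scalar_number(extinct_after, "extinct_after", min = 1,
                            integer = TRUE)

  N <- as.integer(pop_size)
  G <- as.integer(generations)
  n <- instance$n_items
  opt <- dp_optimum(instance)

  pop <- if (is.null(founder)) {
    matrix(0L, N, n)
  } else if (is.matrix(founder)) {
    if (!all(dim(founder) == c(N, n))) {
      stop("`founder` matrix must be pop_size x n_items", call. = FALSE)
    }
    storage.mode(founder) <- "integer"
    founder
  } else {
    if (length(founder) != n || !all(founder %in% c(0, 1))) {
      stop("`founder` vector must be a binary genome of length n_items",
           call. = FALSE)
    }
    matrix(as.integer(founder), N, n, byrow = TRUE)
  }

  mode <- if (mu_leading == mu_lagging) "parity" else
    if (mu_leading < mu_lagging) "disparity" else "leading_biased"
  keep_n <- max(1L, as.integer(round(keep_fraction * 2L * N)))

  local_seed(seed, {
    fit <- fitness_matrix(pop, instance)
    feas <- mean(as.vector(pop %*% instance$weights) <= instance$capacity)
    traj_best <- integer(G + 1L)
    traj_mean <- numeric(G + 1L)
    traj_feas <- numeric(G + 1L)
    traj_best[1L] <- max(fit)
    traj_mean[1L] <- mean(fit)
    traj_feas[1L] <- feas
    gen_solved <- if (max(fit) == opt) 0L else NA_integer_
    extinct <- FALSE
    zero_streak <- if (feas == 0) 1L else 0L
    last_gen <- 0L

    for (gg in seq_len(G)) {
      if (!is.na(gen_solved) && stop_when_solved) break
      flips_lead <- if (mu_leading > 0) {
        matrix(stats::runif(N * n) < mu_leading, N, n)
      } else NULL
      flips_lag <- if (mu_lagging > 0) {
        matrix(stats::runif(N * n) < mu_lagging, N, n)
      } else NULL
      lead <- if (is.null(flips_lead)) pop else (pop + flips_lead) %% 2L
      lag <- if (is.null(flips_lag)) pop else (pop + flips_lag) %% 2L
      daughters <- rbind(lead, lag)
      parent_idx <- rep.int(seq_len(N), 2L)
      channel <- rep(c(0L, 1L), each = N)  # leading before lagging
      dfit <- fitness_matrix(daughters, instance)
      ord <- order(-dfit, parent_idx, channel)
      keep <- ord[seq_len(min(keep_n, 2L * N))]
      keep <- keep[rep_len(seq_along(keep), N)]
      pop <- daughters[keep, , drop = FALSE]
      fit <- dfit[keep]
      feas <- mean(as.vector(pop %*% instance$weights) <= instance$capacity)
      traj_best[gg + 1L] <- max(fit)
      traj_mean[gg + 1L] <- mean(fit)
      traj_feas[gg + 1L] <- feas
      last_gen <- gg
      if (is.na(gen_solved) && max(fit) == opt) gen_solved <- gg
      zero_streak <- if (feas == 0) zero_streak + 1L else 0L
      if (zero_streak >= extinct_after) {
        extinct <- TRUE
        break
      }
    }

    rows <- seq_len(last_gen + 1L)
    trajectory <- data.frame(generation = rows - 1L,
                             best = traj_best[rows],
                             mean = traj_mean[rows],
                             feasible_fraction = traj_feas[rows])
    structure(
      list(trajectory = trajectory,
           solved = !is.na(gen_solved),
           extinct = extinct,
           generation_solved = gen_solved,
           dp_optimum = opt,
           final_best = traj_best[last_gen + 1L],
           params = list(pop_size = N, generations = G,
                         mu_leading = mu_leading, mu_lagging = mu_lagging,
                         total_rate = (mu_leading + mu_lagging) / 2,
                         mode = mode, keep_fraction = keep_fraction,
                         seed = as.integer(seed),
                         extinct_after = as.integer(extinct_after),
                         instance_seed = instance$seed),
           instance = instance),
      class = "ga_run")
  })
}

#' @export
print.ga_run <- function(x, ...) {
  p <- x$params
  cat(sprintf("Strand-asymmetric GA run: %s mode (mu_leading = %.4g, mu_lagging = %.4g, total rate %.4g)\n",
              p$mode, p$mu_leading, p$mu_lagging, p$total_rate))
  cat(sprintf("  N = %d, %d generation(s) run, instance seed %d, run seed %d\n",
              p$pop_size, max(x$trajectory$generation), p$instance_seed,
              p$seed))
  cat(sprintf("  DP optimum %d; final best %d (%s)%s\n", x$dp_optimum,
              x$final_best,
              if (x$solved) sprintf("solved at generation %d",
                                    x$generation_solved) else "not solved",
              if (x$extinct) "; population went extinct" else ""))
  invisible(x)
}

#' @export
plot.ga_run <- function(x, ...) {
  tr <- x$trajectory
  plot(tr$generation, tr$best, type = "l", lwd = 2,
       xlab = "generation", ylab = "knapsack fitness",
       ylim = c(0, max(x$dp_optimum, tr$best)), ...)
  graphics::lines(tr$generation, tr$mean, lty = 2)
  graphics::abline(h = x$dp_optimum, col = "grey50", lty = 3)
  graphics::legend("bottomright", c("best", "mean", "DP optimum"),
                   lty = c(1, 2, 3), lwd = c(2, 1, 1),
                   col = c("black", "black", "grey50"), bty = "n")
  invisible(x)
}
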