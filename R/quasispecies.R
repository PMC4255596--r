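# Eigen quasi-species mutation-selection dynamics on Hamming error classes.
#
# A binary genome of length L on a single-peak landscape (master fitness
# sigma > 1, everything else 1) is permutation-invariant, so the 2^L sequence
# space collapses to L+1 Hamming classes measured from the master.  Copying
# flips each base independently with probability mu; with probability p a
# replication event instead uses an error-free polymerase and copies exactly.
# The mixture kernel is M = p*I + (1-p)*B(mu).

#' Hamming error-class transition matrix
#'
#' Entry `M[j+1, i+1]` is the probability that a parent in class `i` (Hamming
#' distance `i` from the master) produces an offspring in class `j`.  For the
#' uniform-error component this convolves back-mutations among the `i`
#' incorrect positions, `K ~ Binomial(i, mu)`, with fresh errors among the
#' `L - i` correct positions, `Mnew ~ Binomial(L - i, mu)`, so the offspring
#' class is `i - K + Mnew`.  A fraction `p` of replication events are
#' error-free copies, giving `M = p * I + (1 - p) * B(mu)`.
#'
#' @param L genome length in bases (1..1000).
#' @param mu per-base copy error probability, in `[0, 1)`.
#' @param p fraction of replication events carried out by the error-free
#'   polymerase, in `[0, 1]`; `p = 0` recovers the classic uniform-error
#'   quasi-species model.
#' @return `(L+1) x (L+1)` column-stochastic matrix.
#' @examples
#' class_transition_matrix(1, 0.1)      # 2x2 single-site flip matrix
#' class_transition_matrix(20, 0.05)[1, 1]  # faithful copy prob (1-mu)^L
#' @export
class_transition_matrix <- function(L, mu, p = 0) {
  stop_if_not_scalar_number(L, "L", min = 1, max = 1000, integer = TRUE)
  stop_if_not_scalar_number(mu, "mu", min = 0, max = 1, max_open = TRUE)
  stop_if_not_scalar_number(p, "p", min = 0, max = 1)
  L <- as.integer(L)
  B <- matrix(0, L + 1L, L + 1L)
  for (i in 0:L) {
    pk <- stats::dbinom(0:i, i, mu)
    pm <- stats::dbinom(0:(L - i), L - i, mu)
    col <- numeric(L + 1L)
    for (k in 0:i) {
      idx <- (i - k) + 0:(L - i) + 1L
      col[idx] <- col[idx] + pk[k + 1L] * pm
    }
    B[, i + 1L] <- col
  }
  if (p > 0) p * diag(L + 1L) + (1 - p) * B else B
}

single_peak_fitness <- function(sigma, L) c(sigma, rep(1, L))

#' One discrete generation of mutation--selection dynamics
#'
#' Applies selection (class fitnesses `sigma, 1, 1, ...`) then mutation (the
#' class-transition kernel) to a normalized frequency vector and renormalizes:
#' `x' = M (w * x) / sum(M (w * x))`.  Fixed points coincide with the
#' stationary quasi-species distribution of the continuous-time model.
#'
#' @param x frequency vector over classes `0..L`, summing to 1.
#' @param sigma master-class superiority (> 1).
#' @param M transition matrix from [class_transition_matrix()].
#' @return the next normalized frequency vector.
#' @export
qs_iterate <- function(x, sigma, M) {
  stopifnot(is.numeric(x), length(x) == nrow(M))
  if (any(x < -1e-12) || abs(sum(x) - 1) > 1e-9) {
    stop("`x` must be a normalized frequency vector", call. = FALSE)
  }
  stop_if_not_scalar_number(sigma, "sigma", min = 1, max_open = FALSE)
  w <- single_peak_fitness(sigma, nrow(M) - 1L)
  y <- as.vector(M %*% (w * x))
  s <- sum(y)
  if (s <= 0) stop("total fitness flux is zero; cannot renormalize",
                   call. = FALSE)
  y / s
}

#' Stationary quasi-species distribution on a single-peak landscape
#'
#' Solves for the mutation--selection equilibrium over Hamming error classes:
#' the dominant eigenvector of `A = M %*% diag(w)` with
#' `w = (sigma, 1, ..., 1)`, which is the unique fixed point of
#' [qs_iterate()] reachable from positive starting states
#' (Perron--Frobenius).  The default solver takes the dominant eigenpair
#' directly and polishes it by iteration until the sup-norm fixed-point
#' residual is below `tol`; `method = "power"` runs plain power iteration
#' from the uniform state instead, which is used as an independent numerical
#' cross-check.
#'
#' @inheritParams class_transition_matrix
#' @param sigma master-class superiority (> 1).
#' @param tol sup-norm fixed-point tolerance.
#' @param max_iter iteration budget; exceeded -> error reporting the residual.
#' @param method `"eigen"` (default) or `"power"`.
#' @return object of class `qs_state`: list with `x` (frequencies over
#'   classes `0..L`), `master` (`x[1]`, the master-class frequency),
#'   `residual`, `iterations`, and the parameters.
#' @examples
#' st <- solve_stationary(sigma = 2, L = 20, mu = 0.005)
#' st$master   # close to (sigma * (1 - mu)^L - 1) / (sigma - 1)
#' @seealso [master_frequency_closed_form()] for the no-back-mutation
#'   approximation.
#' @export
solve_stationary <- function(sigma, L, mu, p = 0, tol = 1e-12,
                             max_iter = 1e6, method = c("eigen", "power")) {
  method <- match.arg(method)
  stop_if_not_scalar_number(sigma, "sigma", min = 1, max_open = FALSE)
  if (sigma <= 1) stop("`sigma` must exceed 1 (master superiority)",
                       call. = FALSE)
  M <- class_transition_matrix(L, mu, p)
  n <- nrow(M)
  w <- single_peak_fitness(sigma, n - 1L)
  A <- sweep(M, 2L, w, `*`)

  iters <- 0L
  if (method == "eigen") {
    ev <- eigen(A)
    k <- which.max(Re(ev$values))
    v <- Re(ev$vectors[, k])
    if (sum(v) < 0) v <- -v
    v[v < 0] <- 0
    x <- v / sum(v)
  } else {
    x <- rep(1 / n, n)
  }
  repeat {
    y <- as.vector(A %*% x)
    y <- y / sum(y)
    res <- max(abs(y - x))
    x <- y
    iters <- iters + 1L
    if (res < tol) break
    if (iters >= max_iter) {
      stop(sprintf("stationary solve did not converge in %d iterations (sup-norm residual %.3e > tol %.1e)",
                   iters, res, tol), call. = FALSE)
    }
  }
  structure(list(x = x, master = x[1L], residual = res, iterations = iters,
                 sigma = sigma, L = as.integer(L), mu = mu, p = p,
                 method = method),
            class = "qs_state")
}

#' @export
print.qs_state <- function(x, ...) {
  cat(sprintf("Quasi-species stationary state (sigma = %.4g, L = %d, mu = %.4g, p = %.3g)\n",
              x$sigma, x$L, x$mu, x$p))
  cat(sprintf("  master-class frequency: %.6f  (residual %.2e, %d polish iteration(s))\n",
              x$master, x$residual, x$iterations))
  invisible(x)
}

#' No-back-mutation closed form for the master-class frequency
#'
#' Ignoring mutation back into the master class, the stationary master
#' frequency is `max(0, (sigma * Q - 1) / (sigma - 1))` with effective
#' faithful-copy probability `Q = p + (1 - p) * (1 - mu)^L`.  For `L >= 50`
#' this approximates the exact stationary solution to within about 0.02
#' absolute; it also shows directly that for `p > 1/sigma` the master
#' frequency stays positive for every `mu`, i.e. the error threshold
#' disappears.
#'
#' @inheritParams solve_stationary
#' @return master-class frequency approximation (vectorized over `mu`).
#' @export
master_frequency_closed_form <- function(sigma, L, mu, p = 0) {
  q_eff <- p + (1 - p) * (1 - mu)^L
  pmax(0, (sigma * q_eff - 1) / (sigma - 1))
}

#' Locate the quasi-species error threshold by bisection
#'
#' The error threshold is the critical per-base mutation rate above which the
#' master sequence's information is lost from the equilibrium population.  It
#' is located operationally as the rate `mu_c` at which the stationary
#' master-class frequency crosses `epsilon` (the sharp transition exists only
#' in the infinite-genome limit).  With `p = 0` and large `L` the genome-wide
#' critical mutation number `mu_c * L` approaches `ln(sigma)`; in particular
#' `sigma = e` reproduces the classic rule of one mutation per genome per
#' replication.  With an error-free polymerase fraction `p > 1/sigma` the
#' master frequency is bounded below by `(sigma * p - 1)/(sigma - 1)` for all
#' `mu`, so no threshold exists: `exists = FALSE` is returned.
#'
#' @inheritParams solve_stationary
#' @param mu_range interval searched, within `[0, 0.5]`; the master frequency
#'   at the lower end must be at least `epsilon`.
#' @param epsilon master-frequency cutoff defining "lost".
#' @param tol bisection width at which to stop.
#' @param ... passed to [solve_stationary()].
#' @return object of class `qs_threshold`: list with `mu_critical`,
#'   `genome_wide_rate` (`mu_critical * L`), `exists`, and the parameters.
#' @examples
#' th <- find_error_threshold(sigma = exp(1), L = 50)
#' th$genome_wide_rate   # about 1 mutation per genome per replication
#' @export
find_error_threshold <- function(sigma, L, p = 0, mu_range = c(0, 0.5),
                                 epsilon = 1e-3, tol = 1e-5, ...) {
  stopifnot(length(mu_range) == 2L, mu_range[1] < mu_range[2])
  if (mu_range[1] < 0 || mu_range[2] > 0.5) {
    stop("`mu_range` must lie within [0, 0.5]", call. = FALSE)
  }
  stop_if_not_scalar_number(epsilon, "epsilon", min = 0, max = 1,
                            max_open = TRUE)
  master_at <- function(mu) {
    solve_stationary(sigma = sigma, L = L, mu = mu, p = p, ...)$master
  }
  lo <- mu_range[1]
  hi <- mu_range[2]
  if (master_at(lo) < epsilon) {
    stop(sprintf("master frequency at the lower end of mu_range (mu = %g) is already below epsilon = %g; the range does not bracket a threshold",
                 lo, epsilon), call. = FALSE)
  }
  base <- list(sigma = sigma, L = as.integer(L), p = p, epsilon = epsilon,
               tol = tol, mu_range = mu_range)
  if (master_at(hi) >= epsilon) {
    return(structure(c(list(mu_critical = NA_real_,
                            genome_wide_rate = NA_real_, exists = FALSE),
                       base),
                     class = "qs_threshold"))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (master_at(mid) >= epsilon) lo <- mid else hi <- mid
  }
  mu_c <- (lo + hi) / 2
  structure(c(list(mu_critical = mu_c, genome_wide_rate = mu_c * L,
                   exists = TRUE), base),
            class = "qs_threshold")
}

#' @export
print.qs_threshold <- function(x, ...) {
  cat(sprintf("Error threshold (sigma = %.4g, L = %d, p = %.3g, epsilon = %g)\n",
              x$sigma, x$L, x$p, x$epsilon))
  if (x$exists) {
    cat(sprintf("  mu_critical = %.6g per base  (genome-wide %.4g mutations/replication)\n",
                x$mu_critical, x$genome_wide_rate))
  } else {
    cat(sprintf("  no threshold in mu = [%g, %g]: the master class survives across the whole range\n",
                x$mu_range[1], x$mu_range[2]))
  }
  invisible(x)
}

#' Error-threshold phase table over superiority and polymerase-mixture grids
#'
#' Tabulates `mu_critical` for each `(sigma, p)` combination at fixed genome
#' length.  For fixed `sigma` the threshold is non-decreasing in `p`, and
#' rows with `p > 1/sigma` report no threshold at all: raising the error-free
#' polymerase fraction moves the error threshold up or abolishes it.
#'
#' @param sigma_grid,p_grid nonempty numeric grids.
#' @inheritParams find_error_threshold
#' @return data frame (classed `qs_phase_table`) with columns `sigma`, `p`,
#'   `L`, `mu_critical` (`NA` when absent), `genome_wide_rate`, `exists`.
#' @export
threshold_phase_table <- function(sigma_grid, p_grid, L,
                                  mu_range = c(0, 0.5), epsilon = 1e-3,
                                  tol = 1e-5, ...) {
  stopifnot(length(sigma_grid) >= 1L, length(p_grid) >= 1L)
  grid <- expand.grid(p = p_grid, sigma = sigma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    th <- find_error_threshold(sigma = grid$sigma[i], L = L, p = grid$p[i],
                               mu_range = mu_range, epsilon = epsilon,
                               tol = tol, ...)
    data.frame(sigma = grid$sigma[i], p = grid$p[i], L = as.integer(L),
               mu_critical = th$mu_critical,
               genome_wide_rate = th$genome_wide_rate, exists = th$exists)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("qs_phase_table", "data.frame")
  out
}
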