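# Genetic-load and mutation-budget arithmetic.

#' Genetic load under recurrent deleterious mutation
#'
#' Computes the mutation load `L = 1 - exp(-U)`, the fractional reduction of
#' population mean fitness at mutation--selection balance when `U` new
#' deleterious mutations arise per diploid genome per generation and fitness
#' effects combine multiplicatively (Haldane--Kimura--Maruyama load).  At
#' `U = 0` the load is 0; as `U` grows the load approaches 1, i.e. almost no
#' offspring is mutation-free and, under hard selection, the population cannot
#' sustain itself.
#'
#' The load satisfies the survival-multiplicativity identity
#' `1 - genetic_load(a + b) == (1 - genetic_load(a)) * (1 - genetic_load(b))`:
#' independent classes of deleterious mutation multiply their mutation-free
#' fractions.
#'
#' @param U number of new deleterious mutations per diploid genome per
#'   generation; non-negative, vectorized.
#' @return numeric vector of loads in `[0, 1)`.
#' @examples
#' genetic_load(2.2)   # ~0.89, the human estimate at U = 2.2
#' genetic_load(0.35)  # ~0.30, counting functionally important sites only
#' @seealso [mutations_per_generation()], [cell_level_mutations()]
#' @export
genetic_load <- function(U) {
  if (!is.numeric(U) || length(U) == 0L || anyNA(U) || any(!is.finite(U))) {
    stop("`U` must be finite and numeric", call. = FALSE)
  }
  if (any(U < 0)) {
    stop("`U` must be non-negative (a count of deleterious mutations per generation)",
         call. = FALSE)
  }
  1 - exp(-U)
}

#' Expected mutations per generation from per-site rates
#'
#' Multiplies a per-site per-year mutation rate by genome size and generation
#' time to give the expected number of new mutations per genome per
#' generation.  For humans (`rate = 1e-9`, `genome_size_bp = 3e9`,
#' `generation_years = 20` to `25`) this yields 60 to 75 mutations per
#' generation, consistent with direct parent--offspring sequencing estimates
#' of roughly 70.
#'
#' @param rate_per_site_per_year mutation rate per base pair per year (> 0).
#' @param genome_size_bp genome size in base pairs (> 0).
#' @param generation_years generation time in years (> 0).
#' @return expected mutation count per generation (vectorized product).
#' @examples
#' mutations_per_generation(1e-9, 3e9, 20)  # 60
#' mutations_per_generation(1e-9, 3e9, 25)  # 75
#' @export
mutations_per_generation <- function(rate_per_site_per_year, genome_size_bp,
                                     generation_years) {
  args <- list(rate_per_site_per_year = rate_per_site_per_year,
               genome_size_bp = genome_size_bp,
               generation_years = generation_years)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(x <= 0)) {
      stop(sprintf("`%s` must be positive", nm), call. = FALSE)
    }
  }
  rate_per_site_per_year * genome_size_bp * generation_years
}

#' Cell-level mutation count from per-replicore rates
#'
#' A replicore is a replication unit with a single origin from which leading-
#' and lagging-strand synthesis proceed.  Even when the mutation input per
#' replicore per generation is far below one -- so no error-threshold effect
#' operates within a single replicore -- the genome-wide count is the product
#' over replicores: 10,000 replicores at 0.01 mutations each give 100
#' mutations per cell per generation.
#'
#' @param replicore_count number of replicores per (diploid) cell (>= 0).
#' @param mutations_per_replicore expected new mutations per replicore per
#'   generation (>= 0).
#' @return expected mutations per cell per generation (vectorized product).
#' @examples
#' cell_level_mutations(10000, 0.01)  # 100
#' @export
cell_level_mutations <- function(replicore_count, mutations_per_replicore) {
  args <- list(replicore_count = replicore_count,
               mutations_per_replicore = mutations_per_replicore)
  for (nm in names(args)) {
    x <- args[[nm]]
    if (!is.numeric(x) || length(x) == 0L || anyNA(x) || any(x < 0)) {
      stop(sprintf("`%s` must be non-negative", nm), call. = FALSE)
    }
  }
  replicore_count * mutations_per_replicore
}

#' Tabulate genetic load for a set of mutation rates
#'
#' Convenience wrapper building the small `U` vs `L` table emitted by the
#' `load` subcommand.
#'
#' @param U vector of deleterious-mutation counts per generation.
#' @return a data frame with columns `U` and `L`, classed `load_table`.
#' @export
load_table <- function(U) {
  out <- data.frame(U = U, L = genetic_load(U))
  class(out) <- c("load_table", "data.frame")
  out
}
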