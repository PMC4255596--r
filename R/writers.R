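# Writers: TSV tables, JSON metadata and Newick trees per run.
# Runs are write-once: an existing output file is an error, never silently
# overwritten.

write_tsv <- function(df, path) {
  if (file.exists(path)) {
    stop(sprintf("output file already exists (runs are write-once): %s",
                 path), call. = FALSE)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

write_text <- function(txt, path) {
  if (file.exists(path)) {
    stop(sprintf("output file already exists (runs are write-once): %s",
                 path), call. = FALSE)
  }
  writeLines(txt, path)
  path
}

write_meta <- function(meta, path, config = NULL) {
  if (file.exists(path)) {
    stop(sprintf("output file already exists (runs are write-once): %s",
                 path), call. = FALSE)
  }
  meta$package <- "dispmut"
  meta$version <- as.character(utils::packageVersion("dispmut"))
  meta$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  if (!is.null(config)) meta$config <- as_flags(config)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

ensure_outdir <- function(outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (file.access(outdir, mode = 2L) != 0L) {
    stop(sprintf("output directory is not writable: %s", outdir),
         call. = FALSE)
  }
  invisible(outdir)
}

#' Write a run result to an output directory
#'
#' Serializes any engine result as plain-text artifacts: TSV tables with a
#' header row and `.` decimals, JSON metadata (parameters, seeds, package
#' version, timestamp, and -- when `config` is supplied -- the full
#' round-trippable run configuration), plus Newick for pedigree runs.
#' Existing files are never overwritten.
#'
#' Artifacts by result class: `replicore_pedigree` writes `census.tsv`,
#' `tree.nwk`, `meta.json`; `qs_run` writes `stationary.tsv`,
#' `threshold.json`, `meta.json`; `ga_run` writes `trajectory.tsv`,
#' `instance.json`, `meta.json`; `load_table` writes `load.tsv`,
#' `meta.json`; `budget_table` writes `budget.tsv`, `meta.json`.
#'
#' @param result an engine result object.
#' @param outdir output directory (created if needed).
#' @param config optional `run_config` to embed in the metadata.
#' @param ... passed to methods.
#' @return invisible character vector of the paths written.
#' @export
write_results <- function(result, outdir, config = NULL, ...) {
  UseMethod("write_results")
}

#' @export
write_results.default <- function(result, outdir, config = NULL, ...) {
  stop(sprintf("no writer for objects of class `%s`",
               paste(class(result), collapse = "/")), call. = FALSE)
}

#' @export
write_results.replicore_pedigree <- function(result, outdir, config = NULL,
                                             annotate = "mutation_count",
                                             ...) {
  ensure_outdir(outdir)
  cen <- pedigree_census(result)
  names(cen) <- c("generation", "mutation_count", "n_genomes")
  paths <- c(
    write_tsv(cen, file.path(outdir, "census.tsv")),
    write_text(export_newick(result, annotate = annotate),
               file.path(outdir, "tree.nwk")),
    write_meta(list(subcommand = "pedigree", mode = result$mode,
                    d = result$d, generations = result$generations),
               file.path(outdir, "meta.json"), config))
  invisible(paths)
}

#' @export
write_results.qs_run <- function(result, outdir, config = NULL, ...) {
  ensure_outdir(outdir)
  st <- result$stationary
  th <- result$threshold
  stat_df <- data.frame(class = seq_along(st$x) - 1L, frequency = st$x)
  th_path <- file.path(outdir, "threshold.json")
  if (file.exists(th_path)) {
    stop(sprintf("output file already exists (runs are write-once): %s",
                 th_path), call. = FALSE)
  }
  jsonlite::write_json(
    list(sigma = th$sigma, L = th$L, p = th$p, epsilon = th$epsilon,
         bisect_tol = th$tol, mu_range = th$mu_range, exists = th$exists,
         mu_critical = th$mu_critical,
         genome_wide_rate = th$genome_wide_rate),
    th_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  paths <- c(
    write_tsv(stat_df, file.path(outdir, "stationary.tsv")),
    th_path,
    write_meta(list(subcommand = "quasispecies", sigma = st$sigma, L = st$L,
                    mu = st$mu, p = st$p, solver = st$method,
                    residual = st$residual, iterations = st$iterations),
               file.path(outdir, "meta.json"), config))
  invisible(paths)
}

#' @export
write_results.qs_phase_table <- function(result, outdir, config = NULL,
                                         ...) {
  ensure_outdir(outdir)
  out <- as.data.frame(result)
  out$mu_critical <- ifelse(out$exists, format(out$mu_critical), "none")
  out$genome_wide_rate <- ifelse(out$exists, format(out$genome_wide_rate),
                                 "none")
  paths <- c(
    write_tsv(out, file.path(outdir, "phase_table.tsv")),
    write_meta(list(subcommand = "quasispecies", table = "phase"),
               file.path(outdir, "meta.json"), config))
  invisible(paths)
}

#' @export
write_results.ga_run <- function(result, outdir, config = NULL, ...) {
  ensure_outdir(outdir)
  inst <- result$instance
  inst_path <- file.path(outdir, "instance.json")
  if (file.exists(inst_path)) {
    stop(sprintf("output file already exists (runs are write-once): %s",
                 inst_path), call. = FALSE)
  }
  jsonlite::write_json(
    list(n_items = inst$n_items, weights = inst$weights,
         values = inst$values, capacity = inst$capacity, seed = inst$seed,
         weight_range = inst$weight_range, value_range = inst$value_range,
         capacity_fraction = inst$capacity_fraction),
    inst_path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  meta <- c(list(subcommand = "ga", dp_optimum = result$dp_optimum,
                 solved = result$solved, extinct = result$extinct,
                 generation_solved = result$generation_solved,
                 final_best = result$final_best),
            result$params)
  paths <- c(
    write_tsv(result$trajectory, file.path(outdir, "trajectory.tsv")),
    inst_path,
    write_meta(meta, file.path(outdir, "meta.json"), config))
  invisible(paths)
}

#' @export
write_results.load_table <- function(result, outdir, config = NULL, ...) {
  ensure_outdir(outdir)
  paths <- c(
    write_tsv(as.data.frame(result), file.path(outdir, "load.tsv")),
    write_meta(list(subcommand = "load"), file.path(outdir, "meta.json"),
               config))
  invisible(paths)
}

#' @export
write_results.budget_table <- function(result, outdir, config = NULL, ...) {
  ensure_outdir(outdir)
  paths <- c(
    write_tsv(as.data.frame(result), file.path(outdir, "budget.tsv")),
    write_meta(list(subcommand = "budget"), file.path(outdir, "meta.json"),
               config))
  invisible(paths)
}
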