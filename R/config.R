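# Run configuration: subcommand schemas, validation, and execution dispatch.
# Backs the shell entry point in inst/cli/dispmut.

# One schema entry per key: type, default, optional range/choices.
.num <- function(default, min = -Inf, max = Inf) {
  list(type = "numeric", default = default, min = min, max = max)
}
.int <- function(default, min = -Inf, max = Inf) {
  list(type = "integer", default = default, min = min, max = max)
}
.chr <- function(default, choices = NULL) {
  list(type = "character", default = default, choices = choices)
}

config_schemas <- function() {
  list(
    pedigree = list(
      mode = .chr("disparity", c("disparity", "parity")),
      d = .int(2L, min = 1),
      generations = .int(6L, min = 0),
      max_generations = .int(20L, min = 0),
      annotate = .chr("mutation_count", c("mutation_count", "new_mutations"))
    ),
    quasispecies = list(
      sigma = .num(exp(1), min = 1),
      L = .int(100L, min = 1, max = 1000),
      mu = .num(0.005, min = 0, max = 0.5),
      p = .num(0, min = 0, max = 1),
      epsilon = .num(1e-3, min = 0, max = 1),
      bisect_tol = .num(1e-5, min = 0),
      mu_lo = .num(0, min = 0, max = 0.5),
      mu_hi = .num(0.5, min = 0, max = 0.5)
    ),
    ga = list(
      n_items = .int(20L, min = 1),
      instance_seed = .int(1L),
      pop_size = .int(200L, min = 2),
      generations = .int(500L, min = 0),
      mu_leading = .num(0, min = 0, max = 0.5),
      mu_lagging = .num(0.08, min = 0, max = 0.5),
      keep_fraction = .num(0.5, min = 0, max = 1)
    ),
    load = list(
      U = list(type = "numeric_vector", default = c(0, 0.35, 2.2, 3.2),
               min = 0, max = Inf)
    ),
    budget = list(
      rate_per_site_per_year = .num(1e-9, min = 0),
      genome_size_bp = .num(3e9, min = 0),
      generation_years = .num(25, min = 0),
      replicore_count = .num(10000, min = 0),
      mutations_per_replicore = .num(0.01, min = 0)
    )
  )
}

.global_schema <- function() {
  list(seed = .int(1L),
       outdir = .chr("dispmut-run"),
       log_level = .chr("info", c("quiet", "info", "debug")))
}

coerce_key <- function(value, spec, key) {
  if (spec$type %in% c("numeric", "integer") && is.character(value)) {
    value <- suppressWarnings(as.numeric(value))
  }
  if (spec$type == "numeric_vector" && is.character(value)) {
    value <- suppressWarnings(as.numeric(strsplit(value, ",")[[1]]))
  }
  switch(spec$type,
    numeric = , integer = {
      if (!is.numeric(value) || length(value) != 1L || is.na(value)) {
        stop(sprintf("key `%s` must be a single number", key), call. = FALSE)
      }
      if (value < spec$min || value > spec$max) {
        stop(sprintf("key `%s` = %s is out of range [%s, %s]", key,
                     format(value), format(spec$min), format(spec$max)),
             call. = FALSE)
      }
      if (spec$type == "integer") {
        if (value != as.integer(value)) {
          stop(sprintf("key `%s` must be a whole number", key),
               call. = FALSE)
        }
        value <- as.integer(value)
      }
      value
    },
    numeric_vector = {
      if (!is.numeric(value) || length(value) == 0L || anyNA(value)) {
        stop(sprintf("key `%s` must be a numeric vector", key),
             call. = FALSE)
      }
      if (any(value < spec$min) || any(value > spec$max)) {
        stop(sprintf("key `%s` has entries out of range [%s, %s]", key,
                     format(spec$min), format(spec$max)), call. = FALSE)
      }
      value
    },
    character = {
      value <- as.character(value)
      if (length(value) != 1L) {
        stop(sprintf("key `%s` must be a single string", key),
             call. = FALSE)
      }
      if (!is.null(spec$choices) && !(value %in% spec$choices)) {
        stop(sprintf("key `%s` must be one of: %s", key,
                     paste(spec$choices, collapse = ", ")), call. = FALSE)
      }
      value
    }
  )
}

#' Parse and validate a run configuration
#'
#' Resolves a run configuration from an optional YAML file and a named list
#' of flags; flags override file values.  Every key is checked against the
#' schema of its subcommand (`pedigree`, `quasispecies`, `ga`, `load`,
#' `budget`) plus the global keys `seed`, `outdir` and `log_level`; unknown
#' keys and out-of-range values are rejected with an error naming the key.
#' Unspecified keys take documented defaults, so re-running the same
#' configuration reproduces the same outputs bit for bit.
#'
#' @param file optional path to a YAML file of `key: value` pairs (must
#'   include `subcommand` unless given as a flag).
#' @param flags named list (or named character vector) of overrides; values
#'   may be strings, as delivered by a command line.
#' @return object of class `run_config`: list with `subcommand`, `seed`,
#'   `outdir`, `log_level` and `params` (the subcommand's parameters).
#' @examples
#' parse_config(flags = list(subcommand = "load", U = "0,2.2"))
#' @seealso [run_config_execute()], [write_results()]
#' @export
parse_config <- function(file = NULL, flags = list()) {
  vals <- list()
  if (!is.null(file)) {
    if (!file.exists(file)) {
      stop(sprintf("config file not found: %s", file), call. = FALSE)
    }
    vals <- yaml::read_yaml(file)
    if (!is.list(vals)) stop("config file must be a key-value mapping",
                             call. = FALSE)
  }
  flags <- as.list(flags)
  if (length(flags) && (is.null(names(flags)) || any(names(flags) == ""))) {
    stop("all flags must be named", call. = FALSE)
  }
  overridden <- intersect(names(flags), names(vals))
  vals[names(flags)] <- flags
  sub <- vals$subcommand
  schemas <- config_schemas()
  if (is.null(sub) || !is.character(sub) || length(sub) != 1L ||
      !(sub %in% names(schemas))) {
    stop(sprintf("key `subcommand` must be one of: %s",
                 paste(names(schemas), collapse = ", ")), call. = FALSE)
  }
  schema <- c(schemas[[sub]], .global_schema())
  vals$subcommand <- NULL
  unknown <- setdiff(names(vals), names(schema))
  if (length(unknown)) {
    stop(sprintf("unknown key `%s` for subcommand `%s`", unknown[1L], sub),
         call. = FALSE)
  }
  resolved <- lapply(names(schema), function(key) {
    if (key %in% names(vals)) coerce_key(vals[[key]], schema[[key]], key)
    else schema[[key]]$default
  })
  names(resolved) <- names(schema)
  cfg <- structure(
    list(subcommand = sub,
         seed = resolved$seed,
         outdir = resolved$outdir,
         log_level = resolved$log_level,
         params = resolved[setdiff(names(schema), names(.global_schema()))]),
    class = "run_config")
  if (length(overridden) && cfg$log_level != "quiet") {
    message("flags override config file for: ",
            paste(overridden, collapse = ", "))
  }
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run config: subcommand `%s`, seed %d, outdir `%s`, log level %s\n",
              x$subcommand, x$seed, x$outdir, x$log_level))
  for (key in names(x$params)) {
    cat(sprintf("  %s = %s\n", key,
                paste(format(x$params[[key]]), collapse = ", ")))
  }
  invisible(x)
}

#' Flatten a run configuration to a flag list
#'
#' The inverse of [parse_config()]: produces a named list such that
#' `parse_config(flags = as_flags(cfg))` reconstructs an equal
#' configuration.  Used to embed the configuration in run metadata.
#'
#' @param config a `run_config`.
#' @return named list of scalar (or numeric-vector) values.
#' @export
as_flags <- function(config) {
  stopifnot(inherits(config, "run_config"))
  c(list(subcommand = config$subcommand, seed = config$seed,
         outdir = config$outdir, log_level = config$log_level),
    config$params)
}

#' Execute a parsed run configuration
#'
#' Dispatches to the engine named by the subcommand and returns its result
#' object, suitable for [write_results()].
#'
#' @param config a `run_config` from [parse_config()].
#' @return a `replicore_pedigree`, `qs_run`, `ga_run`, `load_table` or
#'   `budget_table`, depending on the subcommand.
#' @export
run_config_execute <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  switch(config$subcommand,
    pedigree = grow_pedigree(mode = p$mode, d = p$d,
                             generations = p$generations,
                             max_generations = p$max_generations),
    quasispecies = {
      st <- solve_stationary(sigma = p$sigma, L = p$L, mu = p$mu, p = p$p)
      th <- find_error_threshold(sigma = p$sigma, L = p$L, p = p$p,
                                 mu_range = c(p$mu_lo, p$mu_hi),
                                 epsilon = p$epsilon, tol = p$bisect_tol)
      structure(list(stationary = st, threshold = th), class = "qs_run")
    },
    ga = run_ga(generate_instance(p$n_items, seed = p$instance_seed),
                pop_size = p$pop_size, generations = p$generations,
                mu_leading = p$mu_leading, mu_lagging = p$mu_lagging,
                keep_fraction = p$keep_fraction, seed = config$seed),
    load = load_table(p$U),
    budget = {
      out <- data.frame(
        quantity = c("mutations_per_generation", "cell_level_mutations"),
        value = c(mutations_per_generation(p$rate_per_site_per_year,
                                           p$genome_size_bp,
                                           p$generation_years),
                  cell_level_mutations(p$replicore_count,
                                       p$mutations_per_replicore)))
      class(out) <- c("budget_table", "data.frame")
      out
    })
}
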