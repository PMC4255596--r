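# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream.
local_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

stop_if_not_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                      integer = FALSE, max_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (integer && x != as.integer(x)) {
    stop(sprintf("`%s` must be a whole number", name), call. = FALSE)
  }
  if (x < min || x > max || (max_open && x == max)) {
    stop(sprintf("`%s` = %s is outside [%s, %s%s", name, format(x),
                 format(min), format(max), if (max_open) ")" else "]"),
         call. = FALSE)
  }
  invisible(x)
}
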