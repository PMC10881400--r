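# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so simulators are reproducible without clobbering
#' the session stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' @noRd
stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

#' @noRd
check_scalar_num <- function(x, field, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_config(field, "must be a single non-missing number")
  }
  if (strict_lower && x <= lower) {
    stop_config(field, sprintf("must be > %g", lower))
  }
  if (!strict_lower && x < lower) {
    stop_config(field, sprintf("must be >= %g", lower))
  }
  if (x > upper) stop_config(field, sprintf("must be <= %g", upper))
  invisible(x)
}

#' Sample from a normal distribution truncated at zero (rejection sampling)
#' @noRd
rnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(max(mean, 0), n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0L) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw > 0
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}
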