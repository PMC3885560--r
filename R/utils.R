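#' @keywords internal
"_PACKAGE"

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
# All stochastic entry points thread their `seed` argument through here so a
# call never perturbs the session RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
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
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar checks used across constructors; stop with the offending field name
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive number", name), call. = FALSE)
  }
  as.numeric(x)
}

check_fraction <- function(x, name, open_left = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1 ||
      (open_left && x == 0)) {
    stop(sprintf("'%s' must be a fraction in %s0, 1]", name,
                 if (open_left) "(" else "["), call. = FALSE)
  }
  as.numeric(x)
}

# sample standard deviation (n - 1 denominator), the convention used
# throughout the pipeline so t statistics downstream are consistent
sd1 <- function(x) stats::sd(x)
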