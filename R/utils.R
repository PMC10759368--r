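clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# round-then-clamp for bounded integer instruments (MMSE, FAQ, recall, RAVLT)
as_bounded_int <- function(x, lo, hi) as.integer(clamp(round(x), lo, hi))

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_number <- function(x, field, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop_field(field, sprintf("must be a single number in [%s, %s]", lo, hi))
  }
  invisible(x)
}

check_proportions <- function(p, field, tol = 1e-9) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop_field(field, "proportions must lie in [0, 1]")
  }
  if (abs(sum(p) - 1) > tol) {
    stop_field(field, sprintf("proportions must sum to 1 (got %.12f)", sum(p)))
  }
  invisible(p)
}

# one derived 31-bit seed stream per master seed; `n` draws
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
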