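# Internal helpers shared across modules.

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_num <- function(x, field, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_field(field, "must be a single finite number")
  }
  if (x < lower) stop_field(field, sprintf("must be >= %g", lower))
  if (x > upper) stop_field(field, sprintf("must be <= %g", upper))
  invisible(x)
}

# Monotone piecewise-cubic interpolant through control points, constant
# beyond the control range (Fritsch-Carlson tangents preserve monotonicity).
monotone_curve <- function(times, values) {
  stopifnot(length(times) == length(values), length(times) >= 2L)
  f <- stats::splinefun(times, values, method = "monoH.FC")
  lo <- min(times); hi <- max(times)
  function(t) f(pmin(pmax(t, lo), hi))
}
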