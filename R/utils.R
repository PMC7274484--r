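# Internal numeric helpers shared across modules.

#' Evaluate code with a temporary RNG state
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards. All stochastic operations in the package take
#' explicit seeds and route through this helper, so nothing leaks into (or
#' depends on) the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
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
  set.seed(as.integer(seed))
  force(code)
}

# First derivative dy/dx on a (possibly nonuniform) grid using three-point
# formulas: second-order centred in the interior, one-sided at the ends.
deriv_grid <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3L)
  d <- numeric(n)
  h1 <- x[2:(n - 1)] - x[1:(n - 2)]
  h2 <- x[3:n] - x[2:(n - 1)]
  d[2:(n - 1)] <- (-h2 / (h1 * (h1 + h2))) * y[1:(n - 2)] +
    ((h2 - h1) / (h1 * h2)) * y[2:(n - 1)] +
    (h1 / (h2 * (h1 + h2))) * y[3:n]
  ha <- x[2] - x[1]
  hb <- x[3] - x[2]
  d[1] <- -(2 * ha + hb) / (ha * (ha + hb)) * y[1] +
    (ha + hb) / (ha * hb) * y[2] -
    ha / (hb * (ha + hb)) * y[3]
  ha <- x[n - 1] - x[n - 2]
  hb <- x[n] - x[n - 1]
  d[n] <- hb / (ha * (ha + hb)) * y[n - 2] -
    (ha + hb) / (ha * hb) * y[n - 1] +
    (ha + 2 * hb) / (hb * (ha + hb)) * y[n]
  d
}

# Full-precision number formatting used by the plain-text writers so that
# read/write round-trips are bit exact for doubles.
format_full <- function(x) {
  sprintf("%.17g", x)
}

stop_if_not_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  }
  invisible(x)
}
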