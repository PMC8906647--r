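# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a fixed RNG seed without disturbing the global stream
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that results are reproducible given a seed and callers'
#' RNG state is left untouched.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
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
  set.seed(as.integer(seed))
  code
}

# Derive a stream of child seeds from one master seed (keeps each stage's
# randomness independent while remaining fully determined by the master).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

# Bivariate standard-normal CDF P(X < a, Y < b) with correlation rho,
# by one-dimensional quadrature of the conditional normal CDF.
pbinorm <- function(a, b, rho) {
  if (abs(rho) < .Machine$double.eps) return(pnorm(a) * pnorm(b))
  if (rho >= 1 - 1e-12) return(pnorm(min(a, b)))
  if (rho <= -1 + 1e-12) return(max(0, pnorm(a) + pnorm(b) - 1))
  s <- sqrt(1 - rho^2)
  integrate(function(x) dnorm(x) * pnorm((b - rho * x) / s),
            -Inf, a, rel.tol = 1e-10)$value
}
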