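#' @useDynLib carnmove, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dgamma rgamma runif rnorm optim qgamma sd
#'   complete.cases lm quantile median setNames aggregate
#' @importFrom utils read.csv write.csv head tail
#' @importFrom grDevices chull
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# go through this so they are pure functions of (inputs, seed).
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
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic per-stage seed derived from a base seed and a stage name.
# Kept below 2^31 so it is always a valid R integer seed.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647L)
}

#' Wrap angles to the interval (-pi, pi]
#'
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped to `(-pi, pi]`.
#' @export
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

#' Draw from a wrapped Cauchy distribution
#'
#' Samples by wrapping a Cauchy variate with location `m` and scale
#' `-log(rho)`; `rho = 0` reduces to the circular uniform.
#'
#' @param n number of draws.
#' @param m location (radians).
#' @param rho concentration in `[0, 1)`.
#' @return angles in `(-pi, pi]`.
#' @export
rwrappedcauchy <- function(n, m = 0, rho = 0) {
  stopifnot(rho >= 0, rho < 1)
  if (rho == 0) return(wrap_angle(runif(n, -pi, pi)))
  gam <- -log(rho)
  wrap_angle(m + gam * tan(pi * (runif(n) - 0.5)))
}

# Gamma draws parameterized by mean and SD.
rgamma_ms <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  rgamma(n, shape = shape, scale = sd^2 / mean)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x > 0 && x == round(x)
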