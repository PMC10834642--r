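# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `code`, and restores the caller's RNG state so that
#' seeded simulation calls never disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation; stays inside 32-bit integer range.
derive_seed <- function(seed, offset) {
  s <- (as.double(seed) * 48271 + as.double(offset) * 1009 + 7) %% 2147483629
  as.integer(s) + 1L
}

# Lognormal multiplicative noise with exact unit mean and coefficient of
# variation `cv`; cv = 0 gives exact ones (consuming no randomness).
noise_multiplier <- function(n, cv) {
  if (cv < 0) stop("noise CV must be >= 0", call. = FALSE)
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

# Height of a Gaussian peak of unit area with the given sigma (minutes);
# peak height = area * gauss_gain(sigma).
gauss_gain <- function(sigma) 1 / (sigma * sqrt(2 * pi))

# Trapezoidal integral of y over grid x.
trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

stopifnot_scalar_pos <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(what, " must be a single positive number", call. = FALSE)
  }
  invisible(x)
}
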