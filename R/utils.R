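# Internal helpers: error signalling, deterministic seed derivation,
# truncated-normal sampling, grid sequences.

mse_abort <- function(class, msg, ...) {
  stop(structure(
    list(message = sprintf(msg, ...), call = sys.call(-1)),
    class = c(class, "mse_error", "error", "condition")
  ))
}

#' Derive a deterministic 32-bit seed from arbitrary labels
#'
#' Hashes the string representation of its arguments into a positive integer
#' seed. Used to give every (context, strategy, replicate) cell its own
#' reproducible random stream, independent of execution order.
#'
#' @param ... atomic values concatenated (with a separator) into the hash input.
#' @return a positive integer scalar suitable for [set.seed()].
#' @export
hash_seed <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                    character(1)), collapse = "|")
  b <- utf8ToInt(s)
  h <- 5381
  # polynomial rolling hash mod a prime < 2^31; doubles stay exact
  for (x in b) h <- (h * 33 + x) %% 2147483629
  as.integer(h) + 1L
}

#' Sample from a truncated normal distribution
#'
#' Inverse-CDF sampler: draws a uniform on the CDF interval covered by
#' \code{[lower, upper]} and maps it back through [stats::qnorm()]. With
#' \code{sd = 0} the degenerate value is clamped to the bounds.
#'
#' @param n number of draws.
#' @param mean,sd location and scale of the parent normal.
#' @param lower,upper truncation bounds (either may be infinite).
#' @return numeric vector of length \code{n}, all values within bounds.
#' @export
rtrunc_norm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  if (any(sd < 0)) mse_abort("mse_domain_error", "sd must be >= 0")
  if (all(sd == 0)) return(pmin(pmax(rep_len(mean, n), lower), upper))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  x <- stats::qnorm(u, mean, sd)
  # guard against floating-point overshoot at the bounds
  pmin(pmax(x, lower), upper)
}

# mean of a truncated normal; used internally for checks/documentation
trunc_norm_mean <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(min(max(mean, lower), upper))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

# seq() replacement robust to floating-point step accumulation
seq_grid <- function(from, to, by) {
  if (by <= 0) mse_abort("mse_invariant_error", "grid step must be > 0")
  if (from > to + 1e-12) mse_abort("mse_invariant_error", "grid min must be <= max")
  n <- floor((to - from) / by + 1e-9)
  round(from + by * (0:n), 10)
}

# short stable hash of a configuration for provenance / cache keys
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "\n")
  sprintf("%08x", hash_seed(s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
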