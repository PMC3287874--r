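#' Derive a reproducible sub-seed from a master seed
#'
#' Counter-based seed derivation: every (master seed, stream id) pair maps
#' deterministically to a sub-seed, so replicates and chains can be
#' re-generated individually without replaying the whole random stream.
#' Uses two rounds of a Lehmer multiplicative congruential step modulo
#' 2^31 - 1; all intermediate products stay below 2^53 and are exact in
#' double precision.
#'
#' @param master integer master seed.
#' @param stream nonnegative integer stream counter (replicate index,
#'   chain index, ...).
#' @return an integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(42, 0)
#' derive_seed(42, 1)
derive_seed <- function(master, stream = 0L) {
  stopifnot(length(master) == 1L, is.finite(master),
            length(stream) == 1L, is.finite(stream), stream >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  x <- (abs(as.numeric(master)) %% (m - 1)) + 1
  x <- (x * 48271) %% m
  x <- (x + (as.numeric(stream) %% m) * 16807) %% m
  if (x == 0) x <- 1
  x <- (x * 48271) %% m
  x <- (x * 48271) %% m
  as.integer(x)
}

# log(1 + exp(x)) without overflow; accurate for |x| up to ~745 and beyond
log1pexp <- function(x) {
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  mid <- x > 18 & x <= 33.3
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

# type-7 empirical quantiles, named for readability at call sites
quantile7 <- function(x, probs) unname(quantile(x, probs = probs, type = 7, names = FALSE))

#' Effective sample size of a scalar MCMC series
#'
#' Initial positive sequence estimator: sums autocorrelations up to the
#' first non-positive lag. A rough but standard monitoring quantity.
#'
#' @param x numeric vector (one chain of a scalar functional).
#' @param max_lag maximum lag considered.
#' @return estimated effective sample size (numeric).
#' @export
ess <- function(x, max_lag = min(length(x) - 1L, 1000L)) {
  n <- length(x)
  if (n < 10L || sd(x) == 0) return(n)
  rho <- acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  pos <- which(rho <= 0)
  if (length(pos)) rho <- rho[seq_len(pos[1] - 1L)]
  n / (1 + 2 * sum(rho))
}
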