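#' Quadrature reference for the posterior deviance distribution
#'
#' Independent validation oracle for the Metropolis sampler, feasible for
#' models with at most two coefficients: the likelihood is evaluated on a
#' dense lattice over the prior box (restricted to MLE +/- 8 standard
#' errors when the MLE exists), normalised to lattice weights, and the
#' deviance at every node is returned with its posterior weight.
#'
#' @param X N x p design matrix with p <= 2 (or a `design_matrix`).
#' @param y binary response.
#' @param prior_bound half-width of the flat prior box (default 25).
#' @param resolution lattice points per dimension (default 2001 for
#'   p = 1, 301 for p = 2).
#' @return list of class `deviance_quadrature` with `deviances`,
#'   `weights` (summing to 1), and `nodes` (lattice coordinates).
#' @export
#' @examples
#' q <- grid_posterior_reference(matrix(1, 10, 1), c(rep(1, 3), rep(0, 7)))
#' sum(q$weights)
grid_posterior_reference <- function(X, y = NULL, prior_bound = 25,
                                     resolution = NULL) {
  if (inherits(X, "design_matrix")) { y <- X$y; X <- X$X }
  X <- as.matrix(X)
  p <- ncol(X)
  if (p > 2L) stop("quadrature reference supports at most 2 coefficients")
  if (is.null(resolution)) resolution <- if (p == 1L) 2001L else 301L
  mle <- tryCatch(fit_logit_mle(X, y), error = function(e) NULL)
  bounds <- lapply(seq_len(p), function(j) {
    if (!is.null(mle) && mle$converged) {
      se <- sqrt(mle$covariance[j, j])
      c(max(-prior_bound, mle$beta_hat[j] - 8 * se),
        min(prior_bound, mle$beta_hat[j] + 8 * se))
    } else c(-prior_bound, prior_bound)
  })
  grids <- lapply(bounds, function(b) seq(b[1], b[2], length.out = resolution))
  nodes <- as.matrix(expand.grid(grids))
  eta <- X %*% t(nodes)
  ll <- colSums(y * eta - log1pexp(eta))
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  structure(list(deviances = -2 * ll, weights = w, nodes = nodes,
                 bounds = bounds),
            class = "deviance_quadrature")
}

#' Importance-resample i.i.d. deviance values from a quadrature reference
#'
#' @param quad a `deviance_quadrature`.
#' @param n number of draws.
#' @param seed optional seed.
#' @return numeric vector of deviance values drawn with the lattice
#'   weights (with replacement).
#' @export
resample_quadrature <- function(quad, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  quad$deviances[sample.int(length(quad$weights), n, replace = TRUE,
                            prob = quad$weights)]
}

#' Posterior mean deviance under a quadrature reference
#' @param quad a `deviance_quadrature`.
#' @return weighted mean of the deviance over the lattice.
#' @export
quadrature_mean_deviance <- function(quad) sum(quad$weights * quad$deviances)

#' Kolmogorov-Smirnov distance between a sample and a reference
#'
#' Sup-norm distance between the empirical CDF of `x` and a reference
#' distribution given either as a CDF function, as a second sample, or
#' as a `deviance_quadrature` (weighted discrete distribution).
#'
#' @param x numeric sample.
#' @param reference a function (vectorised CDF), a numeric vector
#'   (second sample), or a `deviance_quadrature`.
#' @return the KS statistic in `[0, 1]`.
#' @export
#' @examples
#' ks_distance(runif(500), function(q) punif(q))
ks_distance <- function(x, reference) {
  x <- sort(x)
  n <- length(x)
  if (is.function(reference)) {
    Fx <- reference(x)
    return(max(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx)))
  }
  if (inherits(reference, "deviance_quadrature")) {
    ord <- order(reference$deviances)
    v <- reference$deviances[ord]
    cw <- cumsum(reference$weights[ord])
    refF <- function(q) {
      idx <- findInterval(q, v)
      ifelse(idx == 0, 0, cw[pmax(idx, 1)])
    }
    return(ks_distance(x, refF))
  }
  # two-sample form
  y <- sort(as.numeric(reference))
  pts <- sort(unique(c(x, y)))
  F1 <- findInterval(pts, x) / n
  F2 <- findInterval(pts, y) / length(y)
  max(abs(F1 - F2))
}
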