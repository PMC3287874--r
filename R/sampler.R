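#' Sampler configuration for random-walk Metropolis
#'
#' @param n_draws number of retained posterior draws (default 10,000).
#' @param n_burnin number of discarded burn-in iterations (default 2,000).
#' @param proposal_scale `"auto"` (default: 2.38/sqrt(p), the standard
#'   random-walk scaling of the MLE covariance) or a positive number
#'   multiplying the proposal Cholesky factor.
#' @param prior_bound half-width C of the uniform prior box on each
#'   coefficient (default 25). The flat prior is truncated to
#'   `[-C, C]^p` so the posterior is proper even under separation; for
#'   identified models the truncation is numerically irrelevant (an
#'   insensitivity that is itself tested).
#' @param adapt_during_burnin adapt a single global proposal-scale factor
#'   during burn-in only (frozen afterwards, so the retained chain has
#'   the correct invariant distribution). Default `TRUE`.
#' @param target_acceptance acceptance rate targeted by the burn-in
#'   adaptation (default 0.25; for one-coefficient chains the classical
#'   univariate optimum is nearer 0.44 and may be requested explicitly).
#' @param thin keep every `thin`-th post-burn-in iteration (default 1,
#'   i.e. no thinning: the retained chain is the raw chain, as in the
#'   analysis pipeline). Validation checks that compare the retained
#'   draws against an analytic or quadrature distribution use a thinned
#'   chain, because sup-norm distances of the stated sharpness are only
#'   certifiable from weakly dependent draws; the number of retained
#'   draws is `n_draws` either way.
#' @return a list of class `sampler_config`.
#' @export
sampler_config <- function(n_draws = 10000L, n_burnin = 2000L,
                           proposal_scale = "auto", prior_bound = 25,
                           adapt_during_burnin = TRUE,
                           target_acceptance = 0.25, thin = 1L) {
  stopifnot(n_draws >= 1, n_burnin >= 0, prior_bound > 0,
            target_acceptance > 0, target_acceptance < 1, thin >= 1)
  structure(list(n_draws = as.integer(n_draws),
                 n_burnin = as.integer(n_burnin),
                 proposal_scale = proposal_scale,
                 prior_bound = prior_bound,
                 adapt_during_burnin = isTRUE(adapt_during_burnin),
                 target_acceptance = target_acceptance,
                 thin = as.integer(thin)),
            class = "sampler_config")
}

#' Sample the posterior of logistic-regression coefficients
#'
#' The core fitting function of the package. Under a flat prior
#' truncated to the box `[-C, C]^p`, the posterior of the coefficients
#' is proportional to the likelihood of the logistic model; a random-walk
#' Metropolis chain with multivariate-normal proposals (covariance
#' `(2.38^2/p)` times the MLE covariance, falling back to a scaled
#' identity) draws from it, and the deviance `-2 log L` is recorded at
#' every retained draw. The posterior distribution of the deviance — not
#' a single point value — is the evidence object used downstream.
#'
#' The chain starts at the MLE when it exists (minimising burn-in, since
#' the headline statistics depend on the lower tail of the deviance
#' distribution) and at zero otherwise. A global proposal-scale factor
#' may be adapted during burn-in only.
#'
#' @param x design: an N x p numeric matrix, a `design_matrix` from
#'   [build_design_matrix()], or a model formula.
#' @param y binary response vector (not needed when `x` carries one).
#' @param config a [sampler_config()].
#' @param seed integer seed for the chain (recommended: chains compared
#'   by [compare_models()] must use different seeds).
#' @param init optional starting coefficient vector inside the prior box.
#' @param model_label label stored on the result (used in printouts).
#' @param data,... for the formula method: a data frame with the model
#'   variables, and arguments forwarded to the default method.
#' @return an object of class `rwm_logit`: a list with `draws` (M x p),
#'   `deviances` (length M), `acceptance_rate`, `mle` (the
#'   [fit_logit_mle()] anchor, or `NULL` if unidentifiable), `config`,
#'   `seed`, `model_label` and `diagnostics` (deviance effective sample
#'   size and a drift flag comparing mean deviance across chain thirds).
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(200)
#' y <- rbinom(200, 1, plogis(-0.5 + x))
#' fit <- rwm_logit(cbind(1, x), y, sampler_config(2000, 500), seed = 2)
#' summary(fit)
rwm_logit <- function(x, ...) UseMethod("rwm_logit")

#' @rdname rwm_logit
#' @export
rwm_logit.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(x, mf)
  rwm_logit.default(X, y, ...)
}

#' @rdname rwm_logit
#' @export
rwm_logit.design_matrix <- function(x, ...) {
  rwm_logit.default(x$X, x$y, model_label = factor_label(x$factor), ...)
}

#' @rdname rwm_logit
#' @export
rwm_logit.default <- function(x, y, config = sampler_config(),
                              seed = NULL, init = NULL,
                              model_label = "model", ...) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  p <- ncol(X)
  if (qr(X)$rank < p)
    stop("design matrix is not full rank; cannot sample an unidentified model")

  mle <- tryCatch(fit_logit_mle(X, y), error = function(e) NULL)

  C <- config$prior_bound
  if (is.null(init)) {
    init <- if (!is.null(mle) && mle$converged &&
                all(abs(mle$beta_hat) < C)) mle$beta_hat else rep(0, p)
  }
  if (any(abs(init) > C))
    stop("initial value lies outside the prior box")

  prop_L <- NULL
  if (!is.null(mle)) {
    Sigma <- mle$covariance
    # Under (quasi-)separation the MLE covariance blows up along the
    # runaway coordinate and would freeze every other coordinate once
    # the global scale adapts down. Decouple such coordinates and give
    # them a proposal sd matched to the prior box instead.
    bad <- !is.finite(diag(Sigma)) | sqrt(pmax(diag(Sigma), 0)) > C
    if (any(bad)) {
      Sigma[bad, ] <- 0
      Sigma[, bad] <- 0
      diag(Sigma)[bad] <- (C / 2)^2
    }
    prop_L <- tryCatch(t(chol(Sigma)), error = function(e) NULL)
  }
  if (is.null(prop_L)) prop_L <- diag(0.5, p)   # scaled-identity fallback
  scale0 <- if (identical(config$proposal_scale, "auto"))
    2.38 / sqrt(p) else as.numeric(config$proposal_scale)

  if (!is.null(seed)) set.seed(seed)
  res <- rwm_chain_cpp(X, y, as.numeric(init), prop_L, scale0,
                       config$n_burnin, config$n_draws, C,
                       config$adapt_during_burnin,
                       config$target_acceptance, config$thin)
  if (config$n_burnin > 0 && res$burnin_acceptance_rate == 0)
    stop("Metropolis chain accepted no proposal during burn-in; ",
         "check the model and proposal scale")

  devs <- res$deviances
  thirds <- split(devs, cut(seq_along(devs), 3, labels = FALSE))
  third_means <- vapply(thirds, mean, numeric(1))
  drift <- max(third_means) - min(third_means) > 2

  draws <- res$draws
  colnames(draws) <- colnames(X)
  structure(list(draws = draws, deviances = devs,
                 acceptance_rate = res$acceptance_rate,
                 burnin_acceptance_rate = res$burnin_acceptance_rate,
                 final_scale = res$final_scale,
                 mle = mle, config = config, seed = seed,
                 model_label = model_label,
                 diagnostics = list(deviance_ess = ess(devs),
                                    drift_flag = drift,
                                    third_means = third_means),
                 n = length(y), p = p),
            class = "rwm_logit")
}

#' @export
print.rwm_logit <- function(x, ...) {
  cat(sprintf("Random-walk Metropolis posterior: %s\n", x$model_label))
  cat(sprintf("  %d draws (%d burn-in), %d coefficients, acceptance %.2f\n",
              nrow(x$draws), x$config$n_burnin, x$p, x$acceptance_rate))
  cat(sprintf("  deviance: min %.2f, median %.2f, mean %.2f (ESS %.0f%s)\n",
              min(x$deviances), median(x$deviances), mean(x$deviances),
              x$diagnostics$deviance_ess,
              if (x$diagnostics$drift_flag) ", DRIFT FLAG" else ""))
  invisible(x)
}

#' @export
summary.rwm_logit <- function(object, ...) {
  qs <- t(apply(object$draws, 2, quantile7, probs = c(0.025, 0.5, 0.975)))
  tab <- data.frame(mean = colMeans(object$draws),
                    sd = apply(object$draws, 2, sd),
                    `q2.5` = qs[, 1], median = qs[, 2], `q97.5` = qs[, 3],
                    check.names = FALSE)
  out <- list(coefficients = tab,
              deviance = c(min = min(object$deviances),
                           mean = mean(object$deviances),
                           median = median(object$deviances)),
              mle_deviance = if (!is.null(object$mle)) object$mle$deviance_min else NA_real_,
              acceptance_rate = object$acceptance_rate,
              diagnostics = object$diagnostics,
              model_label = object$model_label)
  class(out) <- "summary.rwm_logit"
  out
}

#' @export
print.summary.rwm_logit <- function(x, ...) {
  cat(sprintf("Posterior summary: %s\n", x$model_label))
  print(round(x$coefficients, 4))
  cat(sprintf("posterior deviance: min %.3f, median %.3f, mean %.3f (MLE %.3f)\n",
              x$deviance["min"], x$deviance["median"], x$deviance["mean"],
              x$mle_deviance))
  invisible(x)
}

#' @export
coef.rwm_logit <- function(object, ...) colMeans(object$draws)

#' @export
vcov.rwm_logit <- function(object, ...) var(object$draws)

#' @export
as.matrix.rwm_logit <- function(x, ...) x$draws

#' Posterior deviance draws
#'
#' For an `rwm_logit` fit the deviance is a posterior distribution, not
#' a number; this method returns the full vector of deviance draws.
#' @param object an `rwm_logit` fit.
#' @param ... unused.
#' @return numeric vector of length `n_draws`.
#' @export
deviance.rwm_logit <- function(object, ...) object$deviances

#' @export
plot.rwm_logit <- function(x, main = NULL, ...) {
  plot(sort(x$deviances), seq_along(x$deviances) / length(x$deviances),
       type = "s", xlab = "deviance", ylab = "posterior CDF",
       main = if (is.null(main)) paste("Posterior deviance:", x$model_label) else main,
       ...)
  if (!is.null(x$mle)) graphics::abline(v = x$mle$deviance_min, lty = 2)
  invisible(x)
}

#' Empirical CDF of the posterior deviance on a grid
#'
#' @param drawset an `rwm_logit` fit (or any list with `deviances`).
#' @param grid numeric vector of deviance values.
#' @return right-continuous empirical CDF values at `grid`.
#' @export
posterior_deviance_cdf <- function(drawset, grid) {
  d <- drawset$deviances
  if (!length(d)) stop("empty draw set")
  vapply(grid, function(g) mean(d <= g), numeric(1))
}
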