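#' Bernoulli log-likelihood of a logistic regression model
#'
#' \eqn{\ell(\beta) = \sum_i y_i \log \pi_i + (1-y_i)\log(1-\pi_i)} with
#' \eqn{\pi_i = \mathrm{logit}^{-1}(x_i'\beta)}, evaluated in the
#' overflow-safe form \eqn{\sum_i y_i \eta_i - \log(1 + e^{\eta_i})}.
#'
#' @param beta coefficient vector (length p, finite).
#' @param X N x p design matrix (or a `design_matrix` object).
#' @param y binary response vector (ignored when `X` carries its own).
#' @return the log-likelihood (scalar, possibly `-Inf` only in exact
#'   degenerate limits).
#' @export
#' @examples
#' X <- cbind(1, c(-1, 0, 1))
#' logit_loglik(c(0, 0), X, c(0, 1, 1)) # = -3 log 2
logit_loglik <- function(beta, X, y = NULL) {
  if (inherits(X, "design_matrix")) { y <- X$y; X <- X$X }
  beta <- as.numeric(beta)
  if (any(!is.finite(beta))) stop("non-finite coefficients")
  if (length(beta) != ncol(X)) stop("length(beta) must equal ncol(X)")
  eta <- drop(X %*% beta)
  sum(y * eta - log1pexp(eta))
}

#' Deviance of a logistic regression model
#'
#' Minus twice the log-likelihood at the given coefficients; the
#' fit-quality scale on which all posterior summaries of this package
#' live (lower = better fit).
#'
#' @inheritParams logit_loglik
#' @return nonnegative scalar `-2 * logit_loglik(beta, X, y)`.
#' @export
logit_deviance <- function(beta, X, y = NULL) {
  -2 * logit_loglik(beta, X, y)
}

#' Maximum-likelihood fit of a logistic regression model
#'
#' Fits by iteratively reweighted least squares (via [stats::glm.fit()]
#' with a tight convergence tolerance), reports the minimised deviance
#' and coefficient covariance, and flags (quasi-)complete separation:
#' either a large coefficient (|beta| > 15) with a non-vanishing score,
#' or fitted probabilities pinned to 0/1 for every carrier of a binary
#' predictor column.
#'
#' @param X N x p numeric design matrix (or a `design_matrix`).
#' @param y binary response.
#' @param max_iter IRLS iteration cap.
#' @return a list of class `logit_mle` with `beta_hat`, `deviance_min`,
#'   `covariance`, `converged`, `separation_detected`, `gradient_norm`.
#' @export
#' @examples
#' fit <- fit_logit_mle(matrix(1, 10, 1), c(rep(1, 3), rep(0, 7)))
#' fit$beta_hat           # log(3/7)
#' fit$deviance_min
fit_logit_mle <- function(X, y = NULL, max_iter = 100L) {
  if (inherits(X, "design_matrix")) { y <- X$y; X <- X$X }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = list(epsilon = 1e-12, maxit = max_iter))
  )
  beta <- fit$coefficients
  mu <- fit$fitted.values
  grad <- drop(crossprod(X, y - mu))
  gnorm <- sqrt(sum(grad^2))
  converged <- fit$converged && gnorm < 1e-6
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  covariance <- tryCatch(chol2inv(chol(info)), error = function(e) {
    MASS_ginv(info)
  })
  dimnames(covariance) <- list(colnames(X), colnames(X))
  sep <- (!converged && max(abs(beta)) > 15)
  if (!sep) {
    # binary columns whose carriers all have pinned fitted probabilities
    for (j in seq_len(ncol(X))) {
      xj <- X[, j]
      if (all(xj %in% c(0, 1)) && any(xj == 1) && !all(xj == 1)) {
        muj <- mu[xj == 1]
        if (all(muj < 1e-8) || all(muj > 1 - 1e-8)) { sep <- TRUE; break }
      }
    }
  }
  structure(list(beta_hat = setNames(beta, colnames(X)),
                 deviance_min = -2 * logit_loglik(beta, X, y),
                 covariance = covariance,
                 converged = converged,
                 separation_detected = sep,
                 gradient_norm = gnorm,
                 n = length(y), p = ncol(X)),
            class = "logit_mle")
}

# Moore-Penrose fallback for a (near-)singular information matrix
MASS_ginv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' @export
print.logit_mle <- function(x, ...) {
  cat(sprintf("Logistic regression MLE (n = %d, p = %d)\n", x$n, x$p))
  print(round(x$beta_hat, 4))
  cat(sprintf("deviance: %.4f  converged: %s  separation: %s\n",
              x$deviance_min, x$converged, x$separation_detected))
  invisible(x)
}

#' @export
coef.logit_mle <- function(object, ...) object$beta_hat

#' @export
vcov.logit_mle <- function(object, ...) object$covariance

#' P-value for the genetic effect from standard logistic regression
#'
#' The comparator evidence measure: a two-sided test of the genetic
#' coefficient in the factor model (model 2) against the baseline model
#' (model 1) nested within it.
#'
#' @param fit2 `logit_mle` for the model including the genetic factor.
#' @param fit1 `logit_mle` for the baseline model (one fewer column).
#' @param method `"wald"` (default): normal test of the genetic
#'   coefficient over its standard error; `"lrt"`: chi-square(1) upper
#'   tail of the deviance drop `fit1$deviance_min - fit2$deviance_min`.
#' @param genetic_column index of the genetic coefficient in `fit2`
#'   (default: the last column).
#' @return list with `p_value` in `[0, 1]`, `method`, and `unreliable`
#'   (`TRUE` when separation was detected in the factor model).
#' @export
association_pvalue <- function(fit2, fit1, method = c("wald", "lrt"),
                               genetic_column = fit2$p) {
  method <- match.arg(method)
  if (fit2$p != fit1$p + 1L)
    stop("fit1 must be nested in fit2 with exactly one fewer column")
  if (method == "wald") {
    b <- fit2$beta_hat[genetic_column]
    se <- sqrt(fit2$covariance[genetic_column, genetic_column])
    p <- if (se == 0 && b == 0) 1 else 2 * pnorm(-abs(b / se))
  } else {
    drop <- max(0, fit1$deviance_min - fit2$deviance_min)
    p <- pchisq(drop, df = 1, lower.tail = FALSE)
  }
  list(p_value = min(1, max(0, p)), method = method,
       unreliable = isTRUE(fit2$separation_detected))
}
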