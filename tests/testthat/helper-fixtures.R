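# Shared fixtures: everything is generated in code at test time.

# small cohort for fast design/evidence tests
tiny_cohort <- function(seed = 3, n = 150, ...) {
  simulate_cohort(cohort_config(n_individuals = n, ...), seed = seed)
}

# hand-built minimal cohort with full control over covariates
manual_cohort <- function(age, smoker, ethnicity, genotypes, y,
                          variants = NULL) {
  if (is.null(variants))
    variants <- variant_panel(colnames(genotypes),
                              maf = pmin(colMeans(genotypes) / 2, 0.5),
                              q1_effect = 0)
  structure(list(replicate_id = 1L, genotypes = genotypes, age = age,
                 smoker = smoker, ethnicity = factor(ethnicity),
                 q1 = numeric(length(y)), q2 = numeric(length(y)),
                 liability = numeric(length(y)), y = y,
                 intercept = NA_real_, variants = variants),
            class = "cohort_replicate")
}

# intercept-only fixture with 3 successes of 10: flat prior on the logit
# implies a Beta(3, 7) posterior on the success probability
three_of_ten <- function() {
  list(X = matrix(1, 10, 1), y = c(rep(1, 3), rep(0, 7)))
}

# two-coefficient logistic toy (n = 30), small enough for quadrature
toy_2par <- function(seed = 30) {
  set.seed(seed)
  x <- rnorm(30)
  y <- rbinom(30, 1, plogis(0.3 + 0.8 * x))
  list(X = cbind(1, x), y = y)
}

# simulated logistic data with known coefficients
known_logistic <- function(n, beta, seed) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (length(beta) - 1)), n))
  colnames(X) <- c("intercept", paste0("x", seq_len(length(beta) - 1)))
  list(X = X, y = rbinom(n, 1, plogis(drop(X %*% beta))), beta = beta)
}

fast_sampler <- function(n_draws = 500L, n_burnin = 300L, ...) {
  sampler_config(n_draws = n_draws, n_burnin = n_burnin, ...)
}

# exact two-sided rank-sum p-value by enumeration of all group
# assignments (no ties assumed); independent of stats::wilcox.test
enumerate_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r_obs <- sum(rank(pooled)[seq_len(n1)])
  idx <- utils::combn(length(pooled), n1)
  r_all <- apply(idx, 2, function(i) sum(rank(pooled)[i]))
  ew <- n1 * (length(pooled) + 1) / 2
  mean(abs(r_all - ew) >= abs(r_obs - ew) - 1e-12)
}

# exact unconditional two-sample proportion test: enumerate both
# binomials under the pooled null, order by |difference in proportions|
enumerate_prop_p <- function(k1, k2, n) {
  phat <- (k1 + k2) / (2 * n)
  pa <- dbinom(0:n, n, phat)
  D <- abs(outer(0:n, 0:n, "-")) / n
  sum(outer(pa, pa)[D >= abs(k1 - k2) / n - 1e-12])
}
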