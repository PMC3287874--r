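test_that("baseline design matrix has the canonical seven columns", {
  g <- matrix(0L, 3, 1, dimnames = list(NULL, "v"))
  coh <- manual_cohort(age = c(30, 40, 50), smoker = c(0, 1, 0),
                       ethnicity = c("eth1", "eth2", "eth3"),
                       genotypes = g, y = c(0, 1, 0))
  d <- build_design_matrix(coh)
  expect_equal(dim(d$X), c(3L, 7L))
  expect_true(all(d$X[, 1] == 1))
  expect_identical(d$column_names,
                   c("intercept", "age", "smoker", "eth2", "eth3", "eth4", "eth5"))
  expect_true(is.na(d$genetic_column))
})

test_that("reference-level coding zeroes all dummies for the first ethnicity", {
  g <- matrix(0L, 4, 1, dimnames = list(NULL, "v"))
  coh <- manual_cohort(age = c(30, 40, 50, 60), smoker = c(0, 1, 0, 1),
                       ethnicity = rep("eth1", 4), genotypes = g,
                       y = c(0, 1, 0, 1))
  d <- build_design_matrix(coh)
  expect_true(all(d$X[, 4:7] == 0))
})

test_that("factor codings produce the documented explanatory columns", {
  k <- kdr_variants()
  g <- matrix(0L, 5, 16, dimnames = list(NULL, k$name))
  g[1, 7] <- 1L; g[2, 7] <- 2L   # rare variant carriers
  g[3, 8] <- 2L                  # common variant v08 (MAF 16.5%)
  g[4, 11] <- 1L                 # common variant v11 (MAF 2.08%)
  coh <- manual_cohort(age = 40 + 1:5, smoker = c(0, 1, 0, 1, 0),
                       ethnicity = paste0("eth", c(1, 2, 3, 4, 5)),
                       genotypes = g, y = c(1, 1, 0, 0, 1), variants = k)
  expect_equal(factor_column(coh, genetic_factor("additive", "v07")),
               c(1, 2, 0, 0, 0))
  expect_equal(factor_column(coh, genetic_factor("collapsed", "v07")),
               c(1, 1, 0, 0, 0))
  # any-rare ignores the two common variants
  expect_equal(factor_column(coh, genetic_factor("any_rare")),
               c(1, 1, 0, 0, 0))
  expect_error(factor_column(coh, genetic_factor("additive", "nope")),
               "unknown variant")
  expect_error(factor_column(coh, genetic_factor("additive", 17)),
               "out of range")
})

test_that("log-likelihood matches direct Bernoulli summation and is stable", {
  expect_equal(logit_loglik(c(0, 0), cbind(1, c(-1, 0, 1)), c(0, 1, 1)),
               -3 * log(2))
  set.seed(20)
  X <- cbind(1, rnorm(5), rnorm(5))
  y <- c(1, 0, 1, 1, 0)
  beta <- c(0.3, -1.2, 0.7)
  pi <- plogis(drop(X %*% beta))
  oracle <- sum(dbinom(y, 1, pi, log = TRUE))
  expect_equal(logit_loglik(beta, X, y), oracle, tolerance = 1e-12)
  # definitional identity and stability at extreme linear predictors
  expect_equal(logit_deviance(beta, X, y), -2 * logit_loglik(beta, X, y))
  big <- logit_loglik(700, matrix(1, 2, 1), c(1, 0))
  expect_true(is.finite(big))
  expect_equal(big, -700)               # y=1 contributes ~0, y=0 contributes -700
  expect_equal(logit_deviance(c(0, 0, 0), X[1:2, ], y[1:2]), 4 * log(2))
  expect_error(logit_loglik(c(NA, 0, 0), X, y), "finite")
})

test_that("intercept-only MLE has its closed form", {
  f <- fit_logit_mle(matrix(1, 10, 1), c(rep(1, 3), rep(0, 7)))
  expect_equal(unname(f$beta_hat), log(3 / 7), tolerance = 1e-8)
  expect_equal(f$deviance_min, -2 * (3 * log(0.3) + 7 * log(0.7)),
               tolerance = 1e-8)
  expect_true(f$converged)
  expect_false(f$separation_detected)
})

test_that("MLE agrees with an independent numerical optimiser", {
  set.seed(21)
  X <- cbind(1, matrix(rnorm(200 * 3), 200, 3))
  y <- rbinom(200, 1, plogis(drop(X %*% c(-0.3, 0.8, -0.5, 0.2))))
  f <- fit_logit_mle(X, y)
  opt <- optim(rep(0, 4), function(b) -logit_loglik(b, X, y),
               gr = function(b) -drop(crossprod(X, y - plogis(drop(X %*% b)))),
               method = "BFGS", control = list(reltol = 1e-15, maxit = 500))
  expect_true(max(abs(f$beta_hat - opt$par)) < 1e-6)
  expect_equal(f$deviance_min, 2 * opt$value, tolerance = 1e-9)
  # local optimality along random directions
  set.seed(22)
  for (i in 1:5) {
    dir <- rnorm(4)
    expect_gte(logit_deviance(f$beta_hat + 0.05 * dir, X, y), f$deviance_min)
  }
  # covariance is symmetric positive definite
  expect_equal(f$covariance, t(f$covariance), tolerance = 1e-10)
  expect_true(all(eigen(f$covariance, symmetric = TRUE)$values > 0))
})

test_that("perfect binary predictor is flagged as separation", {
  x <- c(rep(1, 5), rep(0, 5))
  y <- x
  f <- fit_logit_mle(cbind(1, genetic = x), y)
  expect_true(f$separation_detected)
})

test_that("rank-deficient designs are rejected with the offending column", {
  set.seed(23)
  a <- rnorm(20)
  X <- cbind(intercept = 1, a = a, dup = a)
  expect_error(fit_logit_mle(X, rbinom(20, 1, 0.5)), "dup")
})

test_that("affine rescaling of a covariate leaves the fit invariant", {
  coh <- tiny_cohort(seed = 24, n = 250)
  d <- build_design_matrix(coh, genetic_factor("any_rare"))
  f <- fit_logit_mle(d)
  d2 <- d
  d2$X[, "age"] <- (d$X[, "age"] - 45) / 10
  f2 <- fit_logit_mle(d2$X, d2$y)
  expect_equal(f2$deviance_min, f$deviance_min, tolerance = 1e-8)
  expect_equal(unname(f2$beta_hat["age"]), unname(f$beta_hat["age"] * 10),
               tolerance = 1e-6)
  d1 <- build_design_matrix(coh)
  f1 <- fit_logit_mle(d1)
  d1b <- d1; d1b$X[, "age"] <- (d1$X[, "age"] - 45) / 10
  f1b <- fit_logit_mle(d1b$X, d1b$y)
  for (m in c("wald", "lrt"))
    expect_equal(association_pvalue(f2, f1b, m)$p_value,
                 association_pvalue(f, f1, m)$p_value, tolerance = 1e-8)
})

test_that("association p-values follow their definitions", {
  # engineered fits exercising the formulas directly
  fit1 <- structure(list(p = 2L, deviance_min = 100), class = "logit_mle")
  fit2 <- structure(list(p = 3L, deviance_min = 100 - qchisq(0.95, 1),
                         beta_hat = c(0, 0, 0.5), covariance = diag(3) * 0.25,
                         separation_detected = FALSE), class = "logit_mle")
  expect_equal(association_pvalue(fit2, fit1, "lrt")$p_value, 0.05,
               tolerance = 1e-10)
  expect_equal(association_pvalue(fit2, fit1, "wald")$p_value,
               2 * pnorm(-1), tolerance = 1e-10)
  fit2b <- fit2; fit2b$beta_hat[3] <- 0
  expect_equal(association_pvalue(fit2b, fit1, "wald")$p_value, 1)
  expect_error(association_pvalue(fit2, fit2, "wald"), "nested")
  fit2c <- fit2; fit2c$separation_detected <- TRUE
  expect_true(association_pvalue(fit2c, fit1, "wald")$unreliable)
})

test_that("null p-values are approximately uniform", {
  set.seed(25)
  n_rep <- 400
  hits <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    x <- rnorm(300)
    y <- rbinom(300, 1, 0.4)                  # y independent of x
    f2 <- fit_logit_mle(cbind(1, x = x), y)
    f1 <- fit_logit_mle(matrix(1, 300, 1), y)
    hits[r] <- association_pvalue(f2, f1, "lrt")$p_value < 0.1
  }
  expect_true(abs(mean(hits) - 0.10) < 0.045)
})
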