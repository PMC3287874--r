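#' Configuration of the synthetic cohort generating model
#'
#' Describes one generating model for a case-control cohort in the style
#' of a mini-exome association study: genotypes are independent
#' Hardy-Weinberg draws from a [variant_panel()]; minor alleles act
#' additively on a quantitative risk factor Q1, with effects inflated in
#' smokers by `smoker_multiplier`; a second quantitative factor Q2 is
#' correlated with Q1; a latent liability trait increases with age and
#' smoking; and disease status is Bernoulli with log-odds linear in Q1,
#' Q2 and liability, the intercept being calibrated by bisection so the
#' expected prevalence matches `target_prevalence`.
#'
#' All distributional parameters are explicit assumptions of the
#' generator, not estimates from any real cohort; defaults give a common
#' disease (prevalence 0.30) in which the strongest rare variants of the
#' default panel are detectable but far from saturated at N = 697.
#'
#' @param n_individuals cohort size (default 697).
#' @param variants a [variant_panel()]; default [kdr_variants()].
#' @param smoker_multiplier multiplier on per-allele Q1 effects in
#'   smokers; the default 1.5 encodes effects 50% higher in smokers.
#' @param smoking_prevalence probability of being a smoker (default 0.3).
#' @param ethnicity_probs probabilities of the five ethnicity categories;
#'   must be nonnegative and sum to 1 (default uniform).
#' @param age_mean,age_sd,age_range parameters of the truncated-normal
#'   age distribution in years (default mean 45, sd 12, range 18-90).
#' @param q1_noise_sd standard deviation of the non-genetic part of Q1.
#' @param q2_correlation target correlation between Q1 and Q2.
#' @param liability_age,liability_smoking,liability_sd liability trait:
#'   coefficient on standardised age, additive smoking effect, and
#'   residual standard deviation.
#' @param disease_q1,disease_q2,disease_liability log-odds coefficients
#'   of Q1, Q2 and liability in the disease model.
#' @param target_prevalence expected disease prevalence in (0, 1).
#' @param ensure_polymorphic if `TRUE`, genotype columns with zero
#'   carriers are redrawn a bounded number of times (see
#'   [simulate_genotypes()]); default `FALSE`, leaving the marginal MAF
#'   distribution untouched.
#' @param redraw_genotypes if `TRUE` (default) each replicate redraws its
#'   genotype matrix; if `FALSE`, genotypes are generated once and held
#'   fixed across replicates.
#' @return a list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_individuals = 200)
#' cfg$target_prevalence
cohort_config <- function(n_individuals = 697L,
                          variants = kdr_variants(),
                          smoker_multiplier = 1.5,
                          smoking_prevalence = 0.3,
                          ethnicity_probs = rep(0.2, 5),
                          age_mean = 45, age_sd = 12,
                          age_range = c(18, 90),
                          q1_noise_sd = 1,
                          q2_correlation = 0.7,
                          liability_age = 0.5,
                          liability_smoking = 0.5,
                          liability_sd = 1,
                          disease_q1 = 2.0,
                          disease_q2 = 0.3,
                          disease_liability = 0.5,
                          target_prevalence = 0.30,
                          ensure_polymorphic = FALSE,
                          redraw_genotypes = TRUE) {
  if (!inherits(variants, "variant_panel"))
    variants <- variant_panel(variants$name, variants$maf, variants$q1_effect)
  num <- c(smoker_multiplier, smoking_prevalence, age_mean, age_sd,
           age_range, q1_noise_sd, q2_correlation, liability_age,
           liability_smoking, liability_sd, disease_q1, disease_q2,
           disease_liability, target_prevalence)
  if (any(!is.finite(num)))
    stop("all numeric configuration values must be finite")
  if (length(ethnicity_probs) != 5L || any(ethnicity_probs < 0) ||
      abs(sum(ethnicity_probs) - 1) > 1e-12)
    stop("ethnicity_probs must be 5 nonnegative values summing to 1")
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop("target_prevalence must lie strictly in (0, 1)")
  if (smoking_prevalence < 0 || smoking_prevalence > 1)
    stop("smoking_prevalence must lie in [0, 1]")
  if (abs(q2_correlation) > 1)
    stop("q2_correlation must lie in [-1, 1]")
  if (n_individuals < 1)
    stop("n_individuals must be at least 1")
  structure(list(
    n_individuals = as.integer(n_individuals),
    variants = variants,
    smoker_multiplier = smoker_multiplier,
    smoking_prevalence = smoking_prevalence,
    ethnicity_probs = ethnicity_probs,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    q1_noise_sd = q1_noise_sd,
    q2_correlation = q2_correlation,
    liability_age = liability_age,
    liability_smoking = liability_smoking,
    liability_sd = liability_sd,
    disease_q1 = disease_q1, disease_q2 = disease_q2,
    disease_liability = disease_liability,
    target_prevalence = target_prevalence,
    ensure_polymorphic = ensure_polymorphic,
    redraw_genotypes = redraw_genotypes
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  individuals: %d, variants: %d (%d rare)\n",
              x$n_individuals, nrow(x$variants), sum(x$variants$is_rare)))
  cat(sprintf("  target prevalence: %.2f, smoking: %.2f, smoker effect multiplier: %.2f\n",
              x$target_prevalence, x$smoking_prevalence, x$smoker_multiplier))
  cat(sprintf("  disease log-odds coefficients: Q1 %.2f, Q2 %.2f, liability %.2f\n",
              x$disease_q1, x$disease_q2, x$disease_liability))
  invisible(x)
}

#' Simulate a genotype matrix under Hardy-Weinberg equilibrium
#'
#' Minor-allele counts are drawn independently per individual and variant
#' as Binomial(2, maf). Linkage disequilibrium and relatedness are
#' deliberately not modelled: the downstream analysis treats individuals
#' as unrelated and factors one variant at a time.
#'
#' @param variants a [variant_panel()].
#' @param n number of individuals.
#' @param seed optional integer seed; if `NULL`, the current RNG stream
#'   is used.
#' @param ensure_polymorphic redraw columns with zero carriers (up to
#'   `max_retries` times; still-monomorphic columns are kept with a
#'   warning).
#' @param max_retries retry bound per variant when `ensure_polymorphic`.
#' @return integer matrix (n x variants) of minor-allele counts in
#'   `{0, 1, 2}` with variant names as column names.
#' @export
#' @examples
#' g <- simulate_genotypes(kdr_variants(), n = 100, seed = 1)
#' dim(g)
simulate_genotypes <- function(variants, n, seed = NULL,
                               ensure_polymorphic = FALSE,
                               max_retries = 50L) {
  stopifnot(n >= 1)
  if (any(variants$maf < 0 | variants$maf > 0.5))
    stop("minor allele frequencies must lie in [0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  v <- nrow(variants)
  g <- matrix(0L, nrow = n, ncol = v,
              dimnames = list(NULL, variants$name))
  for (j in seq_len(v))
    g[, j] <- rbinom(n, 2L, variants$maf[j])
  if (ensure_polymorphic) {
    for (j in seq_len(v)) {
      tries <- 0L
      while (variants$maf[j] > 0 && sum(g[, j]) == 0L && tries < max_retries) {
        g[, j] <- rbinom(n, 2L, variants$maf[j])
        tries <- tries + 1L
      }
      if (variants$maf[j] > 0 && sum(g[, j]) == 0L)
        warning(sprintf("variant %s monomorphic after %d redraws",
                        variants$name[j], max_retries))
    }
  }
  g
}

# truncated-normal draws by inverse-CDF on the truncated range
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# calibrate the disease-model intercept so that mean(plogis(g0 + lp))
# equals the target prevalence, by bisection on [-50, 50]
calibrate_intercept <- function(lp, target, tol = 1e-4) {
  f <- function(g0) mean(plogis(g0 + lp)) - target
  lo <- -50; hi <- 50
  if (f(lo) > 0 || f(hi) < 0)
    stop("target prevalence unreachable: linear predictor too extreme")
  mid <- (lo + hi) / 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol * 0.1) break
    if (fm > 0) hi <- mid else lo <- mid
  }
  if (abs(f(mid)) > tol)
    stop("intercept bisection failed to reach the target prevalence")
  mid
}

#' Simulate phenotypes and disease status for a genotype matrix
#'
#' Generates age, smoking and ethnicity covariates, the quantitative risk
#' factors Q1 and Q2, the latent liability trait, and Bernoulli disease
#' status, following the generating model described in [cohort_config()]:
#' \deqn{Q1_i = \sum_v \beta_v g_{iv} (1 + (m-1) s_i) + \epsilon_i,}
#' Q2 standardised-jointly-normal with Q1 at the configured correlation,
#' liability = a(standardised age) + b(smoker) + residual, and
#' \eqn{y_i \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1}(\gamma_0 +
#' \gamma_1 Q1_i + \gamma_2 Q2_i + \gamma_3 L_i))} with \eqn{\gamma_0}
#' tuned so the expected prevalence matches the target.
#'
#' @param genotypes matrix from [simulate_genotypes()], with one column
#'   per variant of `config$variants`.
#' @param config a [cohort_config()].
#' @param seed optional integer seed.
#' @param replicate_id integer label stored on the result.
#' @return a list of class `cohort_replicate` with elements `genotypes`,
#'   `age`, `smoker`, `ethnicity`, `q1`, `q2`, `liability`, `y`,
#'   `intercept` (the calibrated \eqn{\gamma_0}) and `variants`.
#' @export
simulate_phenotypes <- function(genotypes, config, seed = NULL,
                                replicate_id = 1L) {
  if (ncol(genotypes) != nrow(config$variants))
    stop("genotype matrix does not match config$variants")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes)
  age <- rnorm_trunc(n, config$age_mean, config$age_sd,
                     config$age_range[1], config$age_range[2])
  smoker <- rbinom(n, 1L, config$smoking_prevalence)
  ethnicity <- factor(sample.int(5L, n, replace = TRUE,
                                 prob = config$ethnicity_probs),
                      levels = 1:5,
                      labels = paste0("eth", 1:5))
  genetic <- as.numeric(genotypes %*% config$variants$q1_effect)
  q1 <- genetic * (1 + (config$smoker_multiplier - 1) * smoker) +
    rnorm(n, 0, config$q1_noise_sd)
  s1 <- sd(q1)
  z1 <- if (s1 > 0) (q1 - mean(q1)) / s1 else rep(0, n)
  rho <- config$q2_correlation
  q2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  zage <- (age - mean(age)) / sd(age)
  liability <- config$liability_age * zage +
    config$liability_smoking * smoker +
    rnorm(n, 0, config$liability_sd)
  lp <- config$disease_q1 * q1 + config$disease_q2 * q2 +
    config$disease_liability * liability
  g0 <- calibrate_intercept(lp, config$target_prevalence)
  y <- rbinom(n, 1L, plogis(g0 + lp))
  structure(list(
    replicate_id = as.integer(replicate_id),
    genotypes = genotypes,
    age = age, smoker = smoker, ethnicity = ethnicity,
    q1 = q1, q2 = q2, liability = liability,
    y = y, intercept = g0,
    variants = config$variants
  ), class = "cohort_replicate")
}

#' Simulate one complete cohort replicate
#'
#' Convenience wrapper drawing genotypes and phenotypes from a single
#' seeded stream.
#'
#' @inheritParams simulate_phenotypes
#' @param config a [cohort_config()].
#' @param seed optional integer seed.
#' @param genotypes optional pre-drawn genotype matrix (used when
#'   genotypes are held fixed across replicates).
#' @return a `cohort_replicate`.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(n_individuals = 150), seed = 7)
#' mean(coh$y)
simulate_cohort <- function(config, seed = NULL, replicate_id = 1L,
                            genotypes = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genotypes))
    genotypes <- simulate_genotypes(config$variants, config$n_individuals,
                                    ensure_polymorphic = config$ensure_polymorphic)
  simulate_phenotypes(genotypes, config, replicate_id = replicate_id)
}

#' Generate a sequence of independent cohort replicates
#'
#' Each replicate gets its own sub-seed derived from the master seed by a
#' counter-based scheme ([derive_seed()]), so replicate r is reproducible
#' in isolation and the set is deterministic for a fixed master seed.
#' With `config$redraw_genotypes = FALSE` the genotype matrix is drawn
#' once (stream 0) and shared by all replicates.
#'
#' @param config a [cohort_config()].
#' @param n_replicates number of replicates (>= 1).
#' @param seed master integer seed.
#' @return a list of `cohort_replicate` objects.
#' @export
#' @examples
#' reps <- generate_replicates(cohort_config(n_individuals = 100), 3, seed = 1)
#' length(reps)
generate_replicates <- function(config, n_replicates, seed) {
  stopifnot(n_replicates >= 1)
  fixed_g <- NULL
  if (!config$redraw_genotypes) {
    set.seed(derive_seed(seed, 0L))
    fixed_g <- simulate_genotypes(config$variants, config$n_individuals,
                                  ensure_polymorphic = config$ensure_polymorphic)
  }
  lapply(seq_len(n_replicates), function(r) {
    simulate_cohort(config, seed = derive_seed(seed, r),
                    replicate_id = r, genotypes = fixed_g)
  })
}

#' @export
print.cohort_replicate <- function(x, ...) {
  n <- length(x$y)
  cat(sprintf("Cohort replicate %d: %d individuals, %d variants\n",
              x$replicate_id, n, ncol(x$genotypes)))
  cat(sprintf("  cases: %d (%.1f%%), smokers: %.1f%%, rare-variant carriers: %d\n",
              sum(x$y), 100 * mean(x$y), 100 * mean(x$smoker),
              sum(rowSums(x$genotypes[, x$variants$is_rare, drop = FALSE]) > 0)))
  invisible(x)
}

#' @export
summary.cohort_replicate <- function(object, ...) {
  carriers <- colSums(object$genotypes > 0)
  data.frame(variant = object$variants$name,
             maf_spec = object$variants$maf,
             maf_obs = colMeans(object$genotypes) / 2,
             carriers = carriers,
             q1_effect = object$variants$q1_effect,
             row.names = NULL)
}
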