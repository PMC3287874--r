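test_that("variant panel validates its fields and flags rare variants", {
  v <- variant_panel(c("a", "b"), maf = c(0.005, 0.2), q1_effect = c(1, 0))
  expect_equal(v$is_rare, c(TRUE, FALSE))
  expect_error(variant_panel("a", maf = 0.7), "\\[0, 0.5\\]")
  expect_error(variant_panel("a", maf = 0.1, q1_effect = Inf), "finite")
  expect_error(variant_panel(c("a", "a"), maf = c(0.1, 0.1)), "unique")
  k <- kdr_variants()
  expect_equal(nrow(k), 16L)
  expect_equal(sum(k$is_rare), 14L)            # v08 (16.5%) and v11 (2.08%) are common
  expect_equal(sum(k$q1_effect > 0), 10L)
  expect_equal(k$q1_effect[c(7, 13)], c(1.08, 0.94))
})

test_that("genotypes are Hardy-Weinberg binomial draws with the right mean", {
  zero <- variant_panel(c("z1", "z2"), maf = c(0, 0))
  expect_true(all(simulate_genotypes(zero, 50, seed = 1) == 0L))

  half <- variant_panel("h", maf = 0.5)
  g <- simulate_genotypes(half, 10000, seed = 2)
  expect_true(abs(mean(g) - 1) < 0.03)         # Binomial(2, 0.5) mean
  expect_true(all(g %in% 0:2))

  expect_error(simulate_genotypes(data.frame(name = "x", maf = 0.9,
                                             q1_effect = 0), 10),
               "\\[0, 0.5\\]")
})

test_that("rare-carrier fraction matches the independence closed form", {
  k <- kdr_variants()
  rare_maf <- k$maf[k$is_rare]
  p_carrier <- 1 - prod((1 - rare_maf)^2)       # P(>= 1 rare allele)
  expect_true(abs(p_carrier - 0.028) < 0.002)
  g <- simulate_genotypes(k, 50000, seed = 4)
  frac <- mean(rowSums(g[, k$is_rare]) > 0)
  mc_sd <- sqrt(p_carrier * (1 - p_carrier) / 50000)
  expect_true(abs(frac - p_carrier) < 4 * mc_sd)
})

test_that("ensure_polymorphic redraws empty columns deterministically", {
  v <- variant_panel("r", maf = 0.002)
  g <- simulate_genotypes(v, 200, seed = 5, ensure_polymorphic = TRUE)
  expect_gte(sum(g), 1L)
  g2 <- simulate_genotypes(v, 200, seed = 5, ensure_polymorphic = TRUE)
  expect_identical(g, g2)
})

test_that("cohort configuration rejects invalid settings", {
  expect_error(cohort_config(ethnicity_probs = c(0.5, 0.5)), "5 nonnegative")
  expect_error(cohort_config(ethnicity_probs = c(0.3, 0.3, 0.2, 0.1, 0.2)),
               "summing to 1")
  expect_error(cohort_config(target_prevalence = 1.2), "\\(0, 1\\)")
  expect_error(cohort_config(disease_q1 = NaN), "finite")
  expect_error(cohort_config(q2_correlation = 1.5), "\\[-1, 1\\]")
})

test_that("degenerate null gives a fair coin and calibration hits the target", {
  null_cfg <- cohort_config(variants = variant_panel("v", 0.1, 0),
                            disease_q1 = 0, disease_q2 = 0,
                            disease_liability = 0, target_prevalence = 0.5)
  coh <- simulate_cohort(null_cfg, seed = 6)
  expect_true(abs(mean(coh$y) - 0.5) < 0.06)    # N = 697 binomial noise
  expect_true(abs(plogis(coh$intercept) - 0.5) < 1e-3)

  # default config: expected prevalence (given covariates) at the target
  cfg <- cohort_config()
  coh2 <- simulate_cohort(cfg, seed = 7)
  lp <- cfg$disease_q1 * coh2$q1 + cfg$disease_q2 * coh2$q2 +
    cfg$disease_liability * coh2$liability
  expect_true(abs(mean(plogis(coh2$intercept + lp)) - 0.3) < 1e-3)

  # observed prevalence across replicates concentrates on the target
  reps <- generate_replicates(cfg, 30, seed = 8)
  prev <- mean(vapply(reps, function(r) mean(r$y), numeric(1)))
  mc_sd <- sqrt(0.3 * 0.7 / (30 * 697))
  expect_true(abs(prev - 0.3) < 3 * mc_sd + 0.005)
})

test_that("smoker effects on Q1 are 50% higher than nonsmoker effects", {
  v <- variant_panel("c", maf = 0.3, q1_effect = 1)
  cfg <- cohort_config(n_individuals = 50000, variants = v,
                       smoker_multiplier = 1.5)
  coh <- simulate_cohort(cfg, seed = 9)
  het <- coh$genotypes[, 1] == 1
  m_smoke <- mean(coh$q1[het & coh$smoker == 1])
  m_non <- mean(coh$q1[het & coh$smoker == 0])
  # nonsmoker heterozygote genetic term is 1; smokers add 50% of it
  expect_true(abs(m_non - 1) < 0.05)
  expect_true(abs(m_smoke - m_non - 0.5 * 1) < 0.07)
})

test_that("Q1-Q2 correlation matches its configured value", {
  cfg <- cohort_config(n_individuals = 50000, q2_correlation = 0.7)
  coh <- simulate_cohort(cfg, seed = 10)
  expect_true(abs(cor(coh$q1, coh$q2) - 0.7) < 0.02)
})

test_that("allele-frequency estimation is unbiased across replicates", {
  v <- variant_panel(c("r1", "c1"), maf = c(0.005, 0.2))
  cfg <- cohort_config(n_individuals = 300, variants = v,
                       disease_q1 = 0, disease_q2 = 0, disease_liability = 0)
  reps <- generate_replicates(cfg, 200, seed = 12)
  mafs <- rowMeans(vapply(reps, function(r) colMeans(r$genotypes) / 2,
                          numeric(2)))
  se <- sqrt(v$maf * (1 - v$maf) / (2 * 300 * 200))
  expect_true(all(abs(mafs - v$maf) < 3 * se + 1e-4))
})

test_that("replicate generation is deterministic and seed-sensitive", {
  cfg <- cohort_config(n_individuals = 120)
  a <- generate_replicates(cfg, 3, seed = 42)
  b <- generate_replicates(cfg, 3, seed = 42)
  expect_identical(a, b)
  c <- generate_replicates(cfg, 3, seed = 43)
  expect_false(identical(a[[1]]$y, c[[1]]$y))
  # replicates within a set differ from each other
  expect_false(identical(a[[1]]$y, a[[2]]$y))
  # cohort size flows through
  expect_true(all(vapply(a, function(r) length(r$y), integer(1)) == 120L))
})

test_that("fixed-genotype mode shares one genotype matrix across replicates", {
  cfg <- cohort_config(n_individuals = 100, redraw_genotypes = FALSE)
  reps <- generate_replicates(cfg, 3, seed = 13)
  expect_identical(reps[[1]]$genotypes, reps[[2]]$genotypes)
  expect_false(identical(reps[[1]]$y, reps[[2]]$y))
  cfg2 <- cohort_config(n_individuals = 100)
  reps2 <- generate_replicates(cfg2, 2, seed = 13)
  expect_false(identical(reps2[[1]]$genotypes, reps2[[2]]$genotypes))
})

test_that("cohort TSV round trip preserves the analysis inputs", {
  coh <- tiny_cohort(seed = 14)
  prefix <- file.path(withr::local_tempdir(), "rep1")
  write_cohort(coh, prefix)
  back <- read_cohort(paste0(prefix, "_genotypes.tsv"),
                      paste0(prefix, "_covariates.tsv"),
                      variants = coh$variants)
  expect_identical(back$genotypes, coh$genotypes)
  expect_identical(back$y, as.integer(coh$y))
  expect_equal(back$age, coh$age, tolerance = 1e-8)
  expect_identical(as.character(back$ethnicity), as.character(coh$ethnicity))
  # analysis gives identical results on the round-tripped cohort
  d0 <- build_design_matrix(coh, genetic_factor("any_rare"))
  d1 <- build_design_matrix(back, genetic_factor("any_rare"))
  expect_equal(fit_logit_mle(d1)$beta_hat, fit_logit_mle(d0)$beta_hat,
               tolerance = 1e-8)
})

test_that("derived sub-seeds are valid and collision-free over streams", {
  seeds <- vapply(0:500, function(s) derive_seed(123, s), integer(1))
  expect_true(all(seeds >= 1 & seeds < 2^31 - 1))
  expect_false(anyDuplicated(seeds) > 0)
  expect_identical(derive_seed(123, 7), derive_seed(123, 7))
  expect_false(derive_seed(123, 7) == derive_seed(124, 7))
})
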