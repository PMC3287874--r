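#' Power of an evidence measure at a rejection threshold
#'
#' Fraction of replicate statistics strictly below the threshold. The
#' strict inequality matches the "< t" rejection convention used for
#' both evidence measures throughout the package.
#'
#' @param stat_values numeric vector of per-replicate statistics in
#'   `[0, 1]` (p-values or proportions of positive deviance differences).
#' @param threshold rejection threshold.
#' @return fraction in `[0, 1]`.
#' @export
#' @examples
#' power_at_threshold(c(0.005, 0.05, 0.2), 0.01)  # 1/3
power_at_threshold <- function(stat_values, threshold) {
  if (!length(stat_values)) stop("empty statistic vector")
  if (any(stat_values < 0 | stat_values > 1, na.rm = TRUE))
    stop("statistics must lie in [0, 1]")
  mean(stat_values < threshold)
}

#' Wilcoxon rank-sum test of a location shift between two methods
#'
#' Two-sided two-sample rank-sum test: exact enumeration when the
#' combined sample size is at most 20 and there are no ties, normal
#' approximation with tie and continuity correction otherwise
#' (delegating to [stats::wilcox.test()], which implements exactly this
#' switch).
#'
#' @param x,y numeric vectors (e.g. the two methods' statistics across
#'   replicates).
#' @return two-sided p-value.
#' @export
#' @examples
#' wilcoxon_location_test(c(1, 3), c(2, 4))  # exact 2/3
wilcoxon_location_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("constant pooled data; no location shift measurable")
    return(1)
  }
  exact <- (length(pooled) <= 20L) && !anyDuplicated(pooled)
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE)$p.value
  )
}

#' Two-sample test for equality of rejection proportions
#'
#' Chi-square test with continuity correction comparing k1/n with k2/n
#' (two-sided), as used to contrast the two evidence measures' rejection
#' counts at a common threshold.
#'
#' @param k1,k2 rejection counts of the two methods.
#' @param n number of replicates for each method.
#' @return two-sided p-value.
#' @export
#' @examples
#' proportion_equality_test(69, 13, 200)  # far below 1e-4
proportion_equality_test <- function(k1, k2, n) {
  if (n <= 0) stop("n must be positive")
  if (k1 < 0 || k2 < 0 || k1 > n || k2 > n)
    stop("counts must lie in [0, n]")
  if (k1 == k2) return(1)
  suppressWarnings(
    prop.test(c(k1, k2), c(n, n), alternative = "two.sided",
              correct = TRUE)$p.value
  )
}

#' Replicate-level power study comparing the two evidence measures
#'
#' Loops generate -> analyse -> summarise: simulates `n_replicates`
#' cohorts from `config`, computes the per-factor [evidence_table()] for
#' each (p-value and proportion of positive deviance differences), and
#' summarises per factor the distribution of both statistics, their
#' power at the thresholds, a Wilcoxon rank-sum test of the location
#' shift between the two statistics, and equality-of-proportion tests of
#' the rejection rates at every threshold. Deterministic for a fixed
#' master seed (replicate r uses cohort sub-seed `derive_seed(seed, r)`
#' and chain seeds derived from `derive_seed(seed, 100000 + r)`).
#'
#' Replicates in which the analysis fails are logged and excluded; the
#' count of failures is reported on the result, never silently dropped.
#'
#' @param config a [cohort_config()].
#' @param n_replicates number of replicates (>= 2).
#' @param seed master integer seed.
#' @param factors factor list (default [standard_factors()] of the
#'   config's panel).
#' @param sampler a [sampler_config()] (scaled-down desk defaults are
#'   sensible here, e.g. 2,000 draws).
#' @param thresholds rejection thresholds (default `c(0.1, 0.05, 0.01)`).
#' @param pvalue_method `"wald"` or `"lrt"`.
#' @param out_dir optional directory; when given,
#'   `replicate_results.csv` and `power_table.csv` are written there.
#' @param verbose print one progress line per replicate.
#' @return a list of class `power_experiment` with `replicates` (long
#'   data frame of per-replicate, per-factor statistics), `power_table`
#'   (per-factor summary), `n_failed`, `thresholds`, `seed`.
#' @export
run_experiment <- function(config, n_replicates, seed,
                           factors = NULL,
                           sampler = sampler_config(n_draws = 2000L,
                                                    n_burnin = 1000L),
                           thresholds = c(0.1, 0.05, 0.01),
                           pvalue_method = c("wald", "lrt"),
                           out_dir = NULL, verbose = FALSE) {
  stopifnot(n_replicates >= 2)
  pvalue_method <- match.arg(pvalue_method)
  if (is.null(factors)) factors <- standard_factors(config$variants)
  cohorts <- generate_replicates(config, n_replicates, seed)
  res <- vector("list", n_replicates)
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    tab <- tryCatch(
      evidence_table(cohorts[[r]], factors, config = sampler,
                     seed = derive_seed(seed, 100000L + r),
                     pvalue_method = pvalue_method),
      error = function(e) {
        message(sprintf("replicate %d failed: %s", r, conditionMessage(e)))
        NULL
      })
    if (is.null(tab)) { n_failed <- n_failed + 1L; next }
    tab$replicate_id <- r
    res[[r]] <- tab
    if (verbose)
      message(sprintf("replicate %d/%d done", r, n_replicates))
  }
  reps <- do.call(rbind, res)
  if (is.null(reps)) stop("all replicates failed")
  power_table <- summarise_power(reps, thresholds)
  out <- structure(list(replicates = reps, power_table = power_table,
                        n_failed = n_failed, thresholds = thresholds,
                        seed = seed, n_replicates = n_replicates),
                   class = "power_experiment")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv2_std(reps, file.path(out_dir, "replicate_results.csv"))
    write.csv2_std(power_table, file.path(out_dir, "power_table.csv"))
  }
  out
}

write.csv2_std <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
}

# per-factor summary across replicates: distribution of each statistic,
# power at each threshold, and between-method tests
summarise_power <- function(reps, thresholds = c(0.1, 0.05, 0.01)) {
  facs <- unique(reps$factor)
  rows <- lapply(facs, function(f) {
    sub <- reps[reps$factor == f, ]
    pv <- sub$p_value
    pp <- sub$prop_positive
    n <- nrow(sub)
    row <- data.frame(factor = f, n_replicates = n,
                      pvalue_median = quantile7(pv, 0.5),
                      pvalue_q2.5 = quantile7(pv, 0.025),
                      pvalue_q97.5 = quantile7(pv, 0.975),
                      propdd_median = quantile7(pp, 0.5),
                      propdd_q2.5 = quantile7(pp, 0.025),
                      propdd_q97.5 = quantile7(pp, 0.975),
                      p_wilcoxon = wilcoxon_location_test(pv, pp),
                      stringsAsFactors = FALSE, check.names = FALSE)
    for (t in thresholds) {
      lab <- sub("^0\\.", "", format(t))
      row[[paste0("power_pvalue_", lab)]] <- power_at_threshold(pv, t)
      row[[paste0("power_propdd_", lab)]] <- power_at_threshold(pp, t)
      row[[paste0("p_prop_", lab)]] <-
        proportion_equality_test(sum(pv < t), sum(pp < t), n)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.power_experiment <- function(x, ...) {
  cat(sprintf("Power experiment: %d replicates (%d failed), seed %s\n",
              x$n_replicates, x$n_failed, format(x$seed)))
  cat(sprintf("thresholds: %s\n", paste(x$thresholds, collapse = ", ")))
  cols <- c("factor", "pvalue_median", "propdd_median",
            grep("^power_", names(x$power_table), value = TRUE))
  tab <- x$power_table[, cols]
  tab[-1] <- lapply(tab[-1], round, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
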