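#' Deviance-difference evidence between two posterior draw sets
#'
#' Pairs draw j of the factor-model chain with draw j of the baseline
#' chain and summarises the deviance differences
#' \eqn{\Delta D_j = D^{(2)}_j - D^{(1)}_j}: the median, the central 95%
#' credible interval (2.5th and 97.5th empirical percentiles, linear
#' interpolation), and the proportion of strictly positive differences.
#' A small proportion means the factor model dominates the baseline over
#' essentially the whole posterior, i.e. strong evidence for the factor.
#' Because the chains are independent, the index pairing is arbitrary
#' and any other pairing is equally valid (a property the test suite
#' exercises).
#'
#' @param draws_factor `rwm_logit` fit of the model with the genetic
#'   factor (model 2).
#' @param draws_baseline `rwm_logit` fit of the baseline model
#'   (model 1), from an independent chain (different seed).
#' @return an object of class `deviance_comparison` with `diffs`,
#'   `median`, `ci95`, `prop_positive`, `m`.
#' @export
#' @examples
#' d2 <- list(deviances = c(5, 1), seed = 1)
#' d1 <- list(deviances = c(2, 2), seed = 2)
#' compare_models(d2, d1)$prop_positive
compare_models <- function(draws_factor, draws_baseline) {
  s2 <- draws_factor$seed; s1 <- draws_baseline$seed
  if (!is.null(s2) && !is.null(s1) && identical(s2, s1))
    stop("the two chains share a seed; independent chains are required")
  d2 <- draws_factor$deviances
  d1 <- draws_baseline$deviances
  if (identical(d2, d1))
    stop("identical deviance series supplied; independent chains are required")
  m <- min(length(d2), length(d1))
  if (length(d2) != length(d1))
    warning("draw sets of unequal length; truncating to ", m, " pairs")
  diffs <- d2[seq_len(m)] - d1[seq_len(m)]
  ci <- quantile7(diffs, c(0.025, 0.975))
  structure(list(diffs = diffs,
                 median = quantile7(diffs, 0.5),
                 ci95 = ci,
                 prop_positive = mean(diffs > 0),
                 m = m),
            class = "deviance_comparison")
}

#' @export
print.deviance_comparison <- function(x, ...) {
  cat(sprintf("Deviance difference over %d paired draws\n", x$m))
  cat(sprintf("  median %.2f, 95%% credible interval (%.2f, %.2f), proportion > 0: %.4f\n",
              x$median, x$ci95[1], x$ci95[2], x$prop_positive))
  invisible(x)
}

#' The standard factor set of a variant panel
#'
#' One factor per variant (default additive coding) plus the any-rare
#' carrier indicator, mirroring the usual single-gene analysis layout.
#'
#' @param variants a [variant_panel()].
#' @param coding per-variant coding, `"additive"` or `"collapsed"`.
#' @param rare_threshold MAF cutoff for the any-rare factor.
#' @return a named list of [genetic_factor()] objects (length
#'   `nrow(variants) + 1`).
#' @export
standard_factors <- function(variants = kdr_variants(),
                             coding = c("additive", "collapsed"),
                             rare_threshold = 0.01) {
  coding <- match.arg(coding)
  f <- lapply(variants$name, function(v) genetic_factor(coding, variant = v))
  f <- c(f, list(genetic_factor("any_rare", rare_threshold = rare_threshold)))
  names(f) <- vapply(f, factor_label, character(1))
  f
}

#' Per-factor evidence table for one cohort
#'
#' For each genetic factor, fits the baseline and factor logistic models,
#' computes the standard-analysis p-value, samples the factor-model
#' posterior, and summarises the deviance difference against a single
#' baseline chain that is sampled once and reused across all factors.
#'
#' Factors whose explanatory column is constant in the cohort (e.g. a
#' rare variant with no carriers in this replicate) carry no
#' information: they are reported with p-value 1 and their deviance
#' difference is computed against an independent second chain of the
#' baseline model, so their `prop_positive` concentrates around 0.5 and
#' they are (correctly) never rejected. Such rows are flagged
#' `degenerate`.
#'
#' @param cohort a `cohort_replicate`.
#' @param factors list of [genetic_factor()] (default:
#'   [standard_factors()] of the cohort's panel).
#' @param config a [sampler_config()].
#' @param seed integer seed; chain i uses sub-seed `derive_seed(seed, i)`
#'   (baseline = stream 0).
#' @param pvalue_method `"wald"` (default) or `"lrt"`.
#' @return a `data.frame` with one row per factor: `factor`, `p_value`,
#'   `dd_median`, `dd_ci_low`, `dd_ci_high`, `prop_positive`,
#'   `separation`, `degenerate`; the baseline chain is attached as
#'   attribute `"baseline"`.
#' @export
evidence_table <- function(cohort, factors = NULL,
                           config = sampler_config(), seed = 1L,
                           pvalue_method = c("wald", "lrt")) {
  pvalue_method <- match.arg(pvalue_method)
  if (is.null(factors)) factors <- standard_factors(cohort$variants)
  d1 <- build_design_matrix(cohort, genetic_factor("none"))
  fit1 <- fit_logit_mle(d1)
  base_chain <- rwm_logit(d1$X, d1$y, config = config,
                          seed = derive_seed(seed, 0L),
                          model_label = "baseline")
  degen_chain <- NULL   # lazily sampled second baseline chain
  rows <- lapply(seq_along(factors), function(i) {
    fac <- factors[[i]]
    col <- factor_column(cohort, fac)
    sub <- derive_seed(seed, i)
    if (is.null(col) || length(unique(col)) < 2L) {
      if (is.null(degen_chain))
        degen_chain <<- rwm_logit(d1$X, d1$y, config = config,
                                  seed = derive_seed(seed, length(factors) + 1L),
                                  model_label = "baseline (2nd chain)")
      cmp <- compare_models(degen_chain, base_chain)
      return(data.frame(factor = factor_label(fac), p_value = 1,
                        dd_median = cmp$median, dd_ci_low = cmp$ci95[1],
                        dd_ci_high = cmp$ci95[2],
                        prop_positive = cmp$prop_positive,
                        separation = FALSE, degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    d2 <- build_design_matrix(cohort, fac)
    fit2 <- fit_logit_mle(d2)
    pv <- association_pvalue(fit2, fit1, method = pvalue_method)
    chain2 <- rwm_logit(d2$X, d2$y, config = config, seed = sub,
                        model_label = factor_label(fac))
    cmp <- compare_models(chain2, base_chain)
    data.frame(factor = factor_label(fac), p_value = pv$p_value,
               dd_median = cmp$median, dd_ci_low = cmp$ci95[1],
               dd_ci_high = cmp$ci95[2],
               prop_positive = cmp$prop_positive,
               separation = pv$unreliable, degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "baseline") <- base_chain
  out
}
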