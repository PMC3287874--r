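#' Variant panel specification
#'
#' A variant panel is a data frame with one row per variant and columns
#' `name` (label), `maf` (minor allele frequency, proportion in
#' `[0, 0.5]`), `q1_effect` (additive effect of one minor allele on the
#' quantitative risk factor Q1 among nonsmokers; 0 for non-functional
#' variants) and `is_rare` (logical, `maf < rare_threshold`).
#'
#' @param name character vector of variant labels.
#' @param maf numeric vector of minor allele frequencies in `[0, 0.5]`.
#' @param q1_effect numeric vector of per-allele effects on Q1 for
#'   nonsmokers (0 = no effect).
#' @param rare_threshold MAF below which a variant counts as rare
#'   (default 0.01, i.e. 1%).
#' @return a `data.frame` of class `variant_panel`.
#' @export
#' @examples
#' variant_panel(c("v1", "v2"), maf = c(0.001, 0.2), q1_effect = c(1, 0))
variant_panel <- function(name, maf, q1_effect = 0, rare_threshold = 0.01) {
  n <- length(name)
  maf <- rep_len(as.numeric(maf), n)
  q1_effect <- rep_len(as.numeric(q1_effect), n)
  if (anyNA(maf) || any(maf < 0 | maf > 0.5))
    stop("minor allele frequencies must lie in [0, 0.5]")
  if (any(!is.finite(q1_effect)))
    stop("q1_effect must be finite")
  if (anyDuplicated(name))
    stop("variant names must be unique")
  out <- data.frame(name = as.character(name), maf = maf,
                    q1_effect = q1_effect,
                    is_rare = maf < rare_threshold,
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_panel", "data.frame")
  out
}

#' The 16-variant KDR gene panel
#'
#' The bundled study panel: 16 variants in the KDR (kinase insert domain
#' receptor) gene region with the minor allele frequencies and nonsmoker
#' Q1 effects of the GAW17 mini-exome simulation. Ten variants influence
#' the quantitative risk factor Q1 (variants 7 and 13 most strongly, 1.08
#' and 0.94 per minor allele); fourteen are rare (MAF < 1%), while
#' variant 8 (MAF 16.5%) and variant 11 (MAF 2.08%) are common.
#' Effects are the nonsmoker values; in the default generating model they
#' are 50% higher in smokers (see [cohort_config()]).
#'
#' @return a [variant_panel()] with 16 rows.
#' @export
#' @examples
#' kdr_variants()
kdr_variants <- function() {
  variant_panel(
    name = sprintf("v%02d", 1:16),
    maf = c(0.14, 0.22, 0.07, 0.07, 0.07, 0.07, 0.07, 16.50,
            0.07, 0.14, 2.08, 0.07, 0.07, 0.22, 0.07, 0.07) / 100,
    q1_effect = c(0, 0.56, 0, 0, 0.58, 0.47, 1.08, 0.14,
                  0.62, 0, 0.30, 0.30, 0.94, 0.42, 0, 0)
  )
}
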