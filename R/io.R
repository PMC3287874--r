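#' Write a cohort replicate to tab-delimited files
#'
#' Two TSVs in the package's cohort dialect: `<prefix>_genotypes.tsv`
#' (rows = individuals, one column per variant, minor-allele counts
#' 0/1/2) and `<prefix>_covariates.tsv` with columns `id`, `age`,
#' `smoker`, `ethnicity`, `y` and, when `latent = TRUE`, the latent
#' `q1`, `q2`, `liability` used to generate the data.
#'
#' @param cohort a `cohort_replicate`.
#' @param prefix file path prefix.
#' @param latent include the latent generating variables (default TRUE).
#' @return invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, prefix, latent = TRUE) {
  gfile <- paste0(prefix, "_genotypes.tsv")
  cfile <- paste0(prefix, "_covariates.tsv")
  write.table(cohort$genotypes, gfile, sep = "\t", quote = FALSE,
              row.names = FALSE)
  cov <- data.frame(id = seq_along(cohort$y), age = cohort$age,
                    smoker = cohort$smoker,
                    ethnicity = as.character(cohort$ethnicity),
                    y = cohort$y)
  if (latent) {
    cov$q1 <- cohort$q1; cov$q2 <- cohort$q2
    cov$liability <- cohort$liability
  }
  write.table(cov, cfile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(genotypes = gfile, covariates = cfile))
}

#' Read a cohort replicate from tab-delimited files
#'
#' Inverse of [write_cohort()]. Variant metadata is reconstructed from
#' `variants` when supplied, otherwise MAFs are estimated from the
#' genotype columns (with unknown Q1 effects set to 0), which is enough
#' to drive the association analysis.
#'
#' @param genotypes_file,covariates_file paths written by
#'   [write_cohort()] (or external files in the same dialect).
#' @param variants optional [variant_panel()] describing the columns.
#' @param replicate_id integer label.
#' @return a `cohort_replicate`.
#' @export
read_cohort <- function(genotypes_file, covariates_file, variants = NULL,
                        replicate_id = 1L) {
  g <- as.matrix(read.delim(genotypes_file, check.names = FALSE))
  storage.mode(g) <- "integer"
  if (any(!g %in% c(0L, 1L, 2L)))
    stop("genotype entries must be minor-allele counts in {0, 1, 2}")
  cov <- read.delim(covariates_file)
  needed <- c("age", "smoker", "ethnicity", "y")
  if (!all(needed %in% names(cov)))
    stop("covariate file must have columns: ", paste(needed, collapse = ", "))
  if (nrow(cov) != nrow(g))
    stop("genotype and covariate files have different numbers of rows")
  if (any(!cov$y %in% c(0, 1))) stop("y must be binary 0/1")
  if (is.null(variants))
    variants <- variant_panel(colnames(g), maf = pmin(colMeans(g) / 2, 0.5),
                              q1_effect = 0)
  structure(list(replicate_id = as.integer(replicate_id),
                 genotypes = g,
                 age = cov$age, smoker = cov$smoker,
                 ethnicity = factor(cov$ethnicity),
                 q1 = cov$q1, q2 = cov$q2, liability = cov$liability,
                 y = as.integer(cov$y), intercept = NA_real_,
                 variants = variants),
            class = "cohort_replicate")
}

#' Export a posterior draw set to CSV
#'
#' One row per retained draw: the coefficients followed by the deviance.
#'
#' @param drawset an `rwm_logit` fit.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_drawset <- function(drawset, path) {
  out <- cbind(as.data.frame(drawset$draws), deviance = drawset$deviances)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
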