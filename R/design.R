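#' Genetic factor codings
#'
#' A genetic factor is a rule turning the genotype matrix into a single
#' explanatory column:
#' \describe{
#'   \item{additive}{minor-allele count of one variant (0/1/2).}
#'   \item{collapsed}{carrier indicator of one variant (count >= 1).}
#'   \item{any_rare}{indicator of carrying at least one minor allele at
#'     any variant with MAF below `rare_threshold`.}
#'   \item{none}{no genetic column (baseline model).}
#' }
#'
#' @param kind one of `"additive"`, `"collapsed"`, `"any_rare"`, `"none"`.
#' @param variant variant name or index (required for additive/collapsed).
#' @param rare_threshold MAF cutoff defining "rare" (default 0.01).
#' @return an object of class `genetic_factor`.
#' @export
#' @examples
#' genetic_factor("additive", variant = 7)
#' genetic_factor("any_rare")
genetic_factor <- function(kind = c("additive", "collapsed", "any_rare", "none"),
                           variant = NULL, rare_threshold = 0.01) {
  kind <- match.arg(kind)
  if (kind %in% c("additive", "collapsed") && is.null(variant))
    stop("additive and collapsed codings need a variant")
  structure(list(kind = kind, variant = variant,
                 rare_threshold = rare_threshold),
            class = "genetic_factor")
}

#' @export
print.genetic_factor <- function(x, ...) {
  cat("Genetic factor:", factor_label(x), "\n")
  invisible(x)
}

#' Label of a genetic factor
#' @param factor a [genetic_factor()].
#' @return character scalar, e.g. `"additive(v07)"`.
#' @export
factor_label <- function(factor) {
  switch(factor$kind,
         none = "none",
         any_rare = "any_rare",
         sprintf("%s(%s)", factor$kind, as.character(factor$variant)))
}

# resolve a variant name or index against the cohort panel
resolve_variant <- function(cohort, variant) {
  nm <- colnames(cohort$genotypes)
  if (is.character(variant)) {
    j <- match(variant, nm)
    if (is.na(j)) stop("unknown variant: ", variant)
  } else {
    j <- as.integer(variant)
    if (j < 1L || j > length(nm)) stop("variant index out of range: ", variant)
  }
  j
}

#' Extract the explanatory column of a genetic factor
#'
#' @param cohort a `cohort_replicate`.
#' @param factor a [genetic_factor()].
#' @return numeric vector of length N (or `NULL` for kind `"none"`).
#' @export
factor_column <- function(cohort, factor) {
  g <- cohort$genotypes
  switch(factor$kind,
    none = NULL,
    additive = as.numeric(g[, resolve_variant(cohort, factor$variant)]),
    collapsed = as.numeric(g[, resolve_variant(cohort, factor$variant)] >= 1L),
    any_rare = {
      rare <- cohort$variants$maf < factor$rare_threshold
      if (!any(rare)) stop("no variant is rare at threshold ", factor$rare_threshold)
      as.numeric(rowSums(g[, rare, drop = FALSE]) >= 1L)
    })
}

#' Build the logistic-regression design matrix for a cohort
#'
#' The baseline design (model 1) has seven columns: intercept, age,
#' smoker, and four ethnicity dummies (reference = first level in sorted
#' label order). A non-`"none"` genetic factor appends one further
#' column (model 2). Column order is deterministic.
#'
#' @param cohort a `cohort_replicate` (or any list with `age`, `smoker`,
#'   `ethnicity`, `genotypes`, `variants`, `y`).
#' @param factor a [genetic_factor()]; default `"none"`.
#' @return a list of class `design_matrix` with elements `X` (N x p
#'   numeric matrix), `y`, `column_names`, and `genetic_column` (index of
#'   the genetic column, or `NA`).
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(n_individuals = 120), seed = 3)
#' d <- build_design_matrix(coh, genetic_factor("any_rare"))
#' colnames(d$X)
build_design_matrix <- function(cohort, factor = genetic_factor("none")) {
  n <- length(cohort$y)
  eth <- factor(as.character(cohort$ethnicity),
                levels = sort(unique(c(paste0("eth", 1:5),
                                       as.character(cohort$ethnicity)))))
  if (nlevels(eth) > 5L) stop("more than five ethnicity levels observed")
  dummies <- sapply(levels(eth)[-1L], function(l) as.numeric(eth == l))
  X <- cbind(intercept = 1, age = cohort$age, smoker = cohort$smoker, dummies)
  gc <- factor_column(cohort, factor)
  gcol <- NA_integer_
  if (!is.null(gc)) {
    X <- cbind(X, genetic = gc)
    gcol <- ncol(X)
  }
  structure(list(X = X, y = as.numeric(cohort$y),
                 column_names = colnames(X),
                 genetic_column = gcol,
                 factor = factor),
            class = "design_matrix")
}
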