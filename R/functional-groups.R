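#' Names of the nine pathway-informed functional groups
#'
#' Derived features combining the 14 proteins by arithmetic reflecting their
#' interactions: redundant effectors are summed (BAX+BAK; the anti-apoptotic
#' trio BCL-2+BCL-XL+MCL-1), apoptosome formation is a product (APAF-1 x
#' pro-caspase 9), caspase inhibition a ratio (XIAP / pro-caspase 3), and
#' SMAC, BID, BIM, PUMA, NOXA pass through unchanged. Order is fixed.
#'
#' @format Character vector of length 9.
#' @export
functional_group_names <- c(
  "BAX_BAK", "ANTIAPOPTOTIC", "APAF_C9", "XIAP_over_C3",
  "SMAC", "BID", "BIM", "PUMA", "NOXA"
)

#' Compute functional groups from relative protein expression
#'
#' Operates on the linear relative-expression scale.
#'
#' @param panel An [expression_panel()] or a named numeric profile covering
#'   the canonical 14 proteins.
#' @return Numeric matrix, samples x 9 groups (columns in
#'   [functional_group_names] order).
#' @export
compute_groups <- function(panel) {
  e <- if (inherits(panel, "expression_panel")) panel$expr else {
    names(panel) <- canonical_protein(names(panel))
    matrix(panel[apoptosis_proteins], nrow = 1,
           dimnames = list("sample", apoptosis_proteins))
  }
  zero_c3 <- which(e[, "CASP3"] <= 0)
  if (length(zero_c3)) {
    stop("CASP3 is 0 for sample(s): ",
         paste(rownames(e)[zero_c3], collapse = ", "),
         " - XIAP/C3 undefined", call. = FALSE)
  }
  g <- cbind(
    BAX_BAK       = e[, "BAX"] + e[, "BAK"],
    ANTIAPOPTOTIC = e[, "BCL2"] + e[, "BCLXL"] + e[, "MCL1"],
    APAF_C9       = e[, "APAF1"] * e[, "CASP9"],
    XIAP_over_C3  = e[, "XIAP"] / e[, "CASP3"],
    SMAC          = e[, "SMAC"],
    BID           = e[, "BID"],
    BIM           = e[, "BIM"],
    PUMA          = e[, "PUMA"],
    NOXA          = e[, "NOXA"]
  )
  rownames(g) <- rownames(e)
  g
}

#' Fit per-group z-score normalisation parameters
#'
#' Means and sample standard deviations (n-1 denominator) per functional
#' group across the training samples. The denominator convention is recorded
#' in the returned object so either convention can be reproduced.
#'
#' @param groups Matrix from [compute_groups()], >= 2 samples.
#' @return Object of class `zscore_params` with `mean`, `sd`, `ddof`.
#' @export
fit_zscore <- function(groups) {
  if (nrow(groups) < 2) stop("need >= 2 samples to fit z-scores", call. = FALSE)
  m <- colMeans(groups)
  s <- apply(groups, 2, stats::sd)
  degenerate <- names(s)[s <= 0 | !is.finite(s)]
  if (length(degenerate)) {
    stop("degenerate (constant) functional group(s): ",
         paste(degenerate, collapse = ", "), call. = FALSE)
  }
  structure(list(mean = m, sd = s, ddof = 1L), class = "zscore_params")
}

#' Apply fitted z-score normalisation
#'
#' @param groups Matrix (or single named vector) of functional-group values.
#' @param params A `zscore_params` object from [fit_zscore()].
#' @return Matrix of z-scores with the same shape.
#' @export
apply_zscore <- function(groups, params) {
  stopifnot(inherits(params, "zscore_params"))
  if (is.null(dim(groups))) groups <- matrix(groups, nrow = 1,
                                             dimnames = list("sample", names(groups)))
  missing <- setdiff(names(params$mean), colnames(groups))
  if (length(missing)) stop("missing functional group(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  groups <- groups[, names(params$mean), drop = FALSE]
  sweep(sweep(groups, 2, params$mean, `-`), 2, params$sd, `/`)
}
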