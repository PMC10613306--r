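#' Canonical apoptosis protein panel
#'
#' The 14 intrinsic-apoptosis signalling proteins quantified relative to a
#' HeLa reference: effectors (BAX, BAK), anti-apoptotic guardians (BCL2,
#' BCLXL, MCL1), BH3-only activators/sensitisers (BID, BIM, PUMA, NOXA),
#' apoptosome components (APAF1, CASP9), the executioner pro-caspase
#' (CASP3), and the XIAP/SMAC axis. Order is fixed so downstream loading
#' matrices are reproducible.
#'
#' @format Character vector of length 14.
#' @export
apoptosis_proteins <- c(
  "APAF1", "BAK", "BAX", "BCLXL", "BCL2", "BID", "BIM",
  "MCL1", "NOXA", "CASP3", "CASP9", "PUMA", "SMAC", "XIAP"
)

# fixed alias table: common synonyms / gene symbols -> canonical panel names
.protein_aliases <- c(
  "APAF1" = "APAF1", "APAF-1" = "APAF1",
  "BAK" = "BAK", "BAK1" = "BAK",
  "BAX" = "BAX",
  "BCLXL" = "BCLXL", "BCL-XL" = "BCLXL", "BCL2L1" = "BCLXL", "BCLX" = "BCLXL",
  "BCL2" = "BCL2", "BCL-2" = "BCL2",
  "BID" = "BID",
  "BIM" = "BIM", "BCL2L11" = "BIM",
  "MCL1" = "MCL1", "MCL-1" = "MCL1",
  "NOXA" = "NOXA", "PMAIP1" = "NOXA",
  "CASP3" = "CASP3", "CASPASE3" = "CASP3", "PRO-CASPASE3" = "CASP3", "C3" = "CASP3",
  "CASP9" = "CASP9", "CASPASE9" = "CASP9", "PRO-CASPASE9" = "CASP9", "C9" = "CASP9",
  "PUMA" = "PUMA", "BBC3" = "PUMA",
  "SMAC" = "SMAC", "DIABLO" = "SMAC",
  "XIAP" = "XIAP", "BIRC4" = "XIAP"
)

#' Resolve protein names through the fixed alias map
#'
#' Unknown names are an error, never silently dropped.
#'
#' @param x Character vector of protein or gene names.
#' @return Character vector of canonical panel names.
#' @export
canonical_protein <- function(x) {
  key <- toupper(gsub("[ _]", "", x))
  out <- .protein_aliases[key]
  if (anyNA(out)) {
    stop("unknown protein name(s): ", paste(x[is.na(out)], collapse = ", "),
         call. = FALSE)
  }
  unname(out)
}

#' Construct an expression panel
#'
#' A panel holds one row per sample of the 14 canonical proteins, expressed
#' relative to HeLa (dimensionless, linear scale), plus optional sensitivity
#' labels.
#'
#' @param expr Numeric matrix or data frame, samples x proteins; column
#'   names resolvable through [canonical_protein()]; rownames (or a
#'   `sample_id` column) give sample ids.
#' @param labels Optional named character vector mapping sample id to
#'   `"high_sensitivity"` or `"reduced_sensitivity"`.
#' @return An object of class `expression_panel`: list with `expr`
#'   (matrix, canonical column order) and `labels`.
#' @export
expression_panel <- function(expr, labels = NULL) {
  if (is.data.frame(expr)) {
    if ("sample_id" %in% names(expr)) {
      rn <- as.character(expr$sample_id)
      expr <- expr[, setdiff(names(expr), c("sample_id", "label")), drop = FALSE]
      rownames(expr) <- rn
    }
    expr <- as.matrix(expr)
  }
  storage.mode(expr) <- "double"
  colnames(expr) <- canonical_protein(colnames(expr))
  missing <- setdiff(apoptosis_proteins, colnames(expr))
  if (length(missing)) {
    stop("panel is missing protein column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  expr <- expr[, apoptosis_proteins, drop = FALSE]
  if (is.null(rownames(expr)) && nrow(expr) > 0) {
    rownames(expr) <- paste0("S", seq_len(nrow(expr)))
  }
  if (anyDuplicated(rownames(expr))) stop("duplicate sample ids", call. = FALSE)
  if (any(!is.finite(expr)) || any(expr < 0)) {
    stop("expression values must be finite and >= 0", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- match_labels(labels, rownames(expr))
  }
  structure(list(expr = expr, labels = labels), class = "expression_panel")
}

match_labels <- function(labels, sample_ids) {
  if (is.null(names(labels))) {
    if (length(labels) != length(sample_ids)) {
      stop("unnamed labels must cover every sample", call. = FALSE)
    }
    names(labels) <- sample_ids
  }
  bad <- setdiff(names(labels), sample_ids)
  if (length(bad)) stop("labelled sample(s) not in panel: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  ok <- c("high_sensitivity", "reduced_sensitivity")
  if (!all(labels %in% ok)) {
    stop("labels must be one of: ", paste(ok, collapse = ", "), call. = FALSE)
  }
  labels
}

#' @export
print.expression_panel <- function(x, ...) {
  cat("expression_panel:", nrow(x$expr), "samples x", ncol(x$expr), "proteins\n")
  if (!is.null(x$labels)) {
    cat("labels:", paste(names(table(x$labels)), table(x$labels),
                         sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Relative quantification of a western-blot band against the HeLa reference
#'
#' Loading-control-corrected band intensity expressed relative to the same
#' ratio in the HeLa lane: `(band/loading) / (hela_band/hela_loading)`.
#' HeLa measured against itself is 1 by construction. The contract is
#' agnostic to which loading control (total-protein stain or housekeeping
#' protein) produced the denominators.
#'
#' @param band,loading Sample band and loading-control intensities.
#' @param hela_band,hela_loading The same for the HeLa reference lane.
#' @return Dimensionless relative expression (>= 0).
#' @export
quantify_relative <- function(band, loading, hela_band, hela_loading) {
  if (any(loading <= 0) || any(hela_loading <= 0) || any(hela_band <= 0)) {
    stop("loading controls and HeLa band must be > 0", call. = FALSE)
  }
  if (any(band < 0)) stop("band intensity must be >= 0", call. = FALSE)
  (band / loading) / (hela_band / hela_loading)
}

#' Read / write an expression panel as TSV or CSV
#'
#' Expected schema: a `sample_id` column, one column per canonical protein
#' (aliases accepted), optionally a `label` column. `write_panel()` followed
#' by `read_panel()` round-trips values bit-exactly for finite decimals.
#'
#' @param path File path; `.csv` is comma-separated, anything else
#'   tab-separated.
#' @return `read_panel()`: an [expression_panel()].
#' @export
read_panel <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("panel file lacks 'sample_id' column",
                                        call. = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- stats::setNames(as.character(df$label), as.character(df$sample_id))
    labels <- labels[!is.na(labels) & labels != ""]
    if (!length(labels)) labels <- NULL
  }
  val_cols <- setdiff(names(df), c("sample_id", "label"))
  for (cc in val_cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value in column '%s', row %d", cc,
                   if (is.na(bad)) 1L else bad), call. = FALSE)
    }
  }
  expression_panel(df, labels = labels)
}

#' @param panel An [expression_panel()].
#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "expression_panel"))
  df <- data.frame(sample_id = rownames(panel$expr), panel$expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(panel$labels)) {
    df$label <- unname(panel$labels[df$sample_id])
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert relative expression to molar concentrations
#'
#' Multiplies HeLa-relative expression by reference absolute HeLa
#' concentrations (in micromolar), as required by the caspase-execution
#' surrogate. The all-ones profile maps to the reference itself.
#'
#' @param panel An [expression_panel()] or a named numeric profile.
#' @param hela_conc Named numeric vector of HeLa concentrations (uM) covering
#'   every requested protein; see [default_hela_concentrations()].
#' @return Matrix (samples x proteins) of concentrations in uM.
#' @export
to_concentrations <- function(panel, hela_conc) {
  expr <- if (inherits(panel, "expression_panel")) panel$expr else
    matrix(panel, nrow = 1, dimnames = list("sample", names(panel)))
  names(hela_conc) <- canonical_protein(names(hela_conc))
  missing <- setdiff(colnames(expr), names(hela_conc))
  if (length(missing)) {
    stop("no reference HeLa concentration for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sweep(expr, 2, hela_conc[colnames(expr)], `*`)
}

#' Reference HeLa concentrations
#'
#' Absolute HeLa protein concentrations (uM) used to put relative expression
#' on a molar scale. These are documented placeholder defaults of plausible
#' magnitude, intended to be overridden with user-measured values via
#' [read_hela_concentrations()].
#'
#' @return Named numeric vector (uM) over the canonical 14 proteins.
#' @export
default_hela_concentrations <- function() {
  read_hela_concentrations(
    system.file("extdata", "hela_concentrations.yaml", package = "apoptosense",
                mustWork = TRUE))
}

#' @param path YAML file with a top-level `concentrations_uM` mapping.
#' @rdname default_hela_concentrations
#' @export
read_hela_concentrations <- function(path) {
  doc <- yaml::read_yaml(path)
  conc <- unlist(doc$concentrations_uM)
  if (is.null(conc)) stop("config lacks 'concentrations_uM'", call. = FALSE)
  names(conc) <- canonical_protein(names(conc))
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("HeLa concentrations must be finite and >= 0", call. = FALSE)
  }
  conc
}
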