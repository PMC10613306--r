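#' Construct an mRNA cohort
#'
#' @param expr Matrix/data frame, patients x genes; gene columns resolvable
#'   via [canonical_protein()]; rownames or `patient_id` column give ids.
#' @param age Numeric vector of ages in years; `NA` = unknown.
#' @return Object of class `mrna_cohort`: `expr` (matrix, canonical column
#'   order), `age`.
#' @export
mrna_cohort <- function(expr, age) {
  if (is.data.frame(expr)) {
    if ("patient_id" %in% names(expr)) {
      rn <- as.character(expr$patient_id)
      expr <- expr[, setdiff(names(expr), c("patient_id", "age")), drop = FALSE]
      rownames(expr) <- rn
    }
    expr <- as.matrix(expr)
  }
  storage.mode(expr) <- "double"
  colnames(expr) <- canonical_protein(colnames(expr))
  missing <- setdiff(apoptosis_proteins, colnames(expr))
  if (length(missing)) stop("cohort is missing gene(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  expr <- expr[, apoptosis_proteins, drop = FALSE]
  if (is.null(rownames(expr)) && nrow(expr) > 0) {
    rownames(expr) <- paste0("P", seq_len(nrow(expr)))
  }
  if (length(age) != nrow(expr)) stop("age must have one entry per patient",
                                      call. = FALSE)
  structure(list(expr = expr, age = as.numeric(age)), class = "mrna_cohort")
}

#' Read an mRNA cohort from TSV/CSV
#'
#' Accepts patients-in-rows (a `patient_id` column plus gene columns) or
#' genes-in-rows (a `gene` column plus one column per patient), detected
#' from the header. An `age` column (or row, in the transposed layout named
#' `age`) carries years; empty/`NA`/"unknown" entries mark unknown age.
#'
#' @param path File path (`.csv` comma-separated, else tab).
#' @return An [mrna_cohort()].
#' @export
read_cohort <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  parse_age <- function(x) {
    x[tolower(trimws(as.character(x))) %in% c("", "na", "unknown")] <- NA
    suppressWarnings(as.numeric(x))
  }
  if ("gene" %in% names(df)) {           # genes x patients
    genes <- df$gene
    m <- t(as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE]))
    colnames(m) <- genes
    age <- rep(NA_real_, nrow(m))
    if ("age" %in% genes) {
      age <- parse_age(m[, "age"])
      m <- m[, setdiff(colnames(m), "age"), drop = FALSE]
    }
    storage.mode(m) <- "double"
    return(mrna_cohort(m, age))
  }
  if (!"patient_id" %in% names(df)) {
    stop("cohort file needs 'patient_id' (patients x genes) or 'gene' ",
         "(genes x patients) column", call. = FALSE)
  }
  age <- if ("age" %in% names(df)) parse_age(df$age) else rep(NA_real_, nrow(df))
  m <- df[, setdiff(names(df), "age"), drop = FALSE]
  mrna_cohort(m, age)
}

#' Keep paediatric patients only
#'
#' Retains patients with a known age of at most `max_age` years; patients
#' older than that, or with unknown age, are removed and counted by reason.
#'
#' @param cohort An [mrna_cohort()].
#' @param max_age Inclusive age cut-off (default 18).
#' @return The filtered cohort, with attribute `removed` =
#'   `c(over_age = , unknown_age = )`.
#' @export
filter_paediatric <- function(cohort, max_age = 18) {
  stopifnot(inherits(cohort, "mrna_cohort"))
  unknown <- is.na(cohort$age)
  over <- !unknown & cohort$age > max_age
  keep <- !unknown & !over
  if (!any(keep) && nrow(cohort$expr) > 0) {
    warning("no patients remain after the paediatric filter")
  }
  out <- mrna_cohort(cohort$expr[keep, , drop = FALSE], cohort$age[keep])
  attr(out, "removed") <- c(over_age = sum(over), unknown_age = sum(unknown))
  out
}

# type-7 (linear interpolation) quartiles, the convention recorded in the map
.q13 <- function(x) stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)

#' Fit the interquartile mRNA-to-protein map
#'
#' For each protein, the cohort mRNA interquartile range \[Q1, Q3\] is mapped
#' linearly onto the cell-line protein interquartile range. Degenerate IQRs
#' (Q1 = Q3) are flagged and fall back to a constant at the protein median.
#'
#' @param cohort An [mrna_cohort()] (>= 4 patients).
#' @param panel An [expression_panel()] (>= 2 samples).
#' @param policy Out-of-IQR policy: `"linear"` continues the same linear map
#'   beyond the IQR (default); `"clamp"` clamps at the mapped Q1/Q3.
#' @return Object of class `quantile_map`: per-protein `mrna_q1/q3`,
#'   `protein_q1/q3`, `protein_median`, `degenerate`, plus `policy` and the
#'   quantile convention.
#' @export
fit_quantile_map <- function(cohort, panel, policy = c("linear", "clamp")) {
  stopifnot(inherits(cohort, "mrna_cohort"), inherits(panel, "expression_panel"))
  policy <- match.arg(policy)
  if (nrow(cohort$expr) < 4) stop("need >= 4 patients per gene", call. = FALSE)
  if (nrow(panel$expr) < 2) stop("need >= 2 panel samples per protein", call. = FALSE)
  proteins <- apoptosis_proteins
  mq <- apply(cohort$expr[, proteins, drop = FALSE], 2, .q13)
  pq <- apply(panel$expr[, proteins, drop = FALSE], 2, .q13)
  degenerate <- mq[2, ] <= mq[1, ] | pq[2, ] <= pq[1, ]
  if (any(degenerate)) {
    warning("degenerate IQR; median-matching fallback for: ",
            paste(proteins[degenerate], collapse = ", "))
  }
  structure(list(
    mrna_q1 = mq[1, ], mrna_q3 = mq[2, ],
    protein_q1 = pq[1, ], protein_q3 = pq[2, ],
    protein_median = apply(panel$expr[, proteins, drop = FALSE], 2, stats::median),
    degenerate = degenerate, policy = policy, quantile_type = 7L
  ), class = "quantile_map")
}

#' Infer HeLa-relative protein profiles from patient mRNA
#'
#' Applies the fitted per-protein linear interquartile map. Values beyond
#' the mRNA IQR follow the map's out-of-range policy; inferred values below
#' zero are clipped to zero with a warning (linear extrapolation can
#' undershoot).
#'
#' @param cohort An [mrna_cohort()] (or single named mRNA vector).
#' @param map A `quantile_map` from [fit_quantile_map()].
#' @return An (unlabelled) [expression_panel()] of inferred profiles.
#' @export
infer_protein_profiles <- function(cohort, map) {
  stopifnot(inherits(map, "quantile_map"))
  m <- if (inherits(cohort, "mrna_cohort")) cohort$expr else {
    names(cohort) <- canonical_protein(names(cohort))
    matrix(cohort[apoptosis_proteins], nrow = 1,
           dimnames = list("patient", apoptosis_proteins))
  }
  missing <- setdiff(apoptosis_proteins, colnames(m))
  if (length(missing)) stop("missing gene(s): ", paste(missing, collapse = ", "),
                            call. = FALSE)
  out <- m
  for (p in apoptosis_proteins) {
    if (map$degenerate[[p]]) {
      out[, p] <- map$protein_median[[p]]
      next
    }
    x <- m[, p]
    if (map$policy == "clamp") {
      x <- pmin(pmax(x, map$mrna_q1[[p]]), map$mrna_q3[[p]])
    }
    slope <- (map$protein_q3[[p]] - map$protein_q1[[p]]) /
      (map$mrna_q3[[p]] - map$mrna_q1[[p]])
    out[, p] <- map$protein_q1[[p]] + slope * (x - map$mrna_q1[[p]])
  }
  if (any(out < 0)) {
    warning(sum(out < 0), " inferred value(s) below 0 clipped to 0")
    out[out < 0] <- 0
  }
  expression_panel(out)
}

#' Project a patient cohort into the fitted sensitivity space
#'
#' Full chain: infer protein profiles via the interquartile map, compute
#' functional groups, z-score with the cell-line training parameters (not
#' cohort-refitted ones), project onto the stored components, classify.
#'
#' @param cohort An [mrna_cohort()] (already age-filtered if desired).
#' @param model A fitted `sensitivity_model`.
#' @param map A fitted `quantile_map`.
#' @return List: `patients` (classification data frame as in [classify()]),
#'   `summary` (data frame of per-label `count` and `fraction`).
#' @export
project_cohort <- function(cohort, model, map) {
  inferred <- infer_protein_profiles(cohort, map)
  res <- classify(model, inferred)
  counts <- table(factor(res$label, levels = model$lda$classes))
  summ <- data.frame(label = names(counts),
                     count = as.integer(counts),
                     fraction = as.numeric(counts) / max(1L, nrow(res)),
                     stringsAsFactors = FALSE)
  list(patients = res, summary = summ)
}
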