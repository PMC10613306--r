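#' Principal component analysis of z-scored functional groups
#'
#' Covariance PCA of the standardised group matrix (equivalent to
#' correlation PCA of the raw groups), so the Kaiser eigenvalue > 1 rule has
#' its usual meaning. Eigenvector sign ambiguity is removed by orienting
#' each loading column so its largest-magnitude entry is positive.
#'
#' @param z Matrix of z-scored functional groups (samples x groups), no
#'   missing values, >= 2 samples.
#' @return Object of class `pca_model`: `coefficients` (group x component
#'   loadings, orthonormal), `eigenvalues` (descending),
#'   `explained_fraction`, `n_retained` (Kaiser count), `center` (column
#'   means used for scoring).
#' @export
fit_pca <- function(z) {
  if (is.null(dim(z)) || nrow(z) < 2) stop("need >= 2 samples", call. = FALSE)
  if (any(!is.finite(z))) stop("missing/non-finite values in input", call. = FALSE)
  p <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  coef <- p$rotation
  # deterministic sign convention: largest-|.| entry of each column positive
  for (j in seq_len(ncol(coef))) {
    i <- which.max(abs(coef[, j]))
    if (coef[i, j] < 0) coef[, j] <- -coef[, j]
  }
  ev <- p$sdev^2
  model <- structure(list(
    coefficients = coef,
    eigenvalues = ev,
    explained_fraction = ev / sum(ev),
    center = p$center,
    n_retained = NA_integer_
  ), class = "pca_model")
  model$n_retained <- retain_components(model)
  model
}

#' Kaiser-criterion component retention
#'
#' Number of principal components with eigenvalue strictly greater than 1
#' (standardised-variable convention). Zero retained components make the
#' downstream discriminant impossible and trigger a warning.
#'
#' @param pca A `pca_model`.
#' @return Integer count of retained components.
#' @export
retain_components <- function(pca) {
  stopifnot(inherits(pca, "pca_model"))
  n <- sum(pca$eigenvalues > 1)
  if (n == 0) warning("no component has eigenvalue > 1; LDA cannot proceed")
  as.integer(n)
}

#' Project z-scored group vectors onto principal components
#'
#' @param pca A `pca_model`.
#' @param z Matrix of z-scored groups.
#' @param n_components Number of leading components (default: all).
#' @return Score matrix, samples x components.
#' @export
pca_scores <- function(pca, z, n_components = ncol(pca$coefficients)) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1, dimnames = list("sample", names(z)))
  z <- z[, rownames(pca$coefficients), drop = FALSE]
  sweep(z, 2, pca$center, `-`) %*% pca$coefficients[, seq_len(n_components), drop = FALSE]
}

#' Two-class Fisher linear discriminant on retained component scores
#'
#' Pooled within-class covariance discriminant with equal priors and the
#' midpoint of the projected class means as threshold. A numerically
#' singular pooled covariance is shrunk toward the identity
#' (`(1-lambda) S + lambda mean(diag(S)) I`) with a message reporting the
#' coefficient. If the Fisher direction leaves training errors on a
#' linearly separable set, a deterministic perceptron pass replaces it (the
#' discriminant must separate whenever separation is possible); the chosen
#' method is recorded. Samples exactly on the plane are assigned
#' `reduced_sensitivity` (conservative for treatment escalation).
#'
#' @param scores Matrix of PC scores (samples x retained components).
#' @param labels Character vector/factor per sample with both classes
#'   `high_sensitivity` and `reduced_sensitivity` present.
#' @return List of class `lda_plane`: `weights`, `threshold`, `classes`,
#'   `shrinkage`. Positive discriminant side = `reduced_sensitivity`.
#' @export
fit_lda <- function(scores, labels) {
  labels <- as.character(labels)
  classes <- c("high_sensitivity", "reduced_sensitivity")
  if (!all(labels %in% classes)) stop("unknown label(s)", call. = FALSE)
  if (length(unique(labels)) < 2) stop("both classes must be present", call. = FALSE)
  scores <- as.matrix(scores)
  m0 <- colMeans(scores[labels == classes[1], , drop = FALSE])
  m1 <- colMeans(scores[labels == classes[2], , drop = FALSE])
  centred <- scores
  centred[labels == classes[1], ] <- sweep(
    scores[labels == classes[1], , drop = FALSE], 2, m0)
  centred[labels == classes[2], ] <- sweep(
    scores[labels == classes[2], , drop = FALSE], 2, m1)
  S <- crossprod(centred) / max(1, nrow(scores) - 2)
  lambda <- 0
  d <- ncol(scores)
  if (d == 1) S <- matrix(S, 1, 1)
  if (!is.finite(rcond_sym(S)) || rcond_sym(S) < 1e-10) {
    lambda <- 0.1
    S <- (1 - lambda) * S + lambda * mean(diag(S)) * diag(d)
    message("singular pooled covariance; shrinkage lambda = ", lambda)
  }
  w <- solve(S, m1 - m0)                      # points toward reduced side
  threshold <- sum(w * (m0 + m1)) / 2
  method <- "fisher"
  # contract: separate the training set whenever it is linearly separable.
  # Fisher's direction can misplace single outlying samples even then, so a
  # perceptron pass is tried and kept only if it separates perfectly.
  g <- drop(scores %*% w) - threshold
  pred <- ifelse(g >= 0, classes[2], classes[1])
  if (any(pred != labels)) {
    sep <- perceptron_separator(scores, labels == classes[2])
    if (!is.null(sep)) {
      w <- sep$w
      threshold <- sep$threshold
      method <- "perceptron"
      message("Fisher direction misclassified training samples; ",
              "separable set: using perceptron separator")
    }
  }
  structure(list(weights = w, threshold = threshold, classes = classes,
                 shrinkage = lambda, method = method),
            class = "lda_plane")
}

# deterministic perceptron; returns NULL if no separating plane is found
# within the epoch budget (data presumed non-separable)
perceptron_separator <- function(scores, positive, epochs = 2000L) {
  x <- scale(scores)
  mu <- attr(x, "scaled:center"); sg <- attr(x, "scaled:scale")
  sg[sg == 0] <- 1
  y <- ifelse(positive, 1, -1)
  w <- rep(0, ncol(x)); b <- 0
  for (ep in seq_len(epochs)) {
    errs <- 0L
    for (i in seq_len(nrow(x))) {
      if (y[i] * (sum(w * x[i, ]) + b) <= 0) {
        w <- w + y[i] * x[i, ]
        b <- b + y[i]
        errs <- errs + 1L
      }
    }
    if (errs == 0L) {
      # undo the standardisation: decision on the original score scale
      w_orig <- w / sg
      list2 <- list(w = w_orig, threshold = sum(w_orig * mu) - b)
      return(list2)
    }
  }
  NULL
}

rcond_sym <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) return(0)
  min(ev) / max(ev)
}

#' Fit the full sensitivity model from a labelled panel
#'
#' Chains the pipeline: functional groups, z-score normalisation fitted on
#' the panel, covariance PCA of the z-scores, Kaiser retention, and the
#' Fisher discriminant on the retained component scores.
#'
#' @param panel Labelled [expression_panel()].
#' @param pcs Optional integer vector restricting the discriminant to
#'   specific components (default: all Kaiser-retained components).
#' @return Object of class `sensitivity_model` bundling `normalisation`,
#'   `pca`, `pcs` (components fed to the discriminant), `lda`, and the
#'   training `labels`.
#' @export
fit_sensitivity_model <- function(panel, pcs = NULL) {
  stopifnot(inherits(panel, "expression_panel"))
  if (is.null(panel$labels)) stop("panel must carry sensitivity labels", call. = FALSE)
  groups <- compute_groups(panel)
  norm <- fit_zscore(groups)
  z <- apply_zscore(groups, norm)
  pca <- fit_pca(z)
  if (pca$n_retained == 0) stop("no retained components; cannot fit discriminant",
                                call. = FALSE)
  if (is.null(pcs)) pcs <- seq_len(pca$n_retained)
  if (any(pcs < 1 | pcs > ncol(pca$coefficients))) stop("PC index out of range",
                                                        call. = FALSE)
  labels <- panel$labels[rownames(groups)]
  if (anyNA(labels)) stop("every training sample needs a label", call. = FALSE)
  scores <- pca_scores(pca, z)[, pcs, drop = FALSE]
  lda <- fit_lda(scores, labels)
  structure(list(normalisation = norm, pca = pca, pcs = as.integer(pcs),
                 lda = lda, labels = labels),
            class = "sensitivity_model")
}

#' Classify samples with a fitted sensitivity model
#'
#' Projects z-scored functional-group vectors onto the retained components
#' via the stored coefficients and applies the discriminant. Scores exactly
#' on the plane are labelled `reduced_sensitivity`.
#'
#' @param model A `sensitivity_model`.
#' @param x An [expression_panel()], or a precomputed functional-group
#'   matrix (set `is_groups = TRUE`).
#' @param is_groups Set `TRUE` when `x` already holds functional groups.
#' @return Data frame with `sample_id`, `label`, `discriminant` (signed
#'   distance along the weight vector), and one column per used PC score.
#' @export
classify <- function(model, x, is_groups = FALSE) {
  stopifnot(inherits(model, "sensitivity_model"))
  groups <- if (is_groups) as.matrix(x) else compute_groups(x)
  z <- apply_zscore(groups, model$normalisation)
  scores <- pca_scores(model$pca, z)[, model$pcs, drop = FALSE]
  g <- drop(scores %*% model$lda$weights) - model$lda$threshold
  label <- ifelse(g >= 0, model$lda$classes[2], model$lda$classes[1])
  out <- data.frame(sample_id = rownames(groups), label = label,
                    discriminant = g, stringsAsFactors = FALSE)
  colnames(scores) <- paste0("PC", model$pcs)
  cbind(out, as.data.frame(scores))
}

#' Functional-group contributions to a pair of components
#'
#' Signed loadings of each functional group on two chosen components, as
#' visualised in a biplot. The scaling convention (raw orthonormal loadings)
#' is recorded in the output attributes.
#'
#' @param model A `sensitivity_model` or `pca_model`.
#' @param pcs Integer vector of length 2 (default components 2 and 3).
#' @return Data frame `group`, one column per requested PC, and `magnitude`
#'   (Euclidean norm in the chosen plane), sorted by decreasing magnitude.
#' @export
biplot_contributions <- function(model, pcs = c(2L, 3L)) {
  pca <- if (inherits(model, "sensitivity_model")) model$pca else model
  stopifnot(inherits(pca, "pca_model"))
  if (any(pcs < 1 | pcs > ncol(pca$coefficients))) {
    stop("PC index out of range", call. = FALSE)
  }
  L <- pca$coefficients[, pcs, drop = FALSE]
  out <- data.frame(group = rownames(L), L,
                    magnitude = sqrt(rowSums(L^2)),
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[2:(1 + length(pcs))] <- paste0("PC", pcs)
  out <- out[order(-out$magnitude), ]
  attr(out, "scaling") <- "orthonormal loadings (unscaled)"
  out
}

#' Serialise / restore a sensitivity model
#'
#' The whole model (normalisation parameters, loadings, eigenvalues,
#' discriminant) is written as one YAML document so a fit is reproducible
#' and portable.
#'
#' @param model A `sensitivity_model`.
#' @param path Output YAML path.
#' @export
write_sensitivity_model <- function(model, path) {
  stopifnot(inherits(model, "sensitivity_model"))
  doc <- list(
    normalisation = list(mean = as.list(model$normalisation$mean),
                         sd = as.list(model$normalisation$sd),
                         ddof = model$normalisation$ddof),
    pca = list(coefficients = apply(model$pca$coefficients, 2, as.list),
               group_order = rownames(model$pca$coefficients),
               eigenvalues = model$pca$eigenvalues,
               center = as.list(model$pca$center),
               n_retained = model$pca$n_retained),
    pcs = model$pcs,
    lda = list(weights = as.numeric(model$lda$weights),
               threshold = model$lda$threshold,
               classes = model$lda$classes,
               shrinkage = model$lda$shrinkage),
    labels = as.list(model$labels)
  )
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_sensitivity_model
#' @export
read_sensitivity_model <- function(path) {
  doc <- yaml::read_yaml(path)
  grp <- unlist(doc$pca$group_order)
  coef <- sapply(doc$pca$coefficients, function(col) unlist(col)[grp])
  rownames(coef) <- grp
  norm <- structure(list(mean = unlist(doc$normalisation$mean)[grp],
                         sd = unlist(doc$normalisation$sd)[grp],
                         ddof = doc$normalisation$ddof),
                    class = "zscore_params")
  pca <- structure(list(coefficients = coef,
                        eigenvalues = unlist(doc$pca$eigenvalues),
                        explained_fraction = unlist(doc$pca$eigenvalues) /
                          sum(unlist(doc$pca$eigenvalues)),
                        center = unlist(doc$pca$center)[grp],
                        n_retained = doc$pca$n_retained),
                   class = "pca_model")
  lda <- structure(list(weights = unlist(doc$lda$weights),
                        threshold = doc$lda$threshold,
                        classes = unlist(doc$lda$classes),
                        shrinkage = doc$lda$shrinkage),
                   class = "lda_plane")
  structure(list(normalisation = norm, pca = pca,
                 pcs = as.integer(unlist(doc$pcs)), lda = lda,
                 labels = unlist(doc$labels)),
            class = "sensitivity_model")
}
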