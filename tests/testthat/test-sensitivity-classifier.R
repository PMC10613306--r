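test_that("PCA eigenvalues match a brute-force covariance eigendecomposition", {
  set.seed(11)
  for (i in 1:5) {
    z <- matrix(rnorm(6 * 9), 6, 9, dimnames = list(NULL, functional_group_names))
    z <- scale(z)
    pca <- fit_pca(z)
    k <- length(pca$eigenvalues)          # prcomp returns min(n, p) components
    oracle <- eigen(cov(z), symmetric = TRUE)$values
    informative <- oracle[seq_len(k)] > 1e-8   # rank is n-1 < p here
    expect_equal(pca$eigenvalues[informative],
                 oracle[seq_len(k)][informative], tolerance = 1e-8)
    expect_lt(max(abs(oracle[!seq_len(length(oracle)) %in% which(informative)])),
              1e-8)
    expect_equal(sum(pca$explained_fraction), 1)
    # loadings orthonormal; reconstruction with all components exact
    expect_equal(crossprod(pca$coefficients),
                 diag(ncol(pca$coefficients)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    scores <- pca_scores(pca, z)
    recon <- scores %*% t(pca$coefficients)
    expect_equal(recon + rep(1, 6) %o% pca$center, unclass(z),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("perfectly correlated two-variable toy loads on one component", {
  x <- c(-1.5, -0.5, 0.5, 1.5)
  z <- cbind(a = x, b = 2 * x)
  pca <- fit_pca(z)
  expect_equal(pca$explained_fraction[1], 1)
})

test_that("PCA is invariant to sample order and has a fixed sign convention", {
  z <- scale(matrix(rnorm(54), 6, 9, dimnames = list(NULL, functional_group_names)))
  set.seed(2)
  perm <- sample(6)
  p1 <- fit_pca(z); p2 <- fit_pca(z[perm, ])
  expect_equal(p1$eigenvalues, p2$eigenvalues)
  informative <- which(p1$eigenvalues > 1e-8)   # null-space vectors are arbitrary
  expect_equal(p1$coefficients[, informative], p2$coefficients[, informative])
  # largest-magnitude entry of each informative loading column is positive
  for (j in informative) {
    col <- p1$coefficients[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
})

test_that("Kaiser retention counts eigenvalues strictly above 1", {
  fake <- structure(list(eigenvalues = c(2.1, 1.3, 0.9)), class = "pca_model")
  expect_identical(retain_components(fake), 2L)
  fake2 <- structure(list(eigenvalues = c(0.5, 0.3)), class = "pca_model")
  expect_warning(n <- retain_components(fake2), "LDA cannot proceed")
  expect_identical(n, 0L)
})

test_that("LDA separates well-separated Gaussian clouds with 100% training accuracy", {
  set.seed(99)
  n <- 20
  scores <- rbind(matrix(rnorm(2 * n), n),            # class 0 at origin
                  matrix(rnorm(2 * n, mean = 6), n))  # class 1 at (6, 6)
  labels <- rep(c("high_sensitivity", "reduced_sensitivity"), each = n)
  plane <- fit_lda(scores, labels)
  g <- drop(scores %*% plane$weights) - plane$threshold
  pred <- ifelse(g >= 0, "reduced_sensitivity", "high_sensitivity")
  expect_identical(pred, labels)
})

test_that("LDA direction agrees with the reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(5)
  scores <- rbind(matrix(rnorm(30), 15), matrix(rnorm(30, 6), 15))
  labels <- rep(c("high_sensitivity", "reduced_sensitivity"), each = 15)
  plane <- fit_lda(scores, labels)
  expect_identical(plane$method, "fisher")   # no separability fallback here
  ref <- MASS::lda(scores, grouping = labels)
  # same direction up to positive scale
  cosine <- sum(plane$weights * ref$scaling) /
    sqrt(sum(plane$weights^2) * sum(ref$scaling^2))
  expect_equal(abs(cosine), 1, tolerance = 1e-6)
})

test_that("degenerate label sets are rejected", {
  scores <- matrix(rnorm(10), 5)
  expect_error(fit_lda(scores, rep("high_sensitivity", 5)), "both classes")
  expect_error(fit_lda(scores, rep("mystery", 5)), "unknown label")
})

test_that("classification reproduces training labels and hand-computed projections", {
  panel <- generate_panel(5, 4, separation = 4, seed = 21)
  model <- fit_sensitivity_model(panel)
  res <- classify(model, panel)
  expect_identical(stats::setNames(res$label, res$sample_id), panel$labels)
  # hand-computed projection for the first sample
  g <- compute_groups(panel)
  z <- apply_zscore(g, model$normalisation)
  manual <- drop((z[1, ] - model$pca$center) %*%
                   model$pca$coefficients[, model$pcs])
  expect_equal(unname(unlist(res[1, paste0("PC", model$pcs)])),
               unname(manual))
  manual_g <- sum(manual * model$lda$weights) - model$lda$threshold
  expect_equal(res$discriminant[1], manual_g)
  # tie-break: a score vector exactly on the plane goes to reduced_sensitivity
  w <- model$lda$weights
  on_plane_score <- model$lda$threshold * w / sum(w^2)
  gv <- sum(on_plane_score * w) - model$lda$threshold
  expect_equal(gv, 0, tolerance = 1e-12)
  expect_identical(ifelse(gv >= 0, model$lda$classes[2], model$lda$classes[1]),
                   "reduced_sensitivity")
})

test_that("biplot contributions expose the stored loadings with recorded scaling", {
  panel <- generate_panel(4, 2, separation = 3, seed = 8)
  model <- fit_sensitivity_model(panel)
  bc <- biplot_contributions(model, pcs = c(2, 3))
  expect_setequal(bc$group, functional_group_names)
  i <- match(bc$group, rownames(model$pca$coefficients))
  expect_equal(bc$PC2, unname(model$pca$coefficients[i, 2]))
  expect_equal(bc$PC3, unname(model$pca$coefficients[i, 3]))
  expect_match(attr(bc, "scaling"), "loadings")
  expect_error(biplot_contributions(model, pcs = c(2, 99)), "out of range")
})

test_that("model serialisation round-trips through YAML", {
  panel <- generate_panel(4, 2, separation = 3, seed = 13)
  model <- fit_sensitivity_model(panel)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sensitivity_model(model, path)
  back <- read_sensitivity_model(path)
  res1 <- classify(model, panel)
  res2 <- classify(back, panel)
  expect_equal(res1$discriminant, res2$discriminant, tolerance = 1e-9)
  expect_identical(res1$label, res2$label)
})
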