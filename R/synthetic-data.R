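#' Generate a synthetic cell-line expression panel with planted labels
#'
#' Baseline relative expression is log-normal per protein (positive and
#' right-skewed around the HeLa reference; unit median, `sdlog` 0.5).
#' Reduced-sensitivity samples receive a planted class effect on the
#' drivers of the discriminating plane: elevated anti-apoptotic proteins
#' (BCL2, BCLXL, MCL1) and reduced SMAC and BID, shifted on the log scale
#' by `separation` within-class standard deviations.
#'
#' @param n_high,n_reduced Samples per class (>= 1 each).
#' @param separation Class separation `s` (>= 0) in within-class sd units.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param sdlog Log-scale within-class standard deviation (default 0.5).
#' @return A labelled [expression_panel()].
#' @export
generate_panel <- function(n_high, n_reduced, separation = 3, seed = 1,
                           sdlog = 0.5) {
  stopifnot(n_high >= 1, n_reduced >= 1, separation >= 0)
  n <- n_high + n_reduced
  with_local_seed(seed, {
    expr <- matrix(stats::rlnorm(n * 14, meanlog = 0, sdlog = sdlog),
                   nrow = n, dimnames = list(NULL, apoptosis_proteins))
    up <- c("BCL2", "BCLXL", "MCL1")
    down <- c("SMAC", "BID")
    idx <- seq(n_high + 1, n)
    expr[idx, up] <- expr[idx, up] * exp(separation * sdlog)
    expr[idx, down] <- expr[idx, down] * exp(-separation * sdlog)
    rownames(expr) <- c(sprintf("high_%02d", seq_len(n_high)),
                        sprintf("red_%02d", seq_len(n_reduced)))
    labels <- stats::setNames(
      rep(c("high_sensitivity", "reduced_sensitivity"), c(n_high, n_reduced)),
      rownames(expr))
    expression_panel(expr, labels = labels)
  })
}

# run code under a locally-seeded RNG without disturbing the caller's stream
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Deterministic synthetic stand-in for the six-line training panel
#'
#' A fixed-seed synthetic panel carrying the six medulloblastoma cell-line
#' names used throughout the documentation, with ONS76 and UW228 planted as
#' the reduced-sensitivity pair. This is synthetic data emulating the
#' qualitative expression structure of that panel (anti-apoptotic proteins
#' up, SMAC/BID down in the reduced pair), not measured values.
#'
#' @param separation Planted class separation (default 3).
#' @return A labelled [expression_panel()] of 6 samples.
#' @export
synthetic_cellline_panel <- function(separation = 3) {
  panel <- generate_panel(n_high = 4, n_reduced = 2, separation = separation,
                          seed = 20231028)
  ids <- c("Daoy", "D425-Med", "D458-Med", "D283-Med", "ONS76", "UW228")
  rownames(panel$expr) <- ids
  names(panel$labels) <- ids
  panel
}

#' Generate a synthetic patient mRNA cohort coupled to latent protein levels
#'
#' Latent per-patient protein profiles are drawn log-normally around the
#' cell-line panel's per-protein medians; mRNA is generated through a
#' Gaussian copula so the mRNA-protein Spearman rank correlation hits the
#' target `rho` (the Pearson correlation of the underlying normal scores is
#' set to `2*sin(pi*rho/6)`). Ages include >18 and unknown entries so the
#' paediatric filter is exercised.
#'
#' @param n_patients Number of patients.
#' @param panel An [expression_panel()] anchoring the latent protein scale.
#' @param rho Target Spearman correlation between mRNA and latent protein,
#'   in \[0, 1\].
#' @param seed Integer seed.
#' @param frac_adult,frac_unknown Fractions of patients given age > 18 or
#'   unknown age (defaults 0.15 and 0.05).
#' @return List: `cohort` (an [mrna_cohort()]), `latent` (matrix of true
#'   protein profiles, patients x proteins).
#' @export
generate_cohort <- function(n_patients, panel, rho = 0.8, seed = 1,
                            frac_adult = 0.15, frac_unknown = 0.05) {
  stopifnot(rho >= 0, rho <= 1, inherits(panel, "expression_panel"))
  r <- if (rho >= 1) 1 else 2 * sin(pi * rho / 6)
  med <- apply(panel$expr, 2, stats::median)
  with_local_seed(seed, {
    zp <- matrix(stats::rnorm(n_patients * 14), n_patients)
    eps <- matrix(stats::rnorm(n_patients * 14), n_patients)
    zm <- r * zp + sqrt(max(0, 1 - r^2)) * eps
    latent <- sweep(exp(0.5 * zp), 2, med, `*`)
    # platform-scale mRNA: arbitrary affine log-intensity scale per gene
    mrna <- 8 + 1.5 * zm
    colnames(latent) <- colnames(mrna) <- apoptosis_proteins
    rownames(latent) <- rownames(mrna) <- sprintf("P%03d", seq_len(n_patients))
    age <- stats::runif(n_patients, 1, 18)
    n_ad <- round(frac_adult * n_patients)
    n_un <- round(frac_unknown * n_patients)
    which_special <- sample.int(n_patients, n_ad + n_un)
    age[which_special[seq_len(n_ad)]] <- stats::runif(n_ad, 19, 70)
    if (n_un > 0) age[which_special[n_ad + seq_len(n_un)]] <- NA
    list(cohort = mrna_cohort(mrna, age), latent = latent)
  })
}

#' Generate a synthetic JC-1 BH3-profiling plate
#'
#' Per condition, triplicate exponential-decay 590 nm traces
#' `baseline * ((1 - d) + d * exp(-t/tau))` with multiplicative Gaussian
#' noise, where `d` in \[0, 1\] is the true depolarisation fraction (DMSO
#' anchor d = 0, FCCP anchor d = 1). The truth is returned alongside.
#'
#' @param conditions Named numeric vector of true depolarisation fractions;
#'   must include `DMSO` and `FCCP`.
#' @param seed Integer seed.
#' @param n_reps Replicate wells per condition (default 3).
#' @param sigma Multiplicative noise sd (default 0.01).
#' @param interval,duration Sampling interval and assay length in minutes
#'   (defaults 5 and 180, i.e. readings every 5 min over 3 h).
#' @param tau Decay time constant in minutes (default 45).
#' @return List: `kinetics` (long data frame `well`, `time_min`, `rfu`),
#'   `plate_map` (`well`, `condition`), `truth` (the `conditions` vector).
#' @export
generate_jc1_plate <- function(conditions, seed = 1, n_reps = 3, sigma = 0.01,
                               interval = 5, duration = 180, tau = 45) {
  if (!all(c("DMSO", "FCCP") %in% names(conditions))) {
    stop("conditions must include DMSO and FCCP anchors", call. = FALSE)
  }
  stopifnot(all(conditions >= 0), all(conditions <= 1))
  time <- seq(0, duration, by = interval)
  baseline <- 1000
  with_local_seed(seed, {
    rows <- list(); map <- list(); w <- 0L
    for (cond in names(conditions)) {
      d <- conditions[[cond]]
      for (rep in seq_len(n_reps)) {
        w <- w + 1L
        well <- sprintf("W%03d", w)
        clean <- baseline * ((1 - d) + d * exp(-time / tau))
        rfu <- clean * exp(stats::rnorm(length(time), 0, sigma))
        rows[[w]] <- data.frame(well = well, time_min = time, rfu = rfu)
        map[[w]] <- data.frame(well = well, condition = cond)
      }
    }
    list(kinetics = do.call(rbind, rows), plate_map = do.call(rbind, map),
         truth = conditions)
  })
}

#' Summarise a synthetic (or real) JC-1 plate into per-peptide responses
#'
#' Averages replicate traces per condition and anchors each non-control
#' condition between DMSO and FCCP via [depolarisation()].
#'
#' @param kinetics Long data frame `well`, `time_min`, `rfu`.
#' @param plate_map Data frame `well`, `condition`.
#' @param mode Passed to [depolarisation()].
#' @return Named numeric vector: percent depolarisation per condition
#'   (anchors excluded).
#' @export
bh3_plate_responses <- function(kinetics, plate_map, mode = "auc") {
  cond_of <- stats::setNames(plate_map$condition, plate_map$well)
  kinetics$condition <- cond_of[kinetics$well]
  time <- sort(unique(kinetics$time_min))
  mean_trace <- function(cond) {
    k <- kinetics[kinetics$condition == cond, ]
    as.numeric(tapply(k$rfu, k$time_min, mean)[as.character(time)])
  }
  conds <- unique(plate_map$condition)
  if (!all(c("DMSO", "FCCP") %in% conds)) {
    stop("plate must contain DMSO and FCCP anchor conditions", call. = FALSE)
  }
  dmso <- mean_trace("DMSO"); fccp <- mean_trace("FCCP")
  peptides <- setdiff(conds, c("DMSO", "FCCP"))
  stats::setNames(
    vapply(peptides, function(p) depolarisation(time, mean_trace(p), dmso,
                                                fccp, mode = mode), 0),
    peptides)
}

#' Generate a synthetic dose-response table from known 4PL parameters
#'
#' Log-spaced doses bracketing the true IC50 (two decades either side) plus
#' vehicle wells, with multiplicative Gaussian noise.
#'
#' @param ic50,slope,top,bottom True four-parameter logistic parameters.
#' @param n_doses Number of non-zero doses (default 8).
#' @param reps Replicates per dose (>= 1).
#' @param sigma Multiplicative noise sd (0 = noise-free).
#' @param seed Integer seed.
#' @return List: `dr` (a `dose_response` data frame), `truth` (named
#'   parameter vector).
#' @export
generate_dose_response <- function(ic50, slope = 1, top = 1, bottom = 0,
                                   n_doses = 8, reps = 2, sigma = 0.05,
                                   seed = 1) {
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  stopifnot(ic50 > 0, n_doses >= 4)
  doses <- rep(c(0, exp(seq(log(ic50 / 100), log(ic50 * 100),
                            length.out = n_doses))), each = reps)
  truth <- c(ic50 = ic50, slope = slope, top = top, bottom = bottom)
  with_local_seed(seed, {
    mu <- ifelse(doses == 0, top,
                 bottom + (top - bottom) / (1 + (doses / ic50)^slope))
    v <- mu * exp(stats::rnorm(length(doses), 0, sigma))
    dr <- data.frame(dose = doses, viability = v)
    class(dr) <- c("dose_response", "data.frame")
    list(dr = dr, truth = truth)
  })
}
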