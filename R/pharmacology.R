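#' Vehicle-normalised viability from plate absorbance
#'
#' Per well, the 620 nm background is subtracted from the 450 nm signal and
#' the result divided by the mean background-corrected signal of the vehicle
#' wells, so the vehicle mean is 1 by construction.
#'
#' @param dose Numeric vector of doses (uM), one per well; vehicle wells
#'   carry dose 0.
#' @param a450,a620 Per-well absorbances at 450 nm and 620 nm.
#' @return Data frame of class `dose_response`: `dose`, `viability`
#'   (replicate-resolved, sorted by dose).
#' @export
normalise_viability <- function(dose, a450, a620) {
  stopifnot(length(dose) == length(a450), length(dose) == length(a620))
  if (!any(dose == 0)) stop("no vehicle (dose 0) wells present", call. = FALSE)
  signal <- a450 - a620
  vehicle <- mean(signal[dose == 0])
  if (!is.finite(vehicle) || vehicle <= 0) {
    stop("non-positive vehicle signal", call. = FALSE)
  }
  out <- data.frame(dose = dose, viability = signal / vehicle)
  out <- out[order(out$dose), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dose_response", "data.frame")
  out
}

#' Four-parameter log-logistic IC50 fit
#'
#' Fits `viability = bottom + (top - bottom) / (1 + (dose/IC50)^slope)`
#' (the variable-slope inhibition model) by Levenberg-Marquardt least
#' squares, with `top` left free rather than fixed at 1. IC50 is the dose
#' of half-maximal response between the fitted top and bottom. Start points
#' come from the data (top = max, bottom = min, IC50 = dose nearest the
#' half-response, slope = 1), making the fit deterministic.
#'
#' @param dr A `dose_response` data frame (`dose`, `viability`), >= 4
#'   distinct doses.
#' @return List of class `dose_response_fit`: `ic50`, `slope`, `top`,
#'   `bottom`, `converged`, `rss`, and the `fit` object. A monotone
#'   *increasing* dose-viability trend triggers a warning; non-convergence
#'   returns a flagged (not thrown) result.
#' @export
fit_ic50 <- function(dr) {
  dose <- dr$dose; v <- dr$viability
  if (length(unique(dose)) < 4) stop("need >= 4 distinct doses", call. = FALSE)
  if (stats::sd(v) == 0) stop("viability is constant; nothing to fit", call. = FALSE)
  mu <- tapply(v, dose, mean)
  du <- as.numeric(names(mu))
  if (all(diff(mu[order(du)]) >= 0)) {
    warning("viability increases with dose; IC50 is not meaningful")
  }
  pos <- sort(unique(dose[dose > 0]))
  half <- (max(mu) + min(mu)) / 2
  ic50_0 <- pos[which.min(abs(mu[as.character(pos)] - half))]
  if (!length(ic50_0) || is.na(ic50_0)) ic50_0 <- stats::median(pos)
  start <- list(top = max(mu), bottom = min(mu),
                log_ic50 = log(ic50_0), slope = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      viability ~ bottom + (top - bottom) / (1 + (dose / exp(log_ic50))^slope),
      data = data.frame(dose = dose, viability = v),
      start = start,
      lower = c(top = -Inf, bottom = -Inf, log_ic50 = log(min(pos)) - 10,
                slope = 0.05),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(ic50 = NA_real_, slope = NA_real_, top = NA_real_,
                          bottom = NA_real_, converged = FALSE,
                          rss = NA_real_, message = conditionMessage(fit)),
                     class = "dose_response_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(ic50 = exp(cf[["log_ic50"]]), slope = cf[["slope"]],
                 top = cf[["top"]], bottom = cf[["bottom"]],
                 converged = fit$convInfo$isConv %||% TRUE,
                 rss = sum(stats::resid(fit)^2), fit = fit),
            class = "dose_response_fit")
}

#' Webb fractional-product synergy score
#'
#' Compares the observed fractional viability of a drug combination with
#' the product of the single-agent fractional viabilities:
#' `score = fAB / (fA * fB)`. A score of 1 is additive, above 1 antagonism,
#' below 1 synergy; below 0.8 strong synergy and 0.8-1 weak synergy.
#'
#' @param fA,fB Single-agent fractional viabilities in (0, 1].
#' @param fAB Combination fractional viability in \[0, 1\].
#' @param tol Tolerance within which the score counts as exactly additive.
#' @return List of class `synergy_result`: `score`, `category` in
#'   `strong_synergy`, `weak_synergy`, `additive`, `antagonism`.
#' @export
webb_score <- function(fA, fB, fAB, tol = 1e-9) {
  if (any(c(fA, fB) <= 0)) stop("single-agent fractions must be > 0 ",
                                "(score undefined at 0)", call. = FALSE)
  if (fA > 1 || fB > 1 || fAB < 0 || fAB > 1) {
    stop("fractions must lie in (0,1] / [0,1]", call. = FALSE)
  }
  score <- fAB / (fA * fB)
  category <- if (abs(score - 1) <= tol) "additive"
  else if (score < 0.8) "strong_synergy"
  else if (score < 1) "weak_synergy"
  else "antagonism"
  structure(list(score = score, category = category), class = "synergy_result")
}

#' Percent mitochondrial depolarisation from JC-1 kinetic traces
#'
#' Summarises each 590 nm trace by its area under the curve over the assay
#' window (trapezoid rule; `mode = "endpoint"` uses the final reading
#' instead) and anchors it between the DMSO control (0% depolarisation,
#' highest retained signal) and FCCP (100%):
#' `percent = 100 * (S_dmso - S_peptide) / (S_dmso - S_fccp)`.
#' Values are deliberately not clamped to \[0, 100\]; out-of-range values
#' are real signals of anchor noise.
#'
#' @param time Common time grid (minutes).
#' @param peptide,dmso,fccp Fluorescence traces on that grid.
#' @param mode Summary statistic: `"auc"` (default) or `"endpoint"`.
#' @return Percent depolarisation (numeric scalar).
#' @export
depolarisation <- function(time, peptide, dmso, fccp, mode = c("auc", "endpoint")) {
  mode <- match.arg(mode)
  n <- length(time)
  stopifnot(length(peptide) == n, length(dmso) == n, length(fccp) == n)
  summarise <- switch(mode,
    auc = function(y) sum(diff(time) * (utils::head(y, -1) + utils::tail(y, -1)) / 2),
    endpoint = function(y) y[n])
  s_pep <- summarise(peptide); s_dmso <- summarise(dmso); s_fccp <- summarise(fccp)
  if (isTRUE(all.equal(s_dmso, s_fccp))) {
    stop("degenerate anchors: DMSO and FCCP summaries coincide", call. = FALSE)
  }
  100 * (s_dmso - s_pep) / (s_dmso - s_fccp)
}

#' Change in priming between two BH3 profiles (dynamic profiling)
#'
#' Per-peptide difference `treated - baseline` in percent depolarisation;
#' positive deltas indicate increased dependence/priming after treatment.
#'
#' @param baseline,treated Named numeric vectors (peptide -> percent
#'   depolarisation) over the same peptide set.
#' @return Named numeric vector of deltas.
#' @export
delta_priming <- function(baseline, treated) {
  only_b <- setdiff(names(baseline), names(treated))
  only_t <- setdiff(names(treated), names(baseline))
  if (length(only_b) || length(only_t)) {
    stop("peptide sets differ; only in baseline: ",
         paste(only_b, collapse = ", "), "; only in treated: ",
         paste(only_t, collapse = ", "), call. = FALSE)
  }
  treated[names(baseline)] - baseline
}
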