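# shared fixtures built in code

# tiny deterministic panel: all-ones HeLa-like rows with named tweaks
toy_panel <- function(n = 3, tweaks = list(), labels = NULL) {
  expr <- matrix(1, n, 14, dimnames = list(paste0("S", seq_len(n)),
                                           apoptosis_proteins))
  for (i in seq_along(tweaks)) {
    tw <- tweaks[[i]]
    expr[tw$sample, tw$protein] <- tw$value
  }
  expression_panel(expr, labels = labels)
}

# minimal surrogate config built directly (independent of the packaged YAML)
toy_surrogate_config <- function(kd, theta = 0.1, eta_upper = 1000) {
  structure(list(
    kd = kd,
    mimetic_kd = list(
      ABT199 = c(BCL2 = 1e-5, BCLXL = Inf, MCL1 = Inf),
      WEHI539 = c(BCL2 = Inf, BCLXL = 1.1e-3, MCL1 = Inf),
      S63845 = c(BCL2 = Inf, BCLXL = Inf, MCL1 = 2e-4)),
    theta = theta, tol = 1e-10, max_iter = 100000L,
    eta_upper = eta_upper, eta_tol = 1e-6,
    caspase_rates = default_surrogate_config()$caspase_rates
  ), class = "surrogate_config")
}

# Kd matrix where only BCL2-BAX bind (1:1 toy); other pairs inert
kd_single_pair <- function(K) {
  kd <- matrix(Inf, 3, 3, dimnames = list(c("BAX", "BAK", "ACT"),
                                          c("BCL2", "BCLXL", "MCL1")))
  kd["BAX", "BCL2"] <- K
  kd
}

# closed-form 1:1 binding: complex concentration for totals TA, TL, Kd K
complex_1to1 <- function(TA, TL, K) {
  b <- TA + TL + K
  (b - sqrt(b^2 - 4 * TA * TL)) / 2
}
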