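test_that("equilibrium matches the closed-form 1:1 binding quadratic", {
  for (case in list(c(1, 1, 1), c(0.5, 2, 0.1), c(3, 0.2, 0.05))) {
    TA <- case[1]; TL <- case[2]; K <- case[3]
    cfg <- toy_surrogate_config(kd_single_pair(K))
    st <- bcl2_state(c(BAX = TL, BAK = 0, BCL2 = TA, BCLXL = 0, MCL1 = 0))
    eq <- solve_equilibrium(st, cfg)
    cplx <- complex_1to1(TA, TL, K)
    expect_equal(unname(eq$free["BAX"]), TL - cplx, tolerance = 1e-6)
    expect_equal(unname(eq$free["BCL2"]), TA - cplx, tolerance = 1e-6)
    expect_equal(unname(eq$bound["BAX", "BCL2"]), cplx, tolerance = 1e-6)
  }
})

test_that("equilibrium agrees with a brute-force fine-grid oracle on a 2-species toy", {
  TA <- 0.8; TL <- 1.3; K <- 0.07
  cfg <- toy_surrogate_config(kd_single_pair(K))
  st <- bcl2_state(c(BAX = TL, BAK = 0, BCL2 = TA, BCLXL = 0, MCL1 = 0))
  eq <- solve_equilibrium(st, cfg)
  # grid search over complex concentration minimising the mass-action residual
  grid <- seq(0, min(TA, TL), length.out = 2e6 + 1)
  resid <- abs((TA - grid) * (TL - grid) - K * grid)
  best <- grid[which.min(resid)]
  expect_equal(unname(TL - eq$free["BAX"]), best, tolerance = 1e-6)
})

test_that("mass is conserved for every species at equilibrium", {
  set.seed(77)
  cfg <- default_surrogate_config()
  for (i in 1:10) {
    conc <- setNames(runif(5, 0, 2), c("BAX", "BAK", "BCL2", "BCLXL", "MCL1"))
    st <- bcl2_state(conc, mimetics = c(WEHI539 = runif(1, 0, 2)),
                     activator = runif(1, 0, 1))
    eq <- solve_equilibrium(st, cfg)
    for (a in c("BCL2", "BCLXL", "MCL1")) {
      expect_equal(unname(eq$free[a] + sum(eq$bound[, a])), unname(conc[a]),
                   tolerance = 1e-6)
    }
    for (l in c("BAX", "BAK")) {
      expect_equal(unname(eq$free[l] + sum(eq$bound[l, ])), unname(conc[l]),
                   tolerance = 1e-6)
    }
  }
})

test_that("with no anti-apoptotic proteins all effectors are free and eta is 0", {
  cfg <- default_surrogate_config()
  st <- bcl2_state(c(BAX = 0.3, BAK = 0.2, BCL2 = 0, BCLXL = 0, MCL1 = 0))
  eq <- solve_equilibrium(st, cfg)
  expect_equal(unname(eq$free["BAX"] + eq$free["BAK"]), 0.5, tolerance = 1e-8)
  expect_equal(stress_dose(st, cfg)$eta, 0)
})

test_that("saturating WEHI-539 approaches the equilibrium with BCL-XL removed", {
  cfg <- default_surrogate_config()
  conc <- c(BAX = 0.3, BAK = 0.3, BCL2 = 0.1, BCLXL = 0.8, MCL1 = 0.1)
  with_mim <- solve_equilibrium(
    bcl2_state(conc, mimetics = c(WEHI539 = 1000)), cfg)
  no_xl <- solve_equilibrium(
    bcl2_state(replace(conc, "BCLXL", 0)), cfg)
  expect_equal(sum(with_mim$free[c("BAX", "BAK")]),
               sum(no_xl$free[c("BAX", "BAK")]), tolerance = 1e-3)
})

test_that("stress dose is monotone in anti-apoptotic totals and mimetic doses", {
  set.seed(123)
  cfg <- default_surrogate_config()
  for (i in 1:40) {
    conc <- setNames(runif(5, 0.05, 1.5), c("BAX", "BAK", "BCL2", "BCLXL", "MCL1"))
    base <- stress_dose(bcl2_state(conc), cfg)
    anti <- sample(c("BCL2", "BCLXL", "MCL1"), 1)
    doubled <- stress_dose(bcl2_state(replace(conc, anti, 2 * conc[anti])), cfg)
    if (base$reachable && doubled$reachable) {
      expect_gte(doubled$eta, base$eta - 2 * cfg$eta_tol)
    }
    mim <- sample(c("ABT199", "WEHI539", "S63845"), 1)
    dosed <- stress_dose(bcl2_state(conc, mimetics = setNames(0.5, mim)), cfg)
    if (base$reachable && dosed$reachable) {
      expect_lte(dosed$eta, base$eta + 2 * cfg$eta_tol)
    }
  }
})

test_that("an unreachable MOMP threshold is flagged, not thrown", {
  cfg <- toy_surrogate_config(kd_single_pair(1e-6), theta = 0.9, eta_upper = 0.1)
  st <- bcl2_state(c(BAX = 1, BAK = 0, BCL2 = 50, BCLXL = 0, MCL1 = 0))
  res <- stress_dose(st, cfg)
  expect_false(res$reachable)
  expect_true(is.na(res$eta))
})

test_that("caspase execution cleaves nothing without caspase 3 and stalls under XIAP excess", {
  none <- simulate_caspase_execution(
    c(APAF1 = 0.4, CASP9 = 0.02, CASP3 = 0, SMAC = 0.4, XIAP = 0.1))
  expect_equal(max(none$cleaved), 0)
  blocked <- simulate_caspase_execution(
    c(APAF1 = 0.4, CASP9 = 0.02, CASP3 = 0.2, SMAC = 0, XIAP = 10))
  expect_lt(blocked$cleaved[blocked$time == 60], 0.8)
  expect_false(is_execution_competent(blocked))
})

test_that("caspase trajectories are monotone, bounded, deterministic and conserve pools", {
  conc <- c(APAF1 = 0.4, CASP9 = 0.02, CASP3 = 0.2, SMAC = 0.4, XIAP = 0.1)
  t1 <- simulate_caspase_execution(conc)
  t2 <- simulate_caspase_execution(conc)
  expect_identical(t1, t2)
  expect_equal(t1$cleaved[1], 0)
  expect_true(all(diff(t1$cleaved) >= -1e-10))
  expect_true(all(t1$cleaved <= 1))
  c3_pool <- t1$c3 + t1$c3a + t1$xiap_c3a
  xiap_pool <- t1$xiap + t1$xiap_c3a + t1$smac_xiap
  expect_equal(c3_pool, rep(conc[["CASP3"]], nrow(t1)), tolerance = 1e-6)
  expect_equal(xiap_pool, rep(conc[["XIAP"]], nrow(t1)), tolerance = 1e-6)
})

test_that("doubling SMAC never decreases cleavage at 60 min", {
  set.seed(9)
  for (i in 1:8) {
    conc <- c(APAF1 = runif(1, 0.1, 0.6), CASP9 = runif(1, 0.01, 0.05),
              CASP3 = runif(1, 0.05, 0.4), SMAC = runif(1, 0, 0.5),
              XIAP = runif(1, 0.05, 0.5))
    a <- simulate_caspase_execution(conc, horizon = 60)
    b <- simulate_caspase_execution(replace(conc, "SMAC", 2 * conc[["SMAC"]]),
                                    horizon = 60)
    expect_gte(b$cleaved[b$time == 60], a$cleaved[a$time == 60] - 1e-8)
  }
})

test_that("competence rule is an 80%-within-60-min boundary", {
  make_traj <- function(t80) {
    tm <- seq(0, 120, 0.5)
    structure(data.frame(time = tm, cleaved = pmin(1, 0.8 * tm / t80)),
              class = c("caspase_trajectory", "data.frame"))
  }
  expect_true(is_execution_competent(make_traj(59)))
  expect_false(is_execution_competent(make_traj(61)))
  flat <- structure(data.frame(time = seq(0, 120, 0.5), cleaved = 0),
                    class = c("caspase_trajectory", "data.frame"))
  expect_false(is_execution_competent(flat))
  short <- structure(data.frame(time = seq(0, 30, 0.5), cleaved = 1),
                     class = c("caspase_trajectory", "data.frame"))
  expect_error(is_execution_competent(short), ">= 60")
})

test_that("Pearson correlation matches hand arithmetic and flags degeneracy", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2.1, 3.9, 6.2, 8.1, 9.8, 12.3)
  res <- correlate(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(4 / (1 - r_hand^2))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  expect_equal(res$r, r_hand, tolerance = 1e-10)
  expect_equal(res$p, p_hand, tolerance = 1e-10)
  expect_equal(correlate(x, 2 * x)$r, 1)
  expect_equal(correlate(x, -x)$r, -1)
  expect_error(correlate(x, rep(1, 6)), "zero variance")
})
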