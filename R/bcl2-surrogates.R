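#' Surrogate configuration for the BCL-2 family models
#'
#' Loads the versioned YAML configuration driving the equilibrium
#' stress-dose surrogate and the reduced caspase-execution ODE: the
#' protein-protein dissociation-constant table (anti-apoptotic vs BAX, BAK
#' and the generic BH3 activator), the BH3-mimetic dissociation constants,
#' the MOMP threshold `theta` (fraction of total BAX+BAK that must be free),
#' solver tolerances/bounds, and the caspase rate constants. All values are
#' documented placeholder defaults (the source models' parameters are not
#' reproduced here) and are user-overridable by editing a copy of the file.
#'
#' @param path YAML config path; default is the packaged file.
#' @return List of class `surrogate_config`.
#' @export
read_surrogate_config <- function(path = system.file(
    "extdata", "surrogate_config.yaml", package = "apoptosense", mustWork = TRUE)) {
  doc <- yaml::read_yaml(path)
  kd <- do.call(rbind, lapply(doc$kd_uM, unlist))
  stopifnot(!is.null(kd))
  theta <- doc$momp_threshold
  if (is.null(theta) || theta <= 0 || theta >= 1) {
    stop("momp_threshold must lie in (0, 1)", call. = FALSE)
  }
  structure(list(
    kd = kd,                                   # ligand x anti-apoptotic, uM
    mimetic_kd = lapply(doc$mimetic_kd_uM, function(x) {
      v <- unlist(x); v[!is.finite(v)] <- Inf; v
    }),
    theta = theta,
    tol = doc$solver$tolerance %||% 1e-8,
    max_iter = doc$solver$max_iter %||% 10000L,
    eta_upper = doc$solver$eta_upper_uM %||% 1000,
    eta_tol = doc$solver$eta_tolerance_uM %||% 1e-4,
    caspase_rates = unlist(doc$caspase_rates)
  ), class = "surrogate_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_surrogate_config
#' @export
default_surrogate_config <- function() read_surrogate_config()

#' BCL-2 family state for the stress-dose surrogate
#'
#' @param conc Named numeric vector of total concentrations (uM) for BAX,
#'   BAK, BCL2, BCLXL, MCL1.
#' @param mimetics Named numeric vector of mimetic doses (uM), names among
#'   ABT199, WEHI539, S63845; may be empty.
#' @param activator Total dose (uM) of the generic stress-induced BH3
#'   activator species.
#' @return List of class `bcl2_state`.
#' @export
bcl2_state <- function(conc, mimetics = numeric(), activator = 0) {
  names(conc) <- canonical_protein(names(conc))
  need <- c("BAX", "BAK", "BCL2", "BCLXL", "MCL1")
  missing <- setdiff(need, names(conc))
  if (length(missing)) stop("state needs concentrations for: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  conc <- conc[need]
  if (any(!is.finite(conc)) || any(conc < 0) || !is.finite(activator) ||
      activator < 0 || any(mimetics < 0)) {
    stop("concentrations and doses must be finite and >= 0", call. = FALSE)
  }
  structure(list(conc = conc, mimetics = mimetics, activator = activator),
            class = "bcl2_state")
}

# assemble ligand totals and the ligand x anti-apoptotic Kd matrix
.binding_system <- function(state, cfg) {
  anti <- c("BCL2", "BCLXL", "MCL1")
  lig_tot <- c(BAX = unname(state$conc["BAX"]), BAK = unname(state$conc["BAK"]),
               ACT = state$activator)
  K <- cfg$kd[c("BAX", "BAK", "ACT"), anti, drop = FALSE]
  if (length(state$mimetics)) {
    for (m in names(state$mimetics)) {
      kd_m <- cfg$mimetic_kd[[m]]
      if (is.null(kd_m)) stop("no Kd entry for mimetic ", m, call. = FALSE)
      lig_tot <- c(lig_tot, stats::setNames(state$mimetics[[m]], m))
      K <- rbind(K, kd_m[anti])
      rownames(K)[nrow(K)] <- m
    }
  }
  list(anti_tot = state$conc[anti], lig_tot = lig_tot, K = K)
}

#' Solve the competitive-binding equilibrium
#'
#' Mass-action equilibrium of each anti-apoptotic protein (BCL-2, BCL-XL,
#' MCL-1) binding each ligand (BAX, BAK, the generic BH3 activator, and any
#' administered mimetic) with the configured dissociation constants. Solved
#' by damped fixed-point iteration on the free concentrations; the unique
#' non-negative equilibrium satisfies every conservation law to within the
#' configured tolerance.
#'
#' @param state A [bcl2_state()].
#' @param cfg A `surrogate_config` (default [default_surrogate_config()]).
#' @return List: `free` (named vector over all species, uM), `bound`
#'   (ligand x anti-apoptotic complex matrix), `residual`, `iterations`.
#' @export
solve_equilibrium <- function(state, cfg = default_surrogate_config()) {
  sys <- .binding_system(state, cfg)
  a <- sys$anti_tot                       # free anti-apoptotics, start = totals
  l <- sys$lig_tot
  Kinv <- 1 / sys$K                       # 0 where Kd = Inf
  Kinv[!is.finite(sys$K)] <- 0
  omega <- 0.5
  for (it in seq_len(cfg$max_iter)) {
    l_new <- sys$lig_tot / (1 + drop(Kinv %*% a))
    a_prop <- sys$anti_tot / (1 + drop(crossprod(Kinv, l_new)))
    a_new <- (1 - omega) * a + omega * a_prop
    res <- max(abs(a_new - a), abs(l_new - l))
    a <- a_new
    l <- l_new
    if (res < cfg$tol) break
  }
  # consistency residual of the binding equations at the returned point
  l_chk <- sys$lig_tot / (1 + drop(Kinv %*% a))
  a_chk <- sys$anti_tot / (1 + drop(crossprod(Kinv, l_chk)))
  residual <- max(abs(a_chk - a), abs(l_chk - l))
  if (residual > 100 * cfg$tol) {
    stop(sprintf("equilibrium solver did not converge (residual %.3g)",
                 residual), call. = FALSE)
  }
  bound <- outer(l, a) * Kinv             # complex concentrations c_ij
  list(free = c(a, l), bound = bound, residual = residual, iterations = it)
}

#' Stress dose required to permeabilise the mitochondrial outer membrane
#'
#' The stress dose is the minimal total dose of a generic promiscuous
#' BH3-only activator such that the free fraction of the effector pool
#' (BAX+BAK) reaches the MOMP threshold `theta`. Found by bisection over
#' the activator dose; lower values mean a more apoptosis-primed state.
#' In-silico BH3-mimetic administration enters through `state$mimetics` and
#' lowers the dose by displacing effectors from their targets.
#'
#' @inheritParams solve_equilibrium
#' @return List of class `stress_dose_result`: `eta` (uM; `NA` if the
#'   threshold is unreachable within the bisection upper bound), `reachable`,
#'   `free_fraction_at_eta`, `iterations`.
#' @export
stress_dose <- function(state, cfg = default_surrogate_config()) {
  stopifnot(inherits(state, "bcl2_state"))
  effector_total <- sum(state$conc[c("BAX", "BAK")])
  free_frac <- function(act) {
    s <- state
    s$activator <- act
    eq <- solve_equilibrium(s, cfg)
    sum(eq$free[c("BAX", "BAK")]) / effector_total
  }
  if (effector_total <= 0) {
    return(structure(list(eta = NA_real_, reachable = FALSE,
                          free_fraction_at_eta = NA_real_, iterations = 0L),
                     class = "stress_dose_result"))
  }
  if (free_frac(0) >= cfg$theta) {
    return(structure(list(eta = 0, reachable = TRUE,
                          free_fraction_at_eta = free_frac(0), iterations = 0L),
                     class = "stress_dose_result"))
  }
  if (free_frac(cfg$eta_upper) < cfg$theta) {
    return(structure(list(eta = NA_real_, reachable = FALSE,
                          free_fraction_at_eta = free_frac(cfg$eta_upper),
                          iterations = 0L),
                     class = "stress_dose_result"))
  }
  lo <- 0; hi <- cfg$eta_upper; it <- 0L
  while (hi - lo > cfg$eta_tol) {
    mid <- (lo + hi) / 2
    if (free_frac(mid) >= cfg$theta) hi <- mid else lo <- mid
    it <- it + 1L
  }
  structure(list(eta = hi, reachable = TRUE,
                 free_fraction_at_eta = free_frac(hi), iterations = it),
            class = "stress_dose_result")
}

#' Reduced caspase-execution kinetics
#'
#' Mass-action ODE surrogate of apoptosome-driven executioner-caspase
#' activation after mitochondrial permeabilisation: apoptosome assembly
#' (APAF-1 + pro-caspase 9), catalytic activation of caspase 3 by the
#' apoptosome, reversible inhibition of active caspase 3 by XIAP,
#' sequestration of XIAP by SMAC, and substrate cleavage by free active
#' caspase 3. Integrated with adaptive stepping (`deSolve::lsoda`).
#'
#' @param conc Named vector of initial concentrations (uM) for APAF1,
#'   CASP9, CASP3, SMAC, XIAP (e.g. one row of [to_concentrations()]).
#' @param rates Named vector of rate constants; default from
#'   [default_surrogate_config()]: `k_apop`, `k_c3act` (uM^-1 min^-1),
#'   `kon_xiap_c3`, `kon_smac_xiap` (uM^-1 min^-1), `koff_xiap_c3`,
#'   `koff_smac_xiap` (min^-1), `k_cleave` (uM^-1 min^-1).
#' @param horizon Simulation horizon in minutes (default 120).
#' @param dt Output time step in minutes (default 0.5).
#' @return Object of class `caspase_trajectory`: data frame with `time`,
#'   all species (uM) and `cleaved` (substrate fraction in \[0, 1\]).
#' @export
simulate_caspase_execution <- function(conc,
                                       rates = default_surrogate_config()$caspase_rates,
                                       horizon = 120, dt = 0.5) {
  names(conc) <- canonical_protein(names(conc))
  need <- c("APAF1", "CASP9", "CASP3", "SMAC", "XIAP")
  missing <- setdiff(need, names(conc))
  if (length(missing)) stop("missing concentration(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  conc <- conc[need]
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("concentrations must be finite and >= 0", call. = FALSE)
  }
  y0 <- c(apaf = unname(conc["APAF1"]), c9 = unname(conc["CASP9"]), apop = 0,
          c3 = unname(conc["CASP3"]), c3a = 0, xiap = unname(conc["XIAP"]),
          xiap_c3a = 0, smac = unname(conc["SMAC"]), smac_xiap = 0, cleaved = 0)
  deriv <- function(t, y, p) {
    with(as.list(c(y, p)), {
      v_apop <- k_apop * apaf * c9
      v_act  <- k_c3act * c3 * apop
      v_xon  <- kon_xiap_c3 * xiap * c3a
      v_xoff <- koff_xiap_c3 * xiap_c3a
      v_son  <- kon_smac_xiap * smac * xiap
      v_soff <- koff_smac_xiap * smac_xiap
      list(c(
        apaf = -v_apop, c9 = -v_apop, apop = v_apop,
        c3 = -v_act, c3a = v_act - v_xon + v_xoff,
        xiap = -v_xon + v_xoff - v_son + v_soff,
        xiap_c3a = v_xon - v_xoff,
        smac = -v_son + v_soff, smac_xiap = v_son - v_soff,
        cleaved = k_cleave * c3a * (1 - cleaved)
      ))
    })
  }
  times <- seq(0, horizon, by = dt)
  sol <- deSolve::ode(y0, times, deriv, as.list(rates),
                      rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0) stop("ODE integration failed; final state: ",
                                       paste(utils::tail(sol, 1), collapse = ", "),
                                       call. = FALSE)
  out <- as.data.frame(sol)
  out$cleaved <- pmin(pmax(out$cleaved, 0), 1)
  structure(out, class = c("caspase_trajectory", "data.frame"))
}

#' Apoptosis-execution competence of a simulated trajectory
#'
#' A profile is execution-competent if the substrate-cleavage fraction
#' reaches 80% within 60 minutes of mitochondrial permeabilisation (time 0
#' of the trajectory).
#'
#' @param traj A `caspase_trajectory` covering at least 60 min.
#' @param threshold Cleavage fraction required (default 0.8).
#' @param within Time limit in minutes (default 60).
#' @return Logical.
#' @export
is_execution_competent <- function(traj, threshold = 0.8, within = 60) {
  stopifnot(inherits(traj, "caspase_trajectory"))
  if (max(traj$time) < within) stop("trajectory must cover >= ", within,
                                    " min", call. = FALSE)
  any(traj$cleaved[traj$time <= within] >= threshold)
}

#' Pearson correlation with two-sided test
#'
#' Thin wrapper around [stats::cor.test()] returning the coefficient and
#' two-sided p-value (t distribution), with an explicit zero-variance error.
#'
#' @param xs,ys Numeric vectors of equal length >= 3.
#' @return List with `r` and `p`.
#' @export
correlate <- function(xs, ys) {
  if (length(xs) != length(ys) || length(xs) < 3) {
    stop("need equal-length vectors of length >= 3", call. = FALSE)
  }
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(xs, ys, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}
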