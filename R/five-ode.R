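#' Kinetic parameters of the five-ODE mass-action cell-cycle model
#'
#' A structurally distinct oscillator used to check that conclusions do
#' not depend on the two-ODE model's Hill nonlinearities. It tracks five
#' concentrations (nM) with strictly mass-action kinetics:
#' cyclin B-Cdk1 (`c`), active (phosphorylated) Greatwall (`g`), free
#' phospho-ENSA (`s`), the PP2A:phospho-ENSA complex (`y`) and active
#' APC/C (`a`). The bistable switch here is between Cdk1 and APC/C,
#' built from the Greatwall/ENSA/PP2A module: Cdk1 activates Greatwall,
#' which phosphorylates ENSA; phospho-ENSA sequesters PP2A by tight,
#' effectively irreversible binding and is only slowly released by
#' catalytic dephosphorylation ("unfair competition"), and free PP2A
#' opposes the Cdk1-driven activation of both Greatwall and APC/C.
#' Greatwall additionally carries a pseudo-first-order basal
#' dephosphorylation `kb` (absorbing phosphatases other than PP2A-B55),
#' which lets the switch reset when PP2A is fully sequestered. There are
#' no Wee1/Cdc25 feedback loops: Cdk1 activity is proportional to cyclin
#' level.
#'
#' \deqn{dc/dt = k_s - k_d\, a\, c}
#' \deqn{dg/dt = k_1 c (G_{tot} - g) - k_2\, p\, g - k_b g}
#' \deqn{ds/dt = k_3 g (S_{tot} - s - y) - k_{ass}\, s\, p}
#' \deqn{dy/dt = k_{ass}\, s\, p - k_{cat} y}
#' \deqn{da/dt = k_5 c (A_{tot} - a) - k_6\, p\, a}
#' with free active PP2A `p = Ptot - y`.
#'
#' The default constants (ten kinetic constants plus four totals) are the
#' package's own parameterization, calibrated once to sustained
#' oscillations with a realistic ~30 min period (see the package
#' vignette).
#'
#' @param ks Cyclin synthesis rate, nM/min.
#' @param kd APC/C-mediated degradation, 1/(nM min).
#' @param k1 Cdk1-driven Greatwall phosphorylation, 1/(nM min).
#' @param k2 PP2A-driven Greatwall dephosphorylation, 1/(nM min).
#' @param kb Basal Greatwall dephosphorylation, 1/min.
#' @param k3 Greatwall-driven ENSA phosphorylation, 1/(nM min).
#' @param kass PP2A:ENSA-P association, 1/(nM min).
#' @param kcat Catalytic release (dephosphorylation of bound ENSA-P),
#'   1/min.
#' @param k5 Cdk1-driven APC/C activation, 1/(nM min).
#' @param k6 PP2A-driven APC/C inactivation, 1/(nM min).
#' @param Gtot,Stot,Ptot,Atot Total Greatwall, ENSA, PP2A and APC/C, nM.
#' @return An object of class `"five_ode_params"`.
#' @export
five_ode_params <- function(ks = 1.1, kd = 0.01, k1 = 0.0035, k2 = 0.03,
                            kb = 0.27, k3 = 0.05, kass = 1.4, kcat = 0.5,
                            k5 = 0.013, k6 = 0.26,
                            Gtot = 40, Stot = 200, Ptot = 50, Atot = 50) {
  vals <- c(ks = ks, kd = kd, k1 = k1, k2 = k2, kb = kb, k3 = k3,
            kass = kass, kcat = kcat, k5 = k5, k6 = k6,
            Gtot = Gtot, Stot = Stot, Ptot = Ptot, Atot = Atot)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all five-ODE constants must be finite and >= 0")
  structure(as.list(vals), class = "five_ode_params")
}

#' @export
print.five_ode_params <- function(x, ...) {
  cat("<five_ode_params>\n")
  v <- unlist(x)
  cat(" ", paste(sprintf("%s=%.4g", names(v), v), collapse = ", "), "\n")
  invisible(x)
}

five_ode_parvec <- function(p) {
  unlist(p[c("ks", "kd", "k1", "k2", "kb", "k3", "kass", "kcat",
             "k5", "k6", "Gtot", "Stot", "Ptot", "Atot")])
}

# Reference R implementation of the RHS (residual checks, full-system
# cross-validation in the tests).
five_ode_rhs <- function(t, state, p) {
  c_ <- state[[1]]; g <- state[[2]]; s <- state[[3]]; y <- state[[4]]
  a <- state[[5]]
  pfree <- p$Ptot - y
  su <- p$Stot - s - y
  c(p$ks - p$kd * a * c_,
    p$k1 * c_ * (p$Gtot - g) - p$k2 * pfree * g - p$kb * g,
    p$k3 * g * su - p$kass * s * pfree,
    p$kass * s * pfree - p$kcat * y,
    p$k5 * c_ * (p$Atot - a) - p$k6 * pfree * a)
}

#' Simulate the five-ODE mass-action oscillator
#'
#' Shares the trajectory container and all downstream period/phase
#' machinery with [simulate_two_ode()]. The state matrix carries `cyc`
#' (the cyclin B-Cdk1 variable, so that [detect_period()] defaults work
#' unchanged) plus `cdk1a` (identical to `cyc`; Cdk1 activity is
#' proportional to cyclin here), `gwl`, `ensap`, `pp2a_c` (the
#' PP2A:ENSA-P complex) and `apc`.
#'
#' @inheritParams simulate_two_ode
#' @param params A [five_ode_params()].
#' @param initial_state Named numeric of length 5
#'   (`c`, `g`, `s`, `y`, `a`); default all-interphase (all zero).
#' @return A `"cc_trajectory"`.
#' @export
simulate_five_ode <- function(params, t_end = 1000, dt = 0.1,
                              initial_state = c(c = 0, g = 0, s = 0,
                                                y = 0, a = 0),
                              rtol = 1e-8, atol = 1e-10,
                              temperature = NA_real_) {
  stopifnot(inherits(params, "five_ode_params"))
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be > 0")
  times <- seq(0, t_end, by = dt)
  out <- deSolve::ode(y = unname(initial_state), times = times,
                      func = "derivs_fiveode", parms = five_ode_parvec(params),
                      dllname = "thermocycle", initfunc = "initmod_fiveode",
                      method = "lsoda", rtol = rtol, atol = atol)
  if (nrow(out) < length(times))
    stop("ODE solver did not converge (stopped at t = ",
         signif(out[nrow(out), 1], 6), " min)")
  st <- unname(out[, -1, drop = FALSE])
  if (min(st) < -1e-6)
    stop("negative state excursion beyond tolerance: min = ", min(st))
  st[st < 0] <- 0
  state <- cbind(cyc = st[, 1], cdk1a = st[, 1], gwl = st[, 2],
                 ensap = st[, 3], pp2a_c = st[, 4], apc = st[, 5])
  structure(list(times = out[, 1], state = state, params = params,
                 temperature = temperature, model = "five_ode",
                 solver = list(method = "lsoda", rtol = rtol, atol = atol)),
            class = "cc_trajectory")
}
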