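#' Hill response curve for the reduced cell-cycle model
#'
#' The two-ODE model eliminates the fast regulators (APC/C, Cdc25, Wee1)
#' by assuming their Cdk1-driven (de)phosphorylation is instantaneous, so
#' each appears as a steady-state fractional activity that is a Hill
#' function of instantaneous active Cdk1.
#'
#' @param basal Minimum fractional activity (`0 <= basal <= max`).
#' @param max Maximum fractional activity.
#' @param ec50 Half-maximal active-Cdk1 concentration (nM, > 0).
#' @param n Hill coefficient (> 0).
#' @param direction `"increasing"` (APC/C degradation response `d`,
#'   Cdc25 activation response `a`) or `"decreasing"` (Wee1 inactivation
#'   response `i`).
#' @return An object of class `"hill_response"`.
#' @export
hill_response <- function(basal, max, ec50, n,
                          direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  if (basal < 0 || basal > max) stop("need 0 <= basal <= max")
  if (ec50 <= 0) stop("ec50 must be > 0")
  if (n <= 0) stop("Hill coefficient n must be > 0")
  structure(list(basal = basal, max = max, ec50 = ec50, n = n,
                 direction = direction), class = "hill_response")
}

#' Evaluate a Hill response
#'
#' @param h A [hill_response()].
#' @param cdk1a Active Cdk1 concentration(s), nM.
#' @return Fractional activity in `[basal, max]`.
#' @export
hill_value <- function(h, cdk1a) {
  x <- pmax(cdk1a, 0)
  frac <- x^h$n / (h$ec50^h$n + x^h$n)
  if (h$direction == "decreasing") frac <- 1 - frac
  h$basal + (h$max - h$basal) * frac
}

hill_to_vec <- function(h) {
  c(h$basal, h$max, h$ec50, h$n, if (h$direction == "increasing") 1 else -1)
}

#' Kinetic parameters of the two-ODE relaxation oscillator
#'
#' The model tracks total cyclin B (`cyc`, nM) and active Cdk1
#' (`cdk1a`, nM):
#' \deqn{dcyc/dt = k_s - k_d d(cdk1a) cyc}
#' \deqn{\epsilon \, dcdk1a/dt = k_a a(cdk1a)(cyc - cdk1a) -
#'   k_i i(cdk1a) cdk1a}
#' where `d`, `a`, `i` are Hill responses standing in for APC/C, Cdc25 and
#' Wee1 activity. Sustained relaxation oscillations need `ks > 0` and a
#' small timescale-separation factor `eps` (documented property, not a
#' precondition).
#'
#' The default Hill set and rates are the package's own calibration,
#' chosen once to yield relaxation oscillations with a realistic period of
#' about 30 minutes at the reference temperature (see the package
#' vignette).
#'
#' @param ks Cyclin synthesis rate, nM/min.
#' @param kd Maximal APC/C-mediated degradation rate, 1/min.
#' @param ka Cdk1 activation rate scale, 1/min.
#' @param ki Cdk1 inactivation rate scale, 1/min.
#' @param eps Timescale-separation factor (dimensionless, > 0).
#' @param hill_d,hill_a,hill_i [hill_response()] records for degradation,
#'   activation and inactivation.
#' @return An object of class `"two_ode_params"`.
#' @export
two_ode_params <- function(ks = 1.1, kd = 0.2, ka = 1, ki = 1, eps = 0.05,
                           hill_d = hill_response(0.01, 1, 32, 15, "increasing"),
                           hill_a = hill_response(0.16, 0.8, 35, 11, "increasing"),
                           hill_i = hill_response(0.08, 0.4, 30, 5, "decreasing")) {
  rates <- c(ks = ks, kd = kd, ka = ka, ki = ki)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("rates ks, kd, ka, ki must be finite and >= 0")
  if (!is.finite(eps) || eps <= 0) stop("eps must be > 0")
  structure(list(ks = ks, kd = kd, ka = ka, ki = ki, eps = eps,
                 hill_d = hill_d, hill_a = hill_a, hill_i = hill_i),
            class = "two_ode_params")
}

#' @export
print.two_ode_params <- function(x, ...) {
  cat("<two_ode_params>\n")
  cat(sprintf("  ks = %.4g nM/min, kd = %.4g /min, ka = %.4g /min, ki = %.4g /min, eps = %.4g\n",
              x$ks, x$kd, x$ka, x$ki, x$eps))
  for (nm in c("hill_d", "hill_a", "hill_i")) {
    h <- x[[nm]]
    cat(sprintf("  %s: %s, basal %.3g, max %.3g, ec50 %.3g nM, n %.3g\n",
                nm, h$direction, h$basal, h$max, h$ec50, h$n))
  }
  invisible(x)
}

two_ode_parvec <- function(p) {
  c(p$ks, p$kd, p$ka, p$ki, p$eps,
    hill_to_vec(p$hill_d), hill_to_vec(p$hill_a), hill_to_vec(p$hill_i))
}

# Right-hand side in R, used for residual spot checks and as a reference
# path independent of the compiled code.
two_ode_rhs <- function(t, state, p) {
  cyc <- state[[1]]; cdk <- state[[2]]
  dcyc <- p$ks - p$kd * hill_value(p$hill_d, cdk) * cyc
  dcdk <- (p$ka * hill_value(p$hill_a, cdk) * (cyc - cdk) -
             p$ki * hill_value(p$hill_i, cdk) * cdk) / p$eps
  c(dcyc, dcdk)
}

#' Simulate the two-ODE cell-cycle oscillator
#'
#' Integrates the relaxation-oscillator ODEs with a stiff implicit
#' multistep solver (`deSolve`, compiled right-hand side), returning a
#' densely sampled trajectory.
#'
#' @param params A [two_ode_params()].
#' @param t_end Simulation length, minutes.
#' @param dt Output sampling interval, minutes.
#' @param initial_state Named numeric `c(cyc = , cdk1a = )`; defaults to
#'   the all-zero interphase state.
#' @param rtol,atol Solver tolerances.
#' @param temperature Optional temperature (C) recorded as trajectory
#'   metadata.
#' @return An object of class `"cc_trajectory"`: list with `times`,
#'   `state` (matrix with columns `cyc`, `cdk1a`), `params`,
#'   `temperature` and solver diagnostics.
#' @export
simulate_two_ode <- function(params, t_end = 1000, dt = 0.1,
                             initial_state = c(cyc = 0, cdk1a = 0),
                             rtol = 1e-8, atol = 1e-10,
                             temperature = NA_real_) {
  stopifnot(inherits(params, "two_ode_params"))
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be > 0")
  times <- seq(0, t_end, by = dt)
  out <- deSolve::ode(y = unname(initial_state), times = times,
                      func = "derivs_twoode", parms = two_ode_parvec(params),
                      dllname = "thermocycle", initfunc = "initmod_twoode",
                      method = "lsoda", rtol = rtol, atol = atol)
  diagn <- attributes(out)[c("istate", "rstate")]
  if (nrow(out) < length(times))
    stop("ODE solver did not converge (stopped at t = ",
         signif(out[nrow(out), 1], 6), " min)")
  state <- unname(out[, -1, drop = FALSE])
  colnames(state) <- c("cyc", "cdk1a")
  neg_tol <- 1e-6
  if (min(state) < -neg_tol)
    stop("negative state excursion beyond tolerance: min = ", min(state))
  state[state < 0] <- 0
  structure(list(times = out[, 1], state = state, params = params,
                 temperature = temperature, model = "two_ode",
                 solver = list(method = "lsoda", rtol = rtol, atol = atol,
                               diagnostics = diagn)),
            class = "cc_trajectory")
}

#' @export
print.cc_trajectory <- function(x, ...) {
  cat(sprintf("<cc_trajectory> %s model, %d samples over %.1f min",
              x$model, length(x$times), max(x$times)))
  if (!is.na(x$temperature)) cat(sprintf(", T = %.2f C", x$temperature))
  cat("\n  variables:", paste(colnames(x$state), collapse = ", "), "\n")
  invisible(x)
}

#' Export a trajectory to tidy long format
#'
#' @param x A `"cc_trajectory"`.
#' @param ... Unused.
#' @return A data.frame with columns `time_min`, `variable`, `value`,
#'   `temperature_C`.
#' @export
as.data.frame.cc_trajectory <- function(x, ...) {
  vars <- colnames(x$state)
  data.frame(
    time_min = rep(x$times, times = length(vars)),
    variable = rep(vars, each = length(x$times)),
    value = as.vector(x$state),
    temperature_C = x$temperature,
    row.names = NULL
  )
}

#' @export
plot.cc_trajectory <- function(x, variables = colnames(x$state), ...) {
  graphics::matplot(x$times, x$state[, variables, drop = FALSE],
                    type = "l", lty = 1, xlab = "time (min)",
                    ylab = "concentration (nM)", ...)
  graphics::legend("topright", legend = variables, lty = 1,
                   col = seq_along(variables), bty = "n")
  invisible(x)
}
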