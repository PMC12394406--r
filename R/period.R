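# Simple peak finder with prominence and minimum-separation filtering.
# Prominence of a peak = height above the higher of the two lowest points
# separating it from higher terrain (or the series boundary) on each side.
find_peaks <- function(x, times, min_prominence = 0, min_separation = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  # collapse flat-topped plateaus: drop candidates whose predecessor
  # candidate has equal value and is adjacent in index with no dip between
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    left <- if (i > 1) x[1:(i - 1)] else x[i]
    hi <- which(left > x[i])
    lmin <- min(x[(if (length(hi)) max(hi) else 1):i])
    right <- if (i < n) x[(i + 1):n] else x[i]
    hi2 <- which(right > x[i])
    rmin <- min(x[i:(i + (if (length(hi2)) min(hi2) else length(right)))])
    x[i] - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  if (min_separation > 0 && length(keep) > 1) {
    ord <- keep[order(x[keep], decreasing = TRUE)]
    sel <- logical(0)
    chosen <- integer(0)
    for (i in ord) {
      if (!length(chosen) || all(abs(times[i] - times[chosen]) >= min_separation))
        chosen <- c(chosen, i)
    }
    keep <- sort(chosen)
  }
  keep
}

#' Detect the oscillation period of a simulated trajectory
#'
#' Peaks of the chosen variable (cyclin by default) are located by local
#' maxima with a minimum prominence of 10\% of the observed amplitude and
#' a minimum inter-peak separation of 2 minutes; the first 100 minutes are
#' treated as transient and discarded when the run is long enough. The
#' period is the time between the last two peaks. If those two peaks
#' differ in height by more than `amplitude_tol` (relative, default 5\%),
#' the oscillation is considered damped rather than sustained and the
#' system is reported as non-oscillating; an arrest class (`low_cdk1` /
#' `high_cdk1`) is then assigned from the final active-Cdk1 level relative
#' to the activation response's ec50.
#'
#' @param traj A `"cc_trajectory"`.
#' @param variable State variable used for peak detection.
#' @param amplitude_tol Maximum relative difference between the last two
#'   peak heights for the oscillation to count as sustained.
#' @param min_prominence_frac Peak prominence threshold, as a fraction of
#'   the observed amplitude.
#' @param min_separation Minimum inter-peak separation, minutes.
#' @param transient Initial stretch discarded before peak analysis,
#'   minutes (only applied when the trajectory is at least twice as long).
#' @return An object of class `"period_result"`: list with `oscillating`,
#'   `period`, `peak_times`, `peak_values`, `trough_times`, `amplitude`,
#'   `arrest_class`.
#' @export
detect_period <- function(traj, variable = "cyc", amplitude_tol = 0.05,
                          min_prominence_frac = 0.1, min_separation = 2,
                          transient = 100) {
  stopifnot(inherits(traj, "cc_trajectory"))
  if (!length(traj$times)) stop("empty trajectory")
  x <- traj$state[, variable]
  tt <- traj$times
  if (max(tt) >= 2 * transient) {
    sel <- tt >= transient
    x <- x[sel]; tt <- tt[sel]
  }
  amp <- diff(range(x))
  peaks <- find_peaks(x, tt, min_prominence = min_prominence_frac * amp,
                      min_separation = min_separation)
  troughs <- find_peaks(-x, tt, min_prominence = min_prominence_frac * amp,
                        min_separation = min_separation)
  res <- list(oscillating = FALSE, period = NA_real_,
              peak_times = tt[peaks], peak_values = x[peaks],
              trough_times = tt[troughs], amplitude = amp,
              arrest_class = "none", variable = variable)
  if (length(peaks) >= 2) {
    last2 <- x[peaks[c(length(peaks) - 1, length(peaks))]]
    rel_diff <- abs(diff(last2)) / max(abs(last2))
    if (rel_diff <= amplitude_tol) {
      res$oscillating <- TRUE
      res$period <- diff(tt[peaks[c(length(peaks) - 1, length(peaks))]])
    }
  }
  if (!res$oscillating) {
    final_cdk <- traj$state[nrow(traj$state), "cdk1a"]
    ec50 <- if (!is.null(traj$params$hill_a)) traj$params$hill_a$ec50 else NA
    res$arrest_class <- if (!is.na(ec50) && final_cdk > ec50) "high_cdk1" else "low_cdk1"
  }
  class(res) <- "period_result"
  res
}

#' @export
print.period_result <- function(x, ...) {
  if (x$oscillating) {
    cat(sprintf("<period_result> oscillating, period %.3f min, %d peaks, amplitude %.3g\n",
                x$period, length(x$peak_times), x$amplitude))
  } else {
    cat(sprintf("<period_result> not oscillating (arrest class: %s)\n",
                x$arrest_class))
  }
  invisible(x)
}

#' Locate and classify a stable arrest state
#'
#' For parameter sets that do not sustain oscillations, the stable steady
#' state is located by long-time integration followed by Newton refinement
#' of the ODE right-hand side, and classified as an interphase-like
#' (`low_cdk1`) or M-phase-like (`high_cdk1`) arrest by comparing the
#' steady active-Cdk1 level with the activation response's ec50.
#'
#' @param params A [two_ode_params()].
#' @param t_settle Integration time used to approach the steady state.
#' @param tol Newton convergence tolerance on the RHS norm.
#' @return List with `arrest_class`, `steady_state` (named vector) and
#'   `residual_norm`.
#' @export
classify_arrest <- function(params, t_settle = 3000, tol = 1e-10) {
  traj <- simulate_two_ode(params, t_end = t_settle, dt = 1)
  pr <- detect_period(traj)
  if (pr$oscillating)
    stop("system oscillates; use detect_period for oscillating trajectories")
  xs <- traj$state[nrow(traj$state), ]
  # damped Newton with a finite-difference Jacobian (2x2 system)
  for (iter in 1:100) {
    f <- two_ode_rhs(0, xs, params)
    if (sqrt(sum(f^2)) < tol) break
    J <- matrix(0, 2, 2)
    h <- pmax(abs(xs), 1) * 1e-7
    for (j in 1:2) {
      xp <- xs; xp[j] <- xp[j] + h[j]
      J[, j] <- (two_ode_rhs(0, xp, params) - f) / h[j]
    }
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      xn <- pmax(xs + lambda * step, 0)
      if (sqrt(sum(two_ode_rhs(0, xn, params)^2)) < sqrt(sum(f^2)) ||
          lambda < 1e-4) break
      lambda <- lambda / 2
    }
    xs <- xn
  }
  cls <- if (xs[["cdk1a"]] > params$hill_a$ec50) "high_cdk1" else "low_cdk1"
  list(arrest_class = cls,
       steady_state = c(cyc = xs[["cyc"]], cdk1a = xs[["cdk1a"]]),
       residual_norm = sqrt(sum(two_ode_rhs(0, xs, params)^2)))
}

#' Nullclines of the two-ODE oscillator
#'
#' The cyclin nullcline has the closed form
#' `cyc = ks / (kd d(cdk1a))` - its position depends solely on the ratio
#' `ks/kd` - and the Cdk1 nullcline solves the activation/inactivation
#' balance, `cyc = cdk1a + ki i(cdk1a) cdk1a / (ka a(cdk1a))`.
#' Intersections (candidate steady states) are found by sign-change
#' bracketing plus root refinement along the grid.
#'
#' @param params A [two_ode_params()].
#' @param cdk1a_grid Grid of active-Cdk1 values (nM, >= 0).
#' @return List with data.frame `curves` (`cdk1a`, `cyc_nullcline`,
#'   `cdk1_nullcline`) and data.frame `intersections`.
#' @export
nullclines <- function(params, cdk1a_grid = seq(0, 120, by = 0.25)) {
  if (any(cdk1a_grid < 0)) stop("cdk1a grid must be >= 0")
  x <- cdk1a_grid
  cyc_nc <- params$ks / (params$kd * hill_value(params$hill_d, x))
  cdk_nc <- x + params$ki * hill_value(params$hill_i, x) * x /
    (params$ka * hill_value(params$hill_a, x))
  gap <- function(z) {
    params$ks / (params$kd * hill_value(params$hill_d, z)) -
      (z + params$ki * hill_value(params$hill_i, z) * z /
         (params$ka * hill_value(params$hill_a, z)))
  }
  g <- cyc_nc - cdk_nc
  sgn <- sign(g)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  inter <- lapply(idx, function(i) {
    r <- stats::uniroot(gap, lower = x[i], upper = x[i + 1], tol = 1e-10)
    data.frame(cdk1a = r$root,
               cyc = params$ks / (params$kd * hill_value(params$hill_d, r$root)))
  })
  exact <- x[g == 0]
  if (length(exact))
    inter <- c(inter, lapply(exact, function(z)
      data.frame(cdk1a = z,
                 cyc = params$ks / (params$kd * hill_value(params$hill_d, z)))))
  list(curves = data.frame(cdk1a = x, cyc_nullcline = cyc_nc,
                           cdk1_nullcline = cdk_nc),
       intersections = if (length(inter)) do.call(rbind, inter)
       else data.frame(cdk1a = numeric(0), cyc = numeric(0)))
}

#' Per-cycle rising and falling phase durations of a model trajectory
#'
#' Splits each oscillation cycle of active Cdk1 into a rising
#' (trough-to-peak, interphase-through-metaphase proxy) and a falling
#' (peak-to-trough, mitotic-exit proxy) segment.
#'
#' @param traj A `"cc_trajectory"` that sustains oscillations.
#' @param variable State variable segmented (active Cdk1 by default).
#' @param ... Passed to [detect_period()].
#' @return data.frame with one row per complete cycle: `cycle`,
#'   `trough_time`, `peak_time`, `next_trough_time`, `rising`, `falling`,
#'   `total` (minutes).
#' @export
model_phase_durations <- function(traj, variable = "cdk1a", ...) {
  pr <- detect_period(traj, variable = variable, ...)
  if (!pr$oscillating)
    stop("trajectory is not oscillating; phase durations undefined")
  phases_from_extrema(pr$trough_times, pr$peak_times)
}

# Shared trough/peak -> per-cycle phase table (also used for FRET traces).
phases_from_extrema <- function(trough_times, peak_times) {
  ev <- rbind(data.frame(t = trough_times, kind = "trough"),
              data.frame(t = peak_times, kind = "peak"))
  ev <- ev[order(ev$t), ]
  # enforce alternation: within a run of same-kind events keep the one
  # retained by the caller's merge rules (here: first)
  keep <- c(TRUE, ev$kind[-1] != ev$kind[-nrow(ev)])
  ev <- ev[keep, ]
  out <- list()
  i <- which(ev$kind == "trough")[1]
  cyc <- 0L
  while (!is.na(i) && i + 2 <= nrow(ev)) {
    if (ev$kind[i] == "trough" && ev$kind[i + 1] == "peak" &&
        ev$kind[i + 2] == "trough") {
      cyc <- cyc + 1L
      out[[cyc]] <- data.frame(
        cycle = cyc, trough_time = ev$t[i], peak_time = ev$t[i + 1],
        next_trough_time = ev$t[i + 2],
        rising = ev$t[i + 1] - ev$t[i],
        falling = ev$t[i + 2] - ev$t[i + 1],
        total = ev$t[i + 2] - ev$t[i])
    }
    i <- i + 2
  }
  if (!length(out))
    return(data.frame(cycle = integer(0), trough_time = numeric(0),
                      peak_time = numeric(0), next_trough_time = numeric(0),
                      rising = numeric(0), falling = numeric(0),
                      total = numeric(0)))
  do.call(rbind, out)
}
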