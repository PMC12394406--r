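#' Attach temperature-scaling laws to an oscillator parameter set
#'
#' A thermal model pairs a base kinetic parameter set (the value of every
#' parameter at the reference temperature) with a map from parameter
#' names to scaling laws. Parameters absent from the map are
#' temperature-independent. Each mapped parameter is scaled
#' multiplicatively relative to the law's own value at the reference
#' temperature, so the base set is recovered exactly at `ref_T`
#' regardless of how the law is normalized.
#'
#' Kinetic rate parameters (everything except `eps`) scale with the
#' law's *rate* equivalent (duration-orientation laws are reciprocated);
#' the timescale-separation factor `eps` is a time-like quantity and
#' scales with the reciprocal, so a positive activation energy makes the
#' Cdk1 switch faster at warmer temperatures.
#'
#' @param base A [two_ode_params()] or [five_ode_params()] set, valid at
#'   `ref_T`.
#' @param laws Named list mapping parameter names to either a
#'   [rate_law()] or a single number, which is shorthand for an SE (pure
#'   Arrhenius) law with that activation energy in kJ/mol.
#' @param ref_T Reference temperature, degrees Celsius.
#' @param multipliers Optional named numeric; each named base parameter
#'   is multiplied by its factor before scaling (used for, e.g.,
#'   synthesis-rate titrations).
#' @return An object of class `"thermal_model"`.
#' @examples
#' tm <- thermal_model(two_ode_params(), laws = list(ks = 75, kd = 75,
#'                                                   ka = 75, ki = 75))
#' rates_at_temperature(tm, 30)$ks / rates_at_temperature(tm, 20)$ks
#' @export
thermal_model <- function(base, laws = list(), ref_T = 20,
                          multipliers = NULL) {
  stopifnot(inherits(base, "two_ode_params") ||
              inherits(base, "five_ode_params"))
  scalar_names <- names(base)[vapply(base, is.numeric, logical(1))]
  laws <- lapply(laws, function(l) {
    if (is.numeric(l) && length(l) == 1)
      rate_law("SE", "rate", Ea = l, ref_T = ref_T, ref_value = 1)
    else if (inherits(l, "rate_law")) l
    else stop("each law must be a rate_law or a single Ea (kJ/mol)")
  })
  bad <- setdiff(names(laws), scalar_names)
  if (length(bad))
    stop("mapped parameter(s) not in the base set: ",
         paste(bad, collapse = ", "))
  if (!is.null(multipliers)) {
    bad <- setdiff(names(multipliers), scalar_names)
    if (length(bad)) stop("unknown multiplier target(s): ",
                          paste(bad, collapse = ", "))
    if (any(multipliers <= 0)) stop("multipliers must be > 0")
    for (nm in names(multipliers)) base[[nm]] <- base[[nm]] * multipliers[[nm]]
  }
  structure(list(base = base, laws = laws, ref_T = ref_T),
            class = "thermal_model")
}

#' @export
print.thermal_model <- function(x, ...) {
  cat(sprintf("<thermal_model> ref_T = %.1f C, %d scaled parameter(s): %s\n",
              x$ref_T, length(x$laws),
              paste(names(x$laws), collapse = ", ")))
  print(x$base)
  invisible(x)
}

# time-like parameters scale inversely to rates
.time_like <- "eps"

#' Concrete kinetic parameters at a query temperature
#'
#' Evaluates every mapped scaling law at `temp_c` and returns the base
#' parameter set with mapped entries rescaled; unmapped parameters pass
#' through unchanged.
#'
#' @param tm A [thermal_model()].
#' @param temp_c Temperature, degrees Celsius.
#' @return A parameter set of the same class as `tm$base`.
#' @export
rates_at_temperature <- function(tm, temp_c) {
  stopifnot(inherits(tm, "thermal_model"))
  p <- tm$base
  for (nm in names(tm$laws)) {
    law <- tm$laws[[nm]]
    scale <- tryCatch(
      law_rate(law, temp_c) / law_rate(law, tm$ref_T),
      error = function(e) stop("scaling law for '", nm, "' failed: ",
                               conditionMessage(e)))
    if (nm %in% .time_like) scale <- 1 / scale
    p[[nm]] <- p[[nm]] * scale
  }
  p
}

simulate_params <- function(params, ...) {
  if (inherits(params, "two_ode_params")) simulate_two_ode(params, ...)
  else simulate_five_ode(params, ...)
}

#' Simulate a thermal model at one temperature
#'
#' @param tm A [thermal_model()].
#' @param temp_c Temperature, degrees Celsius.
#' @param ... Passed to [simulate_two_ode()] / [simulate_five_ode()].
#' @return A `"cc_trajectory"` with temperature metadata set.
#' @export
simulate_at_temperature <- function(tm, temp_c, ...) {
  simulate_params(rates_at_temperature(tm, temp_c), temperature = temp_c, ...)
}

#' Temperature-response curve of an oscillator thermal model
#'
#' Runs one simulation plus period detection per grid temperature and
#' summarizes oscillation period, rising/falling phase durations (last
#' complete cycle), amplitude, and arrest class. The viable temperature
#' range is the maximal contiguous run of oscillating grid points
#' containing the reference temperature; its endpoints are reported as
#' midpoints between the last oscillating and first non-oscillating grid
#' points (grid boundaries are reported as-is and flagged censored).
#'
#' @param tm A [thermal_model()].
#' @param T_grid Sorted temperatures (degrees Celsius, within 0-45).
#' @param t_end,dt Simulation length and sampling interval (minutes).
#' @param amplitude_tol Sustained-oscillation tolerance, see
#'   [detect_period()].
#' @param ... Further arguments to the simulator (tolerances etc.).
#' @return An object of class `"temp_response"`: a data.frame with one
#'   row per temperature (`temperature_C`, `oscillating`, `period`,
#'   `rising`, `falling`, `amplitude`, `arrest_class`) carrying the
#'   viable range in `attr(, "viable_range")`.
#' @export
temperature_response_curve <- function(tm, T_grid, t_end = 1000, dt = 0.1,
                                       amplitude_tol = 0.05, ...) {
  stopifnot(inherits(tm, "thermal_model"))
  if (is.unsorted(T_grid)) stop("T_grid must be sorted increasing")
  if (any(T_grid < 0 | T_grid > 45))
    stop("T_grid must lie within 0-45 degrees C")
  rows <- lapply(T_grid, function(tc) {
    tr <- tryCatch(
      simulate_at_temperature(tm, tc, t_end = t_end, dt = dt, ...),
      error = function(e) NULL)
    if (is.null(tr))
      return(data.frame(temperature_C = tc, oscillating = FALSE,
                        period = NA_real_, rising = NA_real_,
                        falling = NA_real_, amplitude = NA_real_,
                        arrest_class = "none"))
    pr <- detect_period(tr, amplitude_tol = amplitude_tol)
    rising <- falling <- NA_real_
    if (pr$oscillating) {
      pd <- tryCatch(model_phase_durations(tr, amplitude_tol = amplitude_tol),
                     error = function(e) NULL)
      if (!is.null(pd) && nrow(pd)) {
        last <- pd[nrow(pd), ]
        rising <- last$rising
        falling <- last$falling
      }
    }
    data.frame(temperature_C = tc, oscillating = pr$oscillating,
               period = pr$period, rising = rising, falling = falling,
               amplitude = pr$amplitude, arrest_class = pr$arrest_class)
  })
  out <- do.call(rbind, rows)
  attr(out, "viable_range") <- viable_range_from_grid(
    out$temperature_C, out$oscillating, ref_T = tm$ref_T)
  class(out) <- c("temp_response", "data.frame")
  out
}

# Midpoint-rule viable range around the reference temperature.
viable_range_from_grid <- function(temps, oscillating, ref_T) {
  if (!any(oscillating))
    return(list(T_min = NA_real_, T_max = NA_real_, empty = TRUE,
                censored_low = FALSE, censored_high = FALSE))
  runs <- rle(oscillating)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  osc_runs <- which(runs$values)
  # run containing (or nearest to) the reference temperature
  ref_idx <- which.min(abs(temps - ref_T))
  pick <- osc_runs[vapply(osc_runs, function(r)
    starts[r] <= ref_idx && ref_idx <= ends[r], logical(1))]
  if (!length(pick)) {
    dist <- vapply(osc_runs, function(r)
      min(abs(temps[starts[r]:ends[r]] - ref_T)), numeric(1))
    pick <- osc_runs[which.min(dist)]
  }
  i0 <- starts[pick[1]]; i1 <- ends[pick[1]]
  cl <- i0 == 1
  ch <- i1 == length(temps)
  list(T_min = if (cl) temps[i0] else (temps[i0] + temps[i0 - 1]) / 2,
       T_max = if (ch) temps[i1] else (temps[i1] + temps[i1 + 1]) / 2,
       empty = FALSE, censored_low = cl, censored_high = ch)
}

#' @export
print.temp_response <- function(x, ...) {
  vr <- attr(x, "viable_range")
  cat(sprintf("<temp_response> %d temperatures, %d oscillating\n",
              nrow(x), sum(x$oscillating)))
  if (!vr$empty)
    cat(sprintf("  viable range: %.3f%s to %.3f%s C\n",
                vr$T_min, if (vr$censored_low) " (grid edge)" else "",
                vr$T_max, if (vr$censored_high) " (grid edge)" else ""))
  else cat("  no oscillating temperatures\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' @export
plot.temp_response <- function(x, log_arrhenius = TRUE, ...) {
  osc <- x[x$oscillating, ]
  if (log_arrhenius) {
    invT <- 1 / celsius_to_kelvin(osc$temperature_C)
    plot(invT, log(osc$period), xlab = "1/T (1/K)", ylab = "ln period",
         pch = 16, ...)
  } else {
    plot(osc$temperature_C, osc$period, xlab = "temperature (C)",
         ylab = "period (min)", pch = 16, ...)
  }
  invisible(x)
}

#' Arrhenius slope of a temperature-response curve
#'
#' Fits `ln(period)` against `1/T` by ordinary least squares over the
#' oscillating grid points and converts the slope to an apparent
#' activation energy (kJ/mol). Also reports the mean second difference
#' a quadratic-in-`1/T` bowing diagnostic (`curvature` = twice the fitted
#' quadratic coefficient): positive values mean a concave-up Arrhenius
#' plot.
#'
#' @param resp A `"temp_response"`.
#' @return List with `Ea` (kJ/mol), `r_squared`, `curvature`.
#' @export
arrhenius_slope <- function(resp) {
  osc <- resp[resp$oscillating & is.finite(resp$period), ]
  if (nrow(osc) < 3) stop("need at least 3 oscillating temperatures")
  invT <- 1 / celsius_to_kelvin(osc$temperature_C)
  lnP <- log(osc$period)
  fit <- stats::lm(lnP ~ invT)
  curvature <- if (nrow(osc) >= 4) {
    x <- invT - mean(invT)
    2 * unname(stats::coef(stats::lm(lnP ~ x + I(x^2)))[3])
  } else NA_real_
  list(Ea = unname(stats::coef(fit)[2]) * GAS_CONSTANT / 1000,
       r_squared = summary(fit)$r.squared,
       curvature = curvature)
}
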