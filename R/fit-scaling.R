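#' Median-bin a duration-versus-temperature dataset
#'
#' Temperatures are rounded to the nearest integer degree Celsius and the
#' per-bin median duration is taken, yielding one duration per occupied
#' bin. This binned response is the sole input to all scaling-law fits.
#'
#' @param data data.frame with columns `temperature_C` and `duration_min`
#'   (additional columns are ignored). Already-binned input is
#'   idempotent.
#' @return An object of classes `"binned_response"`/`"data.frame"` with
#'   columns `temperature_C` (integer bin), `duration_min` (median) and
#'   `n`.
#' @export
bin_median <- function(data) {
  stopifnot(all(c("temperature_C", "duration_min") %in% names(data)))
  keep <- is.finite(data$temperature_C) & is.finite(data$duration_min)
  data <- data[keep, , drop = FALSE]
  if (!nrow(data)) stop("no finite records to bin")
  if (any(data$duration_min <= 0)) stop("durations must be > 0")
  bins <- round(data$temperature_C)
  med <- tapply(data$duration_min, bins, stats::median)
  n <- tapply(data$duration_min, bins, length)
  out <- data.frame(temperature_C = as.numeric(names(med)),
                    duration_min = as.numeric(med), n = as.integer(n))
  out <- out[order(out$temperature_C), ]
  rownames(out) <- NULL
  class(out) <- c("binned_response", "data.frame")
  out
}

in_interval <- function(temp, interval) {
  if (is.null(interval)) rep(TRUE, length(temp))
  else temp >= interval[1] & temp <= interval[2]
}

# log-duration design fits shared by SE/QE/PE
fit_log_linear <- function(kind, tempK, logdur) {
  invT <- 1 / tempK
  R <- GAS_CONSTANT / 1000 # kJ/mol/K
  if (kind == "SE") {
    cf <- stats::coef(stats::lm(logdur ~ invT))
    list(law = rate_law("SE", "duration", A = exp(cf[[1]]), Ea = cf[[2]] * R))
  } else if (kind == "QE") {
    cf <- stats::coef(stats::lm(logdur ~ invT + I(invT^2)))
    Ea <- cf[[2]] * R
    list(law = rate_law("QE", "duration", A = exp(cf[[1]]), Ea = Ea,
                        B = cf[[3]] / cf[[2]]))
  } else if (kind == "PE") {
    lT <- log(tempK)
    cf <- stats::coef(stats::lm(logdur ~ lT + invT))
    list(law = rate_law("PE", "duration", A = exp(cf[[1]]), Ea = cf[[3]] * R,
                        B = cf[[2]]))
  } else stop("unknown kind")
}

# Two-step DE initialization per the standard recipe: SE fit on the
# (cold) Arrhenius sub-interval, then an SE fit on the positive residual
# differences at the remaining temperatures, followed by full nonlinear
# refinement of all four parameters on log-durations.
fit_de <- function(tempK, dur, arrhenius_idx) {
  R <- GAS_CONSTANT / 1000
  logdur <- log(dur)
  se_all <- fit_log_linear("SE", tempK, logdur)$law
  if (sum(arrhenius_idx) >= 2) {
    se1 <- fit_log_linear("SE", tempK[arrhenius_idx], logdur[arrhenius_idx])$law
  } else se1 <- se_all
  resid <- dur - law_value_kelvin(se1, tempK)
  out_idx <- !arrhenius_idx
  floor_eps <- 1e-6 * stats::median(dur)
  start2 <- if (sum(out_idx) >= 2) {
    r2 <- pmax(resid[out_idx], floor_eps)
    fit_log_linear("SE", tempK[out_idx], log(r2))$law
  } else {
    # degenerate: tiny second branch with opposite-signed Ea
    rate_law("SE", "duration", A = floor_eps, Ea = -se1$Ea)
  }
  de_resid <- function(par) {
    logdur - log(exp(par[1] + par[2] / R / tempK) +
                   exp(par[3] + par[4] / R / tempK))
  }
  as_law <- function(par) {
    if (any(!is.finite(unlist(par)))) return(NULL)
    # a branch whose log-preexponential underflows is kept as a
    # numerically inert floor rather than failing the positivity check
    rate_law("DE", "duration",
             A1 = max(exp(par[[1]]), 1e-300), Ea1 = par[[2]],
             A2 = max(exp(par[[3]]), 1e-300), Ea2 = par[[4]])
  }
  refine <- function(start) {
    # log-A parameterization keeps both pre-exponentials positive
    st <- c(log(start$A1), start$Ea1, log(start$A2), start$Ea2)
    fit <- try(minpack.lm::nls.lm(
      par = st, fn = de_resid,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    as_law(fit$par)
  }
  starts <- list(
    list(A1 = se1$A, Ea1 = se1$Ea, A2 = start2$A, Ea2 = start2$Ea),
    # SE-degenerate start guarantees the refined fit can do no worse
    # than the plain Arrhenius fit
    list(A1 = se_all$A, Ea1 = se_all$Ea,
         A2 = se_all$A * 1e-9, Ea2 = -se_all$Ea))
  cands <- Filter(Negate(is.null),
                  c(lapply(starts, refine),
                    list(as_law(list(log(se_all$A), se_all$Ea,
                                     log(se_all$A * 1e-9), -se_all$Ea)))))
  # order branches: branch 1 = dominant at the coldest fitted temperature
  cands <- lapply(cands, function(l) {
    tmin <- min(tempK)
    v1 <- l$A1 * exp(l$Ea1 / R / tmin)
    v2 <- l$A2 * exp(l$Ea2 / R / tmin)
    if (v2 > v1)
      l[c("A1", "Ea1", "A2", "Ea2")] <- l[c("A2", "Ea2", "A1", "Ea1")]
    l
  })
  if (!length(cands))
    stop("DE nonlinear refinement failed to converge from both starts")
  mses <- vapply(cands, function(l)
    mean((logdur - log(law_value_kelvin(l, tempK)))^2), numeric(1))
  list(law = cands[[which.min(mses)]], converged = TRUE)
}

#' Fit a temperature-scaling law to duration data
#'
#' Fits one of the four scaling forms to median-binned
#' duration-versus-temperature data:
#' * `SE`: ordinary least squares of `ln(duration)` on `1/T`
#'   (slope = `Ea/R`).
#' * `DE`: two-step initialization (Arrhenius fit on a designated cold
#'   sub-interval, then an Arrhenius fit on the residual differences
#'   elsewhere) followed by full nonlinear refinement of all four
#'   parameters on log-durations. A second, Arrhenius-degenerate start
#'   ensures the refined fit is never worse than the SE fit.
#' * `QE`/`PE`: least squares in log space with an extra `1/T^2` or
#'   `ln T` regressor.
#'
#' All fits operate on the log of the duration, matching the mean squared
#' error on log-durations used to score them.
#'
#' @param data data.frame with `temperature_C` and `duration_min`, or a
#'   ready-made [bin_median()] output (re-binning is idempotent).
#' @param kind `"SE"`, `"DE"`, `"QE"` or `"PE"`.
#' @param interval Optional fit interval `c(lo, hi)` in degrees Celsius;
#'   bins outside are excluded from the fit (and from `mse_log`).
#' @param arrhenius_interval For DE: the sub-interval treated as purely
#'   Arrhenius during initialization; defaults to the coldest half of
#'   the occupied bins.
#' @param exclude_bins Integer-degree bins dropped before fitting
#'   (per-dataset outlier rule).
#' @return An object of class `"scaling_fit"` with components `law`
#'   (a duration-orientation [rate_law()]), `kind`, `interval`,
#'   `binned`, `mse_log`, `n_points`, `converged`.
#' @export
fit_scaling_law <- function(data, kind = c("SE", "DE", "QE", "PE"),
                            interval = NULL, arrhenius_interval = NULL,
                            exclude_bins = NULL) {
  kind <- match.arg(kind)
  binned <- bin_median(data)
  if (!is.null(exclude_bins))
    binned <- binned[!(binned$temperature_C %in% round(exclude_bins)), ]
  use <- binned[in_interval(binned$temperature_C, interval), ]
  npar <- c(SE = 2, DE = 4, QE = 3, PE = 3)[[kind]]
  if (nrow(use) < npar + 1)
    stop("need at least ", npar + 1, " occupied bins to fit a ", kind,
         " law (have ", nrow(use), ")")
  tempK <- celsius_to_kelvin(use$temperature_C)
  if (kind == "DE") {
    if (is.null(arrhenius_interval)) {
      ord <- sort(use$temperature_C)
      arrhenius_interval <- c(ord[1], ord[ceiling(length(ord) / 2)])
    }
    arr_idx <- in_interval(use$temperature_C, arrhenius_interval)
    res <- fit_de(tempK, use$duration_min, arr_idx)
  } else {
    res <- fit_log_linear(kind, tempK, log(use$duration_min))
    res$converged <- TRUE
  }
  fit <- structure(list(law = res$law, kind = kind,
                        interval = interval %||% range(use$temperature_C),
                        arrhenius_interval = if (kind == "DE") arrhenius_interval,
                        binned = binned, n_points = nrow(use),
                        converged = isTRUE(res$converged)),
                   class = "scaling_fit")
  fit$mse_log <- mse_log(fit, use)
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean squared error on log-durations
#'
#' @param fit A `"scaling_fit"`.
#' @param binned A [bin_median()] output (defaults to the bins the fit
#'   was built from).
#' @param interval Optional interval restriction, degrees Celsius.
#' @return Mean over bins of `(ln observed - ln predicted)^2`.
#' @export
mse_log <- function(fit, binned = fit$binned, interval = NULL) {
  use <- binned[in_interval(binned$temperature_C, interval), ]
  if (!nrow(use)) stop("interval overlaps no bins")
  pred <- evaluate_law(fit$law, use$temperature_C)
  mean((log(use$duration_min) - log(pred))^2)
}

#' Local Q10 curve of a fitted duration law
#'
#' Applies the forward-interval Q10 to the reciprocal of the fitted
#' duration law across a temperature grid.
#'
#' @param fit A `"scaling_fit"`.
#' @param T_grid Temperatures, degrees Celsius.
#' @param ... Passed to [q10_interval()].
#' @return data.frame with `temperature_C` and `q10`.
#' @export
local_q10_curve <- function(fit, T_grid, ...) {
  data.frame(temperature_C = T_grid,
             q10 = q10_interval(fit$law, T_grid, ...))
}

# The headline activation energy of a fit: for DE, branch 1 (dominant at
# the coldest fitted temperature, i.e. the Arrhenius-like branch).
primary_ea <- function(fit) {
  if (fit$kind == "DE") fit$law$Ea1 else fit$law$Ea
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> %s law on %d bins (%.0f-%.0f C), mse_log %.4g\n",
              x$kind, x$n_points, x$interval[1], x$interval[2], x$mse_log))
  print(x$law)
  invisible(x)
}

#' @export
summary.scaling_fit <- function(object, ...) {
  cat(sprintf("%s scaling-law fit\n", object$kind))
  cat(sprintf("  fit interval: %.1f to %.1f C (%d bins)\n",
              object$interval[1], object$interval[2], object$n_points))
  cat(sprintf("  apparent activation energy: %.2f kJ/mol\n",
              primary_ea(object)))
  cat(sprintf("  Q10 at 20 C: %.2f\n", q10_interval(object$law, 20)))
  cat(sprintf("  mse(log duration): %.4g\n", object$mse_log))
  invisible(object)
}

#' @export
coef.scaling_fit <- function(object, ...) {
  l <- object$law
  switch(object$kind,
         SE = c(A = l$A, Ea = l$Ea),
         DE = c(A1 = l$A1, Ea1 = l$Ea1, A2 = l$A2, Ea2 = l$Ea2),
         QE = c(A = l$A, Ea = l$Ea, B = l$B),
         PE = c(A = l$A, Ea = l$Ea, B = l$B))
}

#' Predicted durations from a fitted scaling law
#'
#' @param object A `"scaling_fit"`.
#' @param newdata Optional data.frame with `temperature_C` (or a numeric
#'   vector of temperatures); defaults to the fitted bins.
#' @param ... Unused.
#' @return Predicted durations (minutes).
#' @export
predict.scaling_fit <- function(object, newdata = NULL, ...) {
  temps <- if (is.null(newdata)) object$binned$temperature_C
  else if (is.numeric(newdata)) newdata
  else newdata$temperature_C
  evaluate_law(object$law, temps)
}

#' @export
residuals.scaling_fit <- function(object, ...) {
  use <- object$binned[in_interval(object$binned$temperature_C,
                                   object$interval), ]
  log(use$duration_min) - log(evaluate_law(object$law, use$temperature_C))
}

#' @export
fitted.scaling_fit <- function(object, ...) {
  use <- object$binned[in_interval(object$binned$temperature_C,
                                   object$interval), ]
  evaluate_law(object$law, use$temperature_C)
}

#' @export
plot.scaling_fit <- function(x, ...) {
  b <- x$binned
  invT <- 1 / celsius_to_kelvin(b$temperature_C)
  plot(invT, log(b$duration_min), xlab = "1/T (1/K)",
       ylab = "ln duration (min)", pch = 16, ...)
  tg <- seq(min(b$temperature_C), max(b$temperature_C), length.out = 200)
  graphics::lines(1 / celsius_to_kelvin(tg), log(evaluate_law(x$law, tg)),
                  col = 2)
  invisible(x)
}

#' Simulate datasets from a fitted scaling law
#'
#' Draws lognormal replicate durations around the fitted curve at the
#' fitted bins, in the duration-dataset schema - the parametric
#' counterpart of the nonparametric bootstrap.
#'
#' @param object A `"scaling_fit"`.
#' @param nsim Number of datasets.
#' @param seed Optional integer seed.
#' @param reps Replicates per temperature bin.
#' @param sigma Lognormal noise SD on log-durations; defaults to the
#'   fit's root mean squared log-residual.
#' @param ... Unused.
#' @return A list of `nsim` data.frames.
#' @export
simulate.scaling_fit <- function(object, nsim = 1, seed = NULL, reps = 10,
                                 sigma = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- sigma %||% sqrt(object$mse_log)
  temps <- object$binned$temperature_C
  mu <- evaluate_law(object$law, temps)
  lapply(seq_len(nsim), function(i) {
    data.frame(
      temperature_C = rep(temps, each = reps),
      duration_min = rep(mu, each = reps) *
        exp(sigma * stats::rnorm(length(temps) * reps)),
      replicate = rep(seq_len(reps), times = length(temps)),
      event = "simulated", label = paste0("sim_", i))
  })
}

#' Bootstrap distribution of the apparent activation energy
#'
#' Resamples observations with replacement within each integer
#' temperature bin, re-bins, refits the chosen law, and collects the
#' fitted activation energies. Summaries are the sample mean and the
#' percentile 90\% confidence interval.
#'
#' @inheritParams fit_scaling_law
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed; the resampling is fully reproducible.
#' @param warn_fail_frac,max_fail_frac Failed-refit fractions above which
#'   a warning is recorded (default 10\%) or an error thrown (50\%).
#' @return An object of class `"bootstrap_distribution"`: list with
#'   `ea` (successful draws), `mean`, `ci90`, `n_replicates`, `n_failed`,
#'   `point_estimate`, `seed`.
#' @export
bootstrap_activation_energy <- function(data, kind = "SE", interval = NULL,
                                        n_reps = 1000, seed = NULL,
                                        arrhenius_interval = NULL,
                                        exclude_bins = NULL,
                                        warn_fail_frac = 0.1,
                                        max_fail_frac = 0.5) {
  stopifnot(all(c("temperature_C", "duration_min") %in% names(data)))
  if (!is.null(seed)) set.seed(seed)
  bins <- round(data$temperature_C)
  occupied <- table(bins)
  if (sum(occupied >= 2) < 3)
    stop("bootstrap needs >= 2 replicate observations in >= 3 bins")
  point <- fit_scaling_law(data, kind, interval = interval,
                           arrhenius_interval = arrhenius_interval,
                           exclude_bins = exclude_bins)
  idx_by_bin <- split(seq_len(nrow(data)), bins)
  draws <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    take <- unlist(lapply(idx_by_bin, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]),
      use.names = FALSE)
    fit <- try(fit_scaling_law(data[take, , drop = FALSE], kind,
                               interval = interval,
                               arrhenius_interval = arrhenius_interval,
                               exclude_bins = exclude_bins), silent = TRUE)
    if (!inherits(fit, "try-error")) draws[r] <- primary_ea(fit)
  }
  n_failed <- sum(is.na(draws))
  if (n_failed > max_fail_frac * n_reps)
    stop("bootstrap failed in ", n_failed, " of ", n_reps, " replicates")
  warned <- n_failed > warn_fail_frac * n_reps
  if (warned)
    warning("bootstrap refits failed in ", n_failed, " of ", n_reps,
            " replicates")
  ea <- draws[!is.na(draws)]
  structure(list(ea = ea, mean = mean(ea),
                 ci90 = unname(stats::quantile(ea, c(0.05, 0.95))),
                 n_replicates = n_reps, n_failed = n_failed,
                 point_estimate = primary_ea(point), kind = kind,
                 seed = seed, warned = warned),
            class = "bootstrap_distribution")
}

#' @export
print.bootstrap_distribution <- function(x, ...) {
  cat(sprintf("<bootstrap_distribution> %s fit, %d replicates (%d failed)\n",
              x$kind, x$n_replicates, x$n_failed))
  cat(sprintf("  Ea: point %.2f, mean %.2f, 90%% CI [%.2f, %.2f] kJ/mol\n",
              x$point_estimate, x$mean, x$ci90[1], x$ci90[2]))
  invisible(x)
}

#' @export
plot.bootstrap_distribution <- function(x, ...) {
  graphics::hist(x$ea, breaks = 30, main = "bootstrap Ea",
                 xlab = "Ea (kJ/mol)", ...)
  graphics::abline(v = c(x$mean, x$ci90), col = c(2, 4, 4), lty = c(1, 2, 2))
  invisible(x)
}
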