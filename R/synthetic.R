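#' Specification for synthetic embryo period-versus-temperature data
#'
#' Describes one species-like dataset: a generating duration law (or a
#' thermal oscillator model whose simulated period plays that role), a
#' temperature grid with per-bin replicate counts, and a multiplicative
#' lognormal noise level. Durations are drawn as
#' `law(T) * exp(sigma * Z)` with standard-normal `Z`: fits are
#' performed on log-durations throughout, so the noise model is
#' multiplicative by design.
#'
#' @param label Dataset label (species/condition).
#' @param law A duration-orientation [rate_law()] (generating truth), or
#'   `NULL` when `thermal` is given.
#' @param thermal Optional [thermal_model()]; the simulated oscillation
#'   period at each temperature is then the generating duration.
#' @param temps Temperature grid, degrees Celsius.
#' @param reps Replicates per temperature.
#' @param sigma Lognormal noise standard deviation (on log durations).
#' @param viable_range Optional `c(lo, hi)` in degrees Celsius; outside
#'   it records are emitted censored (`NA` duration).
#' @param seed Integer seed.
#' @return An object of class `"species_spec"`.
#' @export
species_spec <- function(label = "synthetic", law = NULL, thermal = NULL,
                         temps = 10:26, reps = 10, sigma = 0.1,
                         viable_range = NULL, seed = 1) {
  if (is.null(law) && is.null(thermal))
    stop("give a generating 'law' or a 'thermal' model")
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(label = label, law = law, thermal = thermal,
                 temps = temps, reps = reps, sigma = sigma,
                 viable_range = viable_range, seed = seed),
            class = "species_spec")
}

#' Generate a synthetic period-versus-temperature dataset
#'
#' @param spec A [species_spec()].
#' @param t_end Simulation length per temperature when the generator is
#'   a thermal model, minutes.
#' @return data.frame in the duration-dataset schema (`temperature_C`,
#'   `duration_min`, `replicate`, `event`, `label`); censored records
#'   carry `NA` durations.
#' @export
gen_species_periods <- function(spec, t_end = 800) {
  stopifnot(inherits(spec, "species_spec"))
  set.seed(spec$seed)
  true_dur <- if (!is.null(spec$law)) {
    evaluate_law(spec$law, spec$temps)
  } else {
    resp <- temperature_response_curve(spec$thermal, spec$temps,
                                       t_end = t_end)
    ifelse(resp$oscillating, resp$period, NA_real_)
  }
  if (!is.null(spec$viable_range))
    true_dur[spec$temps < spec$viable_range[1] |
               spec$temps > spec$viable_range[2]] <- NA_real_
  out <- do.call(rbind, lapply(seq_along(spec$temps), function(i) {
    z <- stats::rnorm(spec$reps)
    data.frame(temperature_C = spec$temps[i],
               duration_min = true_dur[i] * exp(spec$sigma * z),
               replicate = seq_len(spec$reps),
               event = "cleavage_period", label = spec$label)
  }))
  rownames(out) <- NULL
  out
}

#' Specification for a synthetic droplet FRET experiment
#'
#' Emulates encapsulated-extract droplets on a temperature gradient:
#' each droplet is assigned a temperature along the gradient, its Cdk1
#' dynamics are simulated from the thermal two-ODE model, all rates are
#' slowed by a uniform time dilation `1 + gamma * t` (the simplest
#' mechanism reproducing the gradual period lengthening of aging
#' extracts), and the FRET ratio is `baseline + gain * cdk1a` plus
#' additive Gaussian noise. Radii are drawn lognormally and track start
#' times uniformly, so downstream quality filters see both passing and
#' failing droplets.
#'
#' @param thermal A [thermal_model()] with a two-ODE base.
#' @param n_droplets Number of droplets.
#' @param temp_range Gradient endpoints `c(lo, hi)`, degrees Celsius;
#'   droplet temperatures are evenly spaced across it.
#' @param dt Sampling interval, minutes.
#' @param t_end Run length, minutes.
#' @param baseline,gain FRET mapping: `ratio = baseline + gain * cdk1a`.
#' @param noise_sd Additive Gaussian noise on the ratio.
#' @param gamma Fractional slowdown per minute (>= 0).
#' @param radius_meanlog,radius_sdlog Lognormal radius distribution
#'   (micrometers).
#' @param start_max Track start times drawn uniformly on
#'   `[0, start_max]` minutes.
#' @param seed Integer seed.
#' @return An object of class `"droplet_spec"`.
#' @export
droplet_spec <- function(thermal, n_droplets = 200, temp_range = c(16, 32),
                         dt = 5, t_end = 1000, baseline = 1, gain = 0.01,
                         noise_sd = 0.01, gamma = 0.001,
                         radius_meanlog = log(55), radius_sdlog = 0.35,
                         start_max = 90, seed = 1) {
  stopifnot(inherits(thermal, "thermal_model"))
  if (dt <= 0) stop("sampling interval must be > 0")
  if (gamma < 0) stop("gamma must be >= 0")
  structure(list(thermal = thermal, n_droplets = n_droplets,
                 temp_range = temp_range, dt = dt, t_end = t_end,
                 baseline = baseline, gain = gain, noise_sd = noise_sd,
                 gamma = gamma, radius_meanlog = radius_meanlog,
                 radius_sdlog = radius_sdlog, start_max = start_max,
                 seed = seed),
            class = "droplet_spec")
}

# internal (undilated) time corresponding to lab time t
dilated_to_internal <- function(t, gamma) {
  if (gamma == 0) t else log(1 + gamma * t) / gamma
}

#' Generate synthetic droplet FRET traces
#'
#' @param spec A [droplet_spec()].
#' @return List of [fret_trace()] objects, one per droplet. Droplets at
#'   non-oscillating temperatures yield flat-plus-noise traces.
#' @export
gen_droplet_traces <- function(spec) {
  stopifnot(inherits(spec, "droplet_spec"))
  set.seed(spec$seed)
  temps <- seq(spec$temp_range[1], spec$temp_range[2],
               length.out = spec$n_droplets)
  radii <- stats::rlnorm(spec$n_droplets, spec$radius_meanlog,
                         spec$radius_sdlog)
  starts <- stats::runif(spec$n_droplets, 0, spec$start_max)
  tau_end <- dilated_to_internal(spec$t_end, spec$gamma)
  lapply(seq_len(spec$n_droplets), function(i) {
    lab_t <- seq(starts[i], spec$t_end, by = spec$dt)
    tau <- dilated_to_internal(lab_t, spec$gamma)
    cdk <- tryCatch({
      tr <- simulate_at_temperature(spec$thermal, temps[i],
                                    t_end = tau_end, dt = 0.2)
      stats::approx(tr$times, tr$state[, "cdk1a"], xout = tau, rule = 2)$y
    }, error = function(e) rep(0, length(tau)))
    ratio <- spec$baseline + spec$gain * cdk +
      stats::rnorm(length(tau), 0, spec$noise_sd)
    fret_trace(sprintf("droplet_%03d", i), lab_t, ratio, radii[i], temps[i])
  })
}

#' Specification for a synthetic biochemical assay panel
#'
#' @param kind Assay kind, see [assay_series()].
#' @param law Generating rate law (the truth recovered downstream);
#'   evaluated as a rate at each temperature.
#' @param temps Assay temperatures, degrees Celsius.
#' @param n_samples Samples per time series.
#' @param series_per_temp Replicate series per temperature.
#' @param t_max Duration of each series, minutes.
#' @param noise_sd Additive Gaussian noise on the signal.
#' @param baseline Signal at time zero for linear assays (decay assays
#'   start at 1 by normalization).
#' @param seed Integer seed.
#' @return An object of class `"assay_spec"`.
#' @export
assay_spec <- function(kind = "synthesis",
                       law = rate_law("SE", "rate", Ea = 87, ref_T = 20,
                                      ref_value = 0.02),
                       temps = 16:26, n_samples = 12, series_per_temp = 3,
                       t_max = 44, noise_sd = 0.02, baseline = 0.1,
                       seed = 1) {
  structure(list(kind = kind, law = law, temps = temps,
                 n_samples = n_samples, series_per_temp = series_per_temp,
                 t_max = t_max, noise_sd = noise_sd, baseline = baseline,
                 seed = seed),
            class = "assay_spec")
}

#' Generate a synthetic biochemical assay panel
#'
#' Linear assays (synthesis, kinase, phosphatase) get
#' `signal = baseline + rate(T) * t + noise`; APC/C degradation assays
#' get `signal = exp(-rate(T) * t) + noise`.
#'
#' @param spec An [assay_spec()].
#' @return List of [assay_series()] objects
#'   (`series_per_temp * length(temps)` of them).
#' @export
gen_assay_panel <- function(spec) {
  stopifnot(inherits(spec, "assay_spec"))
  set.seed(spec$seed)
  tt <- seq(0, spec$t_max, length.out = spec$n_samples)
  out <- list()
  for (tc in spec$temps) {
    rate <- law_rate(spec$law, tc)
    for (r in seq_len(spec$series_per_temp)) {
      clean <- if (spec$kind == "apc_degradation") exp(-rate * tt)
      else spec$baseline + rate * tt
      out[[length(out) + 1]] <-
        assay_series(spec$kind, tt,
                     clean + stats::rnorm(length(tt), 0, spec$noise_sd),
                     temperature_C = tc)
    }
  }
  out
}
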