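#' Canonical temperature-scaling scenarios of the two-ODE oscillator
#'
#' Builds the four standard scenarios for how enzyme-level temperature
#' scaling shapes the period of the cell-cycle oscillator:
#'
#' 1. *Case 1* - all four rates share one activation energy `E`; the
#'    period is exactly Arrhenius with that energy.
#' 2. *Case 2* - synthesis/degradation share `E`, activation/
#'    inactivation share a different energy; with strong timescale
#'    separation the period Arrhenius energy still equals `E`.
#' 3. *Case 3* - an imbalance between `Ea(ks)` and `Ea(kd)` bows the
#'    Arrhenius plot concave-up and creates finite thermal limits, with
#'    an interphase-like (low Cdk1) arrest beyond the hot limit when
#'    `Ea(ks) < Ea(kd)` and an M-phase-like (high Cdk1) arrest when the
#'    imbalance is reversed.
#' 4. *Case 4* - a biphasic (thermal-optimum) synthesis rate produces a
#'    bowed plot with an interior period minimum and a high-temperature
#'    limit.
#'
#' @param E Shared activation energy for Cases 1/2, kJ/mol.
#' @param cases Character subset of
#'   `c("case1","case2","case3","case3_reversed","case4")`.
#' @param T_grid Temperature grid, degrees Celsius.
#' @param t_end Simulation length per temperature, minutes.
#' @param base Base [two_ode_params()] (Case 2 uses a strongly
#'   timescale-separated variant with `eps = 0.005`).
#' @return Named list per case with `thermal` ([thermal_model()]),
#'   `response` (`"temp_response"`), `slope` ([arrhenius_slope()]
#'   output, where >= 3 oscillating points exist) and `viable_range`.
#' @export
run_case_scenarios <- function(E = 75,
                               cases = c("case1", "case2", "case3",
                                         "case3_reversed", "case4"),
                               T_grid = seq(4, 40, by = 1),
                               t_end = 1000,
                               base = two_ode_params()) {
  cases <- match.arg(cases, several.ok = TRUE)
  if (!length(T_grid)) stop("empty temperature grid")
  defs <- list(
    case1 = list(base = base,
                 laws = list(ks = E, kd = E, ka = E, ki = E)),
    case2 = list(base = two_ode_params(ks = base$ks, kd = base$kd,
                                       ka = base$ka, ki = base$ki,
                                       eps = 0.005, hill_d = base$hill_d,
                                       hill_a = base$hill_a,
                                       hill_i = base$hill_i),
                 laws = list(ks = E, kd = E, ka = 40, ki = 40)),
    case3 = list(base = base,
                 laws = list(ks = 30, kd = 120, ka = 60, ki = 60)),
    case3_reversed = list(base = base,
                          laws = list(ks = 120, kd = 30, ka = 60, ki = 60)),
    case4 = list(base = base,
                 laws = list(ks = de_duration_law(80, -150, weight2 = 0.05),
                             kd = E, ka = E, ki = E)))
  out <- lapply(cases, function(nm) {
    def <- defs[[nm]]
    tm <- thermal_model(def$base, laws = def$laws)
    resp <- temperature_response_curve(tm, T_grid, t_end = t_end)
    slope <- if (sum(resp$oscillating) >= 3) arrhenius_slope(resp) else NULL
    list(thermal = tm, response = resp, slope = slope,
         viable_range = attr(resp, "viable_range"))
  })
  names(out) <- cases
  out
}

#' Synthesis-rate titration of the viable temperature range
#'
#' Rescales the basal cyclin synthesis rate (and, to a lesser extent,
#' the degradation rate) of a thermal oscillator model and maps how the
#' viable temperature range and the minimum period respond. Lowering
#' synthesis narrows the range from both ends; raising it broadens the
#' range and speeds the oscillations.
#'
#' @param tm Base [thermal_model()]; defaults to the extract-like
#'   biphasic-synthesis model used by [run_case_scenarios()] Case 4 with
#'   an imbalanced Arrhenius pair.
#' @param ks_mult Synthesis multipliers.
#' @param kd_mult Degradation multipliers, recycled against `ks_mult`.
#' @param T_grid Temperature grid, degrees Celsius.
#' @param t_end Simulation length per temperature, minutes.
#' @return data.frame with one row per multiplier pair: `ks_mult`,
#'   `kd_mult`, `T_min`, `T_max`, `range_width`, `min_period`,
#'   `n_oscillating`; the per-pair responses in `attr(, "responses")`.
#' @export
run_synthesis_titration <- function(tm = default_extract_model(),
                                    ks_mult = c(1 / 3, 1 / 2, 1, 2, 5),
                                    kd_mult = c(1 / 2, 2 / 3, 1, 1.5, 3),
                                    T_grid = seq(2, 42, by = 1),
                                    t_end = 1000) {
  if (any(ks_mult <= 0) || any(kd_mult <= 0))
    stop("multipliers must be > 0")
  kd_mult <- rep_len(kd_mult, length(ks_mult))
  responses <- vector("list", length(ks_mult))
  rows <- lapply(seq_along(ks_mult), function(i) {
    tmi <- tm
    tmi$base$ks <- tm$base$ks * ks_mult[i]
    tmi$base$kd <- tm$base$kd * kd_mult[i]
    resp <- temperature_response_curve(tmi, T_grid, t_end = t_end)
    responses[[i]] <<- resp
    vr <- attr(resp, "viable_range")
    data.frame(ks_mult = ks_mult[i], kd_mult = kd_mult[i],
               T_min = vr$T_min, T_max = vr$T_max,
               range_width = if (vr$empty) 0 else vr$T_max - vr$T_min,
               min_period = if (any(resp$oscillating))
                 min(resp$period, na.rm = TRUE) else NA_real_,
               n_oscillating = sum(resp$oscillating))
  })
  out <- do.call(rbind, rows)
  attr(out, "responses") <- responses
  out
}

#' Extract-like thermal model
#'
#' Biphasic (thermal-optimum) cyclin synthesis combined with weakly
#' Arrhenius degradation and intermediate activation/inactivation
#' scaling - the configuration inferred for cycling extracts, used as
#' the default for titration and end-to-end synthetic experiments.
#'
#' @param base Base [two_ode_params()].
#' @param ref_T Reference temperature, degrees Celsius.
#' @return A [thermal_model()].
#' @export
default_extract_model <- function(base = two_ode_params(), ref_T = 20) {
  thermal_model(base,
                laws = list(ks = de_duration_law(80, -150, weight2 = 0.05,
                                                 ref_T = ref_T),
                            kd = 40, ka = 60, ki = 60),
                ref_T = ref_T)
}

#' Embryo-versus-extract rescaling check
#'
#' Embryos cycle faster than extracts; a single-point rescaling of
#' synthesis (x 1.6) and degradation (x 0.7) maps the extract-calibrated
#' model onto embryo-like timing. Reports the period at the matching
#' temperature before and after rescaling.
#'
#' @param tm Extract-calibrated [thermal_model()].
#' @param factor_ks,factor_kd Rescaling factors.
#' @param match_T Matching temperature, degrees Celsius.
#' @param t_end Simulation length, minutes.
#' @return List with `extract_period`, `embryo_period`, `ratio` at
#'   `match_T`.
#' @export
run_embryo_rescaling <- function(tm = default_extract_model(),
                                 factor_ks = 1.6, factor_kd = 0.7,
                                 match_T = 25, t_end = 600) {
  per_at <- function(model) {
    tr <- simulate_at_temperature(model, match_T, t_end = t_end)
    pr <- detect_period(tr)
    if (pr$oscillating) pr$period else NA_real_
  }
  tm2 <- tm
  tm2$base$ks <- tm$base$ks * factor_ks
  tm2$base$kd <- tm$base$kd * factor_kd
  p0 <- per_at(tm)
  p1 <- per_at(tm2)
  list(extract_period = p0, embryo_period = p1, ratio = p1 / p0)
}

#' End-to-end synthetic analysis pipeline
#'
#' Exercises every stage of the package on synthetic data generated
#' from known ground truth, and reports recovered quantities against
#' that truth: (1) embryo-like period data -> Arrhenius fit + bootstrap
#' CI; (2) droplet FRET traces from a known thermal model -> filtering,
#' cycle annotation, DE fit of total durations, log-error against the
#' model's own response curve; (3) biochemical assay panels -> rate
#' fits -> Arrhenius energies and their ordering; (4) SMC-ABC on
#' noise-free phase durations -> posterior recovery of `Ea(ks)`,
#' `Ea(kd)` and the probability of the synthesis-more-sensitive
#' ordering. Stage failures are isolated: downstream stages that depend
#' on a failed stage are skipped and the error recorded.
#'
#' @param seed Global integer seed; every stochastic stage derives its
#'   seed from it.
#' @param n_droplets,n_boot,abc_particles,abc_generations Stage sizes
#'   (defaults sized for a few minutes of runtime).
#' @param verbose Print stage progress.
#' @return An object of class `"pipeline_report"`: nested list with one
#'   element per stage (`species`, `droplets`, `assays`, `abc`), each
#'   carrying `truth`, recovered values, and `error` (NULL on success),
#'   plus a `provenance` record (seed, sizes, package version, config
#'   hash).
#' @export
run_synthetic_pipeline <- function(seed = 1, n_droplets = 60,
                                   n_boot = 200, abc_particles = 64,
                                   abc_generations = 4, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t_all <- proc.time()[3]
  config <- list(seed = seed, n_droplets = n_droplets, n_boot = n_boot,
                 abc_particles = abc_particles,
                 abc_generations = abc_generations)
  report <- list(provenance = c(config, list(
    package_version = as.character(utils::packageVersion("thermocycle")),
    config_hash = config_hash(config))))
  stage <- function(expr) {
    tryCatch(c(expr, list(error = NULL)),
             error = function(e) list(error = conditionMessage(e)))
  }

  say("stage 1/4: species periods + Arrhenius fit + bootstrap")
  report$species <- stage({
    truth_ea <- 75
    spec <- species_spec("synthetic_embryo",
                         law = rate_law("SE", "duration", Ea = truth_ea,
                                        ref_T = 20, ref_value = 30),
                         temps = 10:26, reps = 10, sigma = 0.1,
                         seed = seed)
    dat <- gen_species_periods(spec)
    fit <- fit_scaling_law(dat, "SE")
    boot <- bootstrap_activation_energy(dat, "SE", n_reps = n_boot,
                                        seed = seed + 1)
    list(truth = truth_ea, fitted_ea = primary_ea(fit),
         boot_mean = boot$mean, boot_ci90 = boot$ci90,
         covered = boot$ci90[1] <= truth_ea & truth_ea <= boot$ci90[2])
  })

  say("stage 2/4: droplet traces -> annotation -> DE fit")
  report$droplets <- stage({
    tm <- default_extract_model()
    spec <- droplet_spec(tm, n_droplets = n_droplets,
                         temp_range = c(16, 30), dt = 2, t_end = 400,
                         noise_sd = 0.005, gamma = 0, seed = seed + 2)
    traces <- gen_droplet_traces(spec)
    kept <- filter_droplets(traces)
    durs <- do.call(rbind, lapply(kept, function(tr) {
      ann <- select_cycles(annotate_cycles(tr), "first_300min")
      if (!nrow(ann)) return(NULL)
      data.frame(temperature_C = trace_meta(tr, "temperature_C"),
                 duration_min = ann$total)
    }))
    fit <- fit_scaling_law(durs, "DE")
    resp <- temperature_response_curve(tm, sort(unique(round(durs$temperature_C))),
                                      t_end = 400)
    ok <- resp$oscillating
    log_err <- stats::median(abs(log(evaluate_law(fit$law, resp$temperature_C[ok])) -
                                   log(resp$period[ok])))
    list(n_kept = length(kept), n_cycles = nrow(durs), fit = fit,
         median_abs_log_error = log_err)
  })

  say("stage 3/4: assay panels -> rates -> Arrhenius energies")
  report$assays <- stage({
    ea_syn <- 87; ea_deg <- 51
    syn <- gen_assay_panel(assay_spec("synthesis",
      law = rate_law("SE", "rate", Ea = ea_syn, ref_T = 20,
                     ref_value = 0.02), seed = seed + 3))
    apc <- gen_assay_panel(assay_spec("apc_degradation",
      law = rate_law("SE", "rate", Ea = ea_deg, ref_T = 20,
                     ref_value = 0.05), noise_sd = 0.01, seed = seed + 4))
    refit <- function(panel) {
      rates <- do.call(rbind, lapply(panel, function(s) {
        f <- fit_assay_rate(s)
        data.frame(temperature_C = f$temperature_C, rate = f$rate)
      }))
      rates <- rates[rates$rate > 0, ]
      # rates fit as reciprocal durations
      fit <- fit_scaling_law(data.frame(temperature_C = rates$temperature_C,
                                        duration_min = 1 / rates$rate), "SE")
      primary_ea(fit)
    }
    ea_syn_hat <- refit(syn)
    ea_deg_hat <- refit(apc)
    list(truth = c(synthesis = ea_syn, degradation = ea_deg),
         recovered = c(synthesis = ea_syn_hat, degradation = ea_deg_hat),
         ordering_preserved = ea_syn_hat > ea_deg_hat)
  })

  say("stage 4/4: SMC-ABC recovery of activation energies")
  report$abc <- stage({
    truth <- c(Ea_ks = 100, Ea_kd = 40)
    T_grid <- seq(14, 26, by = 3)
    fwd <- thermal_forward_model(two_ode_params(), T_grid, mode = "se")
    observed <- fwd(truth)
    prior <- prior_spec(lower = c(Ea_ks = 0, Ea_kd = 0),
                        upper = c(Ea_ks = 200, Ea_kd = 200))
    post <- smc_abc(fwd, prior, observed, n_particles = abc_particles,
                    n_generations = abc_generations, seed = seed + 5)
    summ <- posterior_summary(post)
    p_order <- sum(post$weights[post$particles[, "Ea_ks"] >
                                  post$particles[, "Ea_kd"]])
    list(truth = truth, summary = summ, p_ks_gt_kd = p_order,
         posterior = post)
  })

  report$elapsed_s <- unname(proc.time()[3] - t_all)
  class(report) <- "pipeline_report"
  report
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(config), collapse = ""), f)
  unname(tools::md5sum(f))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  for (nm in c("species", "droplets", "assays", "abc")) {
    st <- x[[nm]]
    if (is.null(st)) next
    if (!is.null(st$error)) {
      cat(sprintf("  %s: FAILED (%s)\n", nm, st$error))
    } else {
      cat(sprintf("  %s: ok\n", nm))
    }
  }
  cat(sprintf("  elapsed: %.1f s (seed %d)\n", x$elapsed_s,
              x$provenance$seed))
  invisible(x)
}
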