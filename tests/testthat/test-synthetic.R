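test_that("species-period generator is exact at zero noise and seed-stable", {
  law <- rate_law("SE", "duration", Ea = 75, ref_T = 20, ref_value = 30)
  spec <- species_spec("x", law = law, temps = 12:20, reps = 3, sigma = 0,
                       seed = 5)
  d <- gen_species_periods(spec)
  expect_equal(d$duration_min,
               rep(evaluate_law(law, 12:20), each = 3))

  spec2 <- species_spec("x", law = law, temps = 12:20, reps = 3,
                        sigma = 0.1, seed = 5)
  expect_identical(gen_species_periods(spec2), gen_species_periods(spec2))

  # censoring outside the viable range
  spec3 <- species_spec("x", law = law, temps = 10:25, reps = 2,
                        sigma = 0, viable_range = c(12, 21), seed = 1)
  d3 <- gen_species_periods(spec3)
  expect_true(all(is.na(d3$duration_min[d3$temperature_C < 12])))
  expect_true(all(is.finite(d3$duration_min[d3$temperature_C %in% 12:21])))
})

test_that("downstream fits recover the generating activation energy", {
  law <- rate_law("SE", "duration", Ea = 75, ref_T = 20, ref_value = 30)
  eas <- sapply(1:10, function(s) {
    spec <- species_spec("x", law = law, temps = 10:22, reps = 10,
                         sigma = 0.1, seed = s)
    coef(fit_scaling_law(gen_species_periods(spec), "SE"))[["Ea"]]
  })
  expect_rel_equal(median(eas), 75, 0.03)
})

test_that("noise-free droplet traces reproduce the model period; drift lengthens cycles", {
  tm <- thermal_model(two_ode_params(), laws = list(ks = 75, kd = 75,
                                                    ka = 75, ki = 75))
  spec <- droplet_spec(tm, n_droplets = 4, temp_range = c(20, 24),
                       dt = 1, t_end = 300, noise_sd = 0, gamma = 0,
                       start_max = 30, seed = 2)
  traces <- gen_droplet_traces(spec)
  for (tr in traces) {
    ann <- annotate_cycles(tr)
    expect_gte(nrow(ann), 3)
    model_period <- detect_period(
      simulate_at_temperature(tm, attr(tr, "temperature_C"),
                              t_end = 300))$period
    expect_lt(abs(median(ann$total) - model_period), 1 + 1e-9)
  }

  specd <- droplet_spec(tm, n_droplets = 6, temp_range = c(20, 24),
                        dt = 1, t_end = 500, noise_sd = 0, gamma = 0.002,
                        start_max = 10, seed = 3)
  slopes <- sapply(gen_droplet_traces(specd), function(tr) {
    ann <- annotate_cycles(tr)
    if (nrow(ann) < 3) return(NA_real_)
    coef(lm(ann$total ~ ann$cycle))[[2]]
  })
  expect_gt(median(slopes, na.rm = TRUE), 0)
})

test_that("droplet radii and start times exercise both sides of the quality filter", {
  tm <- thermal_model(two_ode_params(), laws = list())
  spec <- droplet_spec(tm, n_droplets = 40, temp_range = c(20, 21),
                       dt = 10, t_end = 100, seed = 11)
  traces <- gen_droplet_traces(spec)
  kept <- filter_droplets(traces)
  expect_gt(length(kept), 0)
  expect_lt(length(kept), 40)
})

test_that("assay panels recover their generating law", {
  law <- rate_law("SE", "rate", Ea = 87, ref_T = 20, ref_value = 0.02)
  spec <- assay_spec("synthesis", law, temps = 16:26, noise_sd = 0,
                     seed = 4)
  panel <- gen_assay_panel(spec)
  expect_length(panel, 3 * 11)
  for (s in panel[c(1, 15, 33)]) {
    f <- fit_assay_rate(s)
    expect_equal(f$rate, law_rate(law, s$temperature_C), tolerance = 1e-9)
  }

  # with noise, per-temperature medians sit on the law within 2 sd/sqrt(n)
  specn <- assay_spec("synthesis", law, temps = 16:26, noise_sd = 0.02,
                      series_per_temp = 8, seed = 6)
  rates <- do.call(rbind, lapply(gen_assay_panel(specn), function(s) {
    f <- fit_assay_rate(s)
    data.frame(temperature_C = f$temperature_C, rate = f$rate)
  }))
  med <- tapply(rates$rate, rates$temperature_C, median)
  truth <- law_rate(law, as.numeric(names(med)))
  spread <- tapply(rates$rate, rates$temperature_C, sd)
  # per-bin ~95% band (2 se of the median, se_median ~ 1.25 sd/sqrt(n));
  # nearly all of the 11 bins should fall inside it
  inside <- abs(med - truth) <= 2 * 1.25 * spread / sqrt(8) + 1e-12
  expect_gte(mean(inside), 9 / 11)
})

test_that("decay-assay panels preserve the synthesis/degradation Ea ordering", {
  refit_ea <- function(kind, ea, ref_value, noise, seed) {
    spec <- assay_spec(kind,
                       rate_law("SE", "rate", Ea = ea, ref_T = 20,
                                ref_value = ref_value),
                       temps = 16:26, noise_sd = noise, seed = seed)
    rates <- do.call(rbind, lapply(gen_assay_panel(spec), function(s) {
      f <- fit_assay_rate(s)
      data.frame(temperature_C = f$temperature_C, rate = f$rate)
    }))
    rates <- rates[rates$rate > 0, ]
    coef(fit_scaling_law(data.frame(temperature_C = rates$temperature_C,
                                    duration_min = 1 / rates$rate),
                         "SE"))[["Ea"]]
  }
  ok <- sapply(1:10, function(s)
    refit_ea("synthesis", 87, 0.02, 0.02, s) >
      refit_ea("apc_degradation", 51, 0.05, 0.01, s + 100))
  expect_gte(mean(ok), 0.9)
})
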