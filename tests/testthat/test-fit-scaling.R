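make_se_data <- function(ea = 75, temps = 10:22, reps = 1, sigma = 0,
                         ref_value = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  law <- rate_law("SE", "duration", Ea = ea, ref_T = 20,
                  ref_value = ref_value)
  data.frame(
    temperature_C = rep(temps, each = reps),
    duration_min = rep(evaluate_law(law, temps), each = reps) *
      exp(sigma * rnorm(length(temps) * reps)))
}

test_that("binning rounds to integer degrees and takes per-bin medians", {
  b <- bin_median(data.frame(temperature_C = c(20.4, 19.6),
                             duration_min = c(30, 34)))
  expect_equal(nrow(b), 1)
  expect_equal(b$temperature_C, 20)
  expect_equal(b$duration_min, 32)
  expect_equal(b$n, 2L)

  # identical durations per temperature pass through
  d <- data.frame(temperature_C = rep(10:12, each = 3),
                  duration_min = rep(c(50, 40, 33), each = 3))
  expect_equal(bin_median(d)$duration_min, c(50, 40, 33))

  # idempotence
  b2 <- bin_median(b)
  expect_equal(b2$duration_min, b$duration_min)
  expect_equal(b2$temperature_C, b$temperature_C)
})

test_that("bin medians converge to the generating median under lognormal noise", {
  set.seed(99)
  temps <- 15:18
  true_med <- c(40, 35, 31, 27)
  d <- data.frame(
    temperature_C = rep(temps, each = 500),
    duration_min = rep(true_med, each = 500) * exp(0.2 * rnorm(2000)))
  expect_rel_equal(bin_median(d)$duration_min, true_med, 0.02)
})

test_that("noiseless generator parameters are recovered by each fit kind", {
  # SE: exact log-linear fit
  fit <- fit_scaling_law(make_se_data(ea = 75), "SE")
  expect_rel_equal(coef(fit)[["Ea"]], 75, 1e-6)
  expect_lt(fit$mse_log, 1e-20)

  # DE: U-shaped duration with a 20% second branch at 20 C
  true_de <- de_duration_law(85, -120, weight2 = 0.2, ref_T = 20,
                             ref_value = 30)
  d <- data.frame(temperature_C = 8:30,
                  duration_min = evaluate_law(true_de, 8:30))
  fit_de <- fit_scaling_law(d, "DE")
  expect_rel_equal(coef(fit_de)[["Ea1"]], true_de$Ea1, 0.005)
  expect_rel_equal(coef(fit_de)[["Ea2"]], true_de$Ea2, 0.005)
  expect_rel_equal(coef(fit_de)[["A1"]], true_de$A1, 0.005)
  expect_rel_equal(coef(fit_de)[["A2"]], true_de$A2, 0.005)

  # QE
  true_qe <- rate_law("QE", "duration", A = 1e-10, Ea = 70, B = 35)
  dq <- data.frame(temperature_C = 10:24,
                   duration_min = evaluate_law(true_qe, 10:24))
  fit_qe <- fit_scaling_law(dq, "QE")
  expect_rel_equal(coef(fit_qe)[["Ea"]], 70, 1e-6)
  expect_rel_equal(coef(fit_qe)[["B"]], 35, 1e-4)

  # PE
  true_pe <- rate_law("PE", "duration", A = 1e-15, Ea = 60, B = 3)
  dp <- data.frame(temperature_C = 10:24,
                   duration_min = evaluate_law(true_pe, 10:24))
  fit_pe <- fit_scaling_law(dp, "PE")
  expect_rel_equal(coef(fit_pe)[["Ea"]], 60, 1e-5)
  expect_rel_equal(coef(fit_pe)[["B"]], 3, 1e-4)
})

test_that("restricting to a 12-21 C window keeps the generated Ea in band", {
  set.seed(4)
  d <- make_se_data(ea = 70, temps = 9:29, reps = 8, sigma = 0.08)
  fit <- fit_scaling_law(d, "SE", interval = c(12, 21))
  expect_gt(coef(fit)[["Ea"]], 60)
  expect_lt(coef(fit)[["Ea"]], 80)
})

test_that("mse_log matches its definition", {
  fit <- fit_scaling_law(make_se_data(), "SE")
  expect_equal(mse_log(fit), 0, tolerance = 1e-12)

  # predictions uniformly e*observed give exactly 1
  shifted <- fit
  shifted$law$A <- fit$law$A / exp(1)
  expect_equal(mse_log(shifted, fit$binned), 1, tolerance = 1e-9)

  # explicit-loop oracle on random data
  set.seed(5)
  for (i in 1:10) {
    d <- make_se_data(ea = runif(1, 40, 110), reps = 3, sigma = 0.15)
    f <- fit_scaling_law(d, "SE")
    b <- f$binned
    acc <- 0
    for (r in seq_len(nrow(b)))
      acc <- acc + (log(b$duration_min[r]) -
                      log(evaluate_law(f$law, b$temperature_C[r])))^2
    expect_equal(f$mse_log, acc / nrow(b), tolerance = 1e-12)
  }
})

test_that("flexible forms never fit worse than the Arrhenius baseline", {
  set.seed(6)
  for (i in 1:5) {
    d <- make_se_data(ea = runif(1, 50, 100), temps = 8:28, reps = 5,
                      sigma = 0.12)
    mse_se <- fit_scaling_law(d, "SE")$mse_log
    for (kind in c("DE", "QE", "PE"))
      expect_lte(fit_scaling_law(d, kind)$mse_log, mse_se + 1e-12)
  }
})

test_that("activation energies are invariant to duration unit rescaling", {
  d <- make_se_data(ea = 88, reps = 4, sigma = 0.1, seed = 8)
  d2 <- transform(d, duration_min = duration_min * 1440) # minutes -> days^-1 scale
  for (kind in c("SE", "QE", "PE", "DE")) {
    f1 <- fit_scaling_law(d, kind)
    f2 <- fit_scaling_law(d2, kind)
    e1 <- if (kind == "DE") coef(f1)[c("Ea1", "Ea2")] else coef(f1)[["Ea"]]
    e2 <- if (kind == "DE") coef(f2)[c("Ea1", "Ea2")] else coef(f2)[["Ea"]]
    expect_rel_equal(e2, e1, 1e-6)
  }
})

test_that("the outlier-exclusion rule drops the designated bin", {
  d <- make_se_data(temps = 10:20)
  d$duration_min[d$temperature_C == 10] <- d$duration_min[1] * 3 # outlier
  f_all <- fit_scaling_law(d, "SE")
  f_excl <- fit_scaling_law(d, "SE", exclude_bins = 10)
  expect_false(10 %in% f_excl$binned$temperature_C)
  expect_rel_equal(coef(f_excl)[["Ea"]], 75, 1e-6)
  expect_gt(abs(coef(f_all)[["Ea"]] - 75), 1)
})

test_that("local Q10 curves follow the fitted law", {
  fit <- fit_scaling_law(make_se_data(ea = 75), "SE")
  q <- local_q10_curve(fit, c(10, 20, 30))
  expect_equal(round(q$q10[q$temperature_C == 20], 1), 2.8)

  flat <- fit_scaling_law(make_se_data(ea = 0), "SE")
  expect_equal(local_q10_curve(flat, 10:20)$q10, rep(1, 11),
               tolerance = 1e-9)

  de_data <- data.frame(
    temperature_C = 8:30,
    duration_min = evaluate_law(de_duration_law(85, -120, 0.05,
                                                ref_value = 30), 8:30))
  fde <- fit_scaling_law(de_data, "DE")
  grid <- seq(10, 28, by = 2)
  brute <- evaluate_law(fde$law, grid) / evaluate_law(fde$law, grid + 10)
  expect_equal(local_q10_curve(fde, grid)$q10, brute, tolerance = 1e-9)
})

test_that("prediction, residuals and simulation methods are coherent", {
  d <- make_se_data(reps = 5, sigma = 0.1, seed = 10)
  fit <- fit_scaling_law(d, "SE")
  expect_equal(predict(fit, c(20)), evaluate_law(fit$law, 20))
  expect_equal(length(residuals(fit)), nrow(fit$binned))
  sims <- simulate(fit, nsim = 2, seed = 1, reps = 4)
  expect_length(sims, 2)
  refit <- fit_scaling_law(sims[[1]], "SE")
  expect_rel_equal(coef(refit)[["Ea"]], coef(fit)[["Ea"]], 0.25)
})

test_that("bootstrap on zero-noise data degenerates to the point estimate", {
  d <- make_se_data(reps = 5, sigma = 0)
  boot <- bootstrap_activation_energy(d, "SE", n_reps = 50, seed = 1)
  expect_true(all(abs(boot$ea - boot$point_estimate) < 1e-9))
  expect_equal(boot$ci90[1], boot$ci90[2], tolerance = 1e-9)
})

test_that("bootstrap is seed-reproducible and tightens with sample size", {
  d <- make_se_data(reps = 10, sigma = 0.1, seed = 12)
  b1 <- bootstrap_activation_energy(d, "SE", n_reps = 100, seed = 7)
  b2 <- bootstrap_activation_energy(d, "SE", n_reps = 100, seed = 7)
  expect_identical(b1$ea, b2$ea)

  widths <- sapply(c(5, 50), function(reps) {
    mean(replicate(8, {
      dd <- make_se_data(reps = reps, sigma = 0.1)
      b <- bootstrap_activation_energy(dd, "SE", n_reps = 100,
                                       seed = sample.int(1e6, 1))
      diff(b$ci90)
    }))
  })
  expect_lt(widths[2], widths[1])
})

test_that("insufficient data is rejected with clear errors", {
  expect_error(fit_scaling_law(make_se_data(temps = 10:11), "DE"),
               "at least 5 occupied bins")
  expect_error(
    bootstrap_activation_energy(make_se_data(temps = 10:20, reps = 1), "SE"),
    ">= 2 replicate")
})
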