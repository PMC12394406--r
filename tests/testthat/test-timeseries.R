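test_that("droplet filter applies strict radius and start-time cuts", {
  mk <- function(r, t0) fret_trace("d", seq(t0, t0 + 50, 5),
                                   rep(1, 11), r, 20)
  expect_length(filter_droplets(list(mk(100.0, 0))), 0) # boundary excluded
  expect_length(filter_droplets(list(mk(99.9, 59.9))), 1)
  expect_length(filter_droplets(list(mk(50, 60))), 0)
  expect_length(filter_droplets(list(mk(50, 0))), 1)

  set.seed(31)
  traces <- lapply(1:50, function(i)
    mk(runif(1, 20, 150), runif(1, 0, 120)))
  kept <- filter_droplets(traces)
  manual <- Filter(function(tr)
    attr(tr, "radius_um") < 100 && attr(tr, "t_start") < 60, traces)
  expect_identical(kept, manual)
})

test_that("cycle annotation recovers a known sawtooth", {
  tr <- sawtooth_trace(rise = 25, fall = 5, n_cycles = 6, dt = 0.5)
  ann <- annotate_cycles(tr)
  expect_gte(nrow(ann), 4)
  expect_true(all(abs(ann$rising - 25) <= 1))
  expect_true(all(abs(ann$falling - 5) <= 1))
  expect_true(all(ann$trough_time < ann$peak_time &
                    ann$peak_time < ann$next_trough_time))
  expect_equal(ann$rising + ann$falling, ann$total)
})

test_that("annotation is invariant to offset and positive scaling", {
  tr <- sawtooth_trace()
  ann0 <- annotate_cycles(tr)
  tr2 <- tr
  tr2$ratio <- 5 + 3 * tr$ratio
  ann2 <- annotate_cycles(tr2)
  expect_equal(ann0$trough_time, ann2$trough_time)
  expect_equal(ann0$peak_time, ann2$peak_time)
})

test_that("annotated periods agree with the autocorrelation oracle", {
  set.seed(17)
  for (i in 1:20) {
    period <- runif(1, 20, 50)
    frac <- runif(1, 0.7, 0.9)
    dt <- 1
    tr <- sawtooth_trace(rise = frac * period, fall = (1 - frac) * period,
                         n_cycles = 8, dt = dt)
    tr$ratio <- tr$ratio + rnorm(nrow(tr), 0, 0.01)
    ann <- annotate_cycles(tr)
    expect_gte(nrow(ann), 3)
    expect_lt(abs(median(ann$total) - acf_period(tr$ratio, dt)) /
                period, 0.05)
  }
})

test_that("non-monotone time is rejected; featureless traces yield empty annotation", {
  expect_error(annotate_cycles(data.frame(time_min = c(0, 2, 1),
                                          ratio = c(1, 2, 3))),
               "strictly increasing")
  flat <- fret_trace("f", seq(0, 100, 5), rep(1, 21), 50, 20)
  expect_equal(nrow(annotate_cycles(flat)), 0)
})

test_that("cycle selection modes follow their definitions", {
  ann <- data.frame(cycle = 1:6,
                    trough_time = seq(0, 250, by = 50),
                    peak_time = seq(40, 290, by = 50),
                    next_trough_time = seq(50, 300, by = 50),
                    rising = 40, falling = 10, total = 50)
  expect_equal(select_cycles(ann, "cycles_2_to_4")$cycle, 2:4)
  expect_equal(select_cycles(ann, "first_300min")$cycle, 1:6)

  set.seed(23)
  for (i in 1:50) {
    n <- sample(1:8, 1)
    starts <- cumsum(runif(n, 20, 80))
    a <- data.frame(cycle = seq_len(n), trough_time = starts - 20,
                    peak_time = starts - 5, next_trough_time = starts,
                    rising = 15, falling = 5, total = 20)
    expect_equal(select_cycles(a, "cycles_2_to_4")$cycle,
                 a$cycle[a$cycle %in% 2:4])
    expect_equal(select_cycles(a, "first_300min")$cycle,
                 a$cycle[a$next_trough_time <= 300])
  }
})

test_that("interphase slope is exact on linear segments and matches OLS", {
  tt <- seq(0, 30, by = 1)
  tr <- fret_trace("lin", tt, 1 + 0.02 * tt, 50, 20)
  ann <- data.frame(cycle = 1, trough_time = 0, peak_time = 30,
                    next_trough_time = 30, rising = 30, falling = 0,
                    total = 30)
  sl <- interphase_slope(tr, ann)
  expect_lt(abs(sl$median - 0.02), 1e-9)

  set.seed(29)
  for (i in 1:5) {
    y <- cumsum(rnorm(31, 0.05, 0.2))
    tr2 <- fret_trace("r", tt, y, 50, 20)
    sl2 <- interphase_slope(tr2, ann)$median
    sel <- tt >= 6 & tt <= 24 # central 60% of the 0-30 segment
    ols <- coef(lm(y[sel] ~ tt[sel]))[[2]]
    expect_equal(sl2, ols, tolerance = 1e-9)
  }
})

test_that("average waveform reproduces identical cycles and is sawtooth-skewed", {
  tr <- sawtooth_trace(rise = 24, fall = 6, n_cycles = 8, dt = 0.25)
  ann <- annotate_cycles(tr)
  avg <- average_waveform(list(tr), list(ann))
  expect_equal(nrow(avg), 100)
  # identical cycles: zero dispersion and exact sawtooth shape
  expect_lt(max(avg$sd), 1e-9)
  expect_gt(avg$phase[which.max(avg$mean)], 0.5)
  # the rising limb is linear in phase
  rising <- avg[avg$phase > 0.1 & avg$phase < 0.7, ]
  fit <- lm(mean ~ phase, data = rising)
  expect_lt(max(abs(resid(fit))), 0.02)
})

test_that("assay rates are recovered per kind", {
  tt <- seq(0, 40, by = 4)
  # exact exponential decay, rate 0.1/min
  dec <- assay_series("apc_degradation", tt, 2.4 * exp(-0.1 * tt), 22)
  f <- fit_assay_rate(dec)
  expect_lt(abs(f$rate - 0.1), 1e-6)

  # linear fits equal closed-form OLS
  set.seed(37)
  for (i in 1:5) {
    y <- 0.1 + 0.03 * tt + rnorm(length(tt), 0, 0.02)
    lin <- assay_series("synthesis", tt, y, 20)
    expect_equal(fit_assay_rate(lin)$rate, coef(lm(y ~ tt))[[2]],
                 tolerance = 1e-9)
  }

  # increasing signal in a decay assay warns
  up <- assay_series("apc_degradation", tt, 1 + 0.01 * tt, 20)
  expect_warning(fit_assay_rate(up), "increases")
})

test_that("droplet and duration CSV round-trips are lossless", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  traces <- list(fret_trace("a", c(0, 5, 10), c(1, 1.2, 1.1), 40, 18),
                 fret_trace("b", c(2, 7, 12), c(1.1, 1.3, 1.2), 80, 25))
  write_droplet_traces(traces, tmp)
  back <- read_droplet_traces(tmp)
  expect_equal(length(back), 2)
  expect_equal(back[["a"]]$ratio, traces[[1]]$ratio)
  expect_equal(attr(back[["b"]], "radius_um"), 80)

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(temperature_C = c(18.2, 20.1), duration_min = c(40, 31),
                  replicate = 1:2, event = "cleavage_period", label = "x")
  write_duration_data(d, tmp2)
  expect_equal(read_duration_data(tmp2), d)
})
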