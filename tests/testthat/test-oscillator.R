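test_that("reference two-ODE parameters sustain a ~30 min relaxation oscillation", {
  tr <- simulate_two_ode(two_ode_params(), t_end = 600)
  pr <- detect_period(tr)
  expect_true(pr$oscillating)
  expect_gt(pr$period, 20)
  expect_lt(pr$period, 40)
  pd <- model_phase_durations(tr)
  # interphase (rising) dominates the cycle
  expect_gt(median(pd$rising), 5 * median(pd$falling))
})

test_that("zero synthesis from an empty state stays empty", {
  p <- two_ode_params(ks = 0)
  tr <- simulate_two_ode(p, t_end = 200)
  expect_lt(max(tr$state[, "cyc"]), 1e-8)
  expect_lt(max(tr$state[, "cdk1a"]), 1e-8)
  expect_false(detect_period(tr)$oscillating)
})

test_that("stiff solver agrees with brute-force fixed-step RK4", {
  p <- two_ode_params()
  tr <- simulate_two_ode(p, t_end = 200, dt = 0.1)
  # start on the attractor, integrate 20 min with both methods
  i0 <- which(tr$times == 150)
  y0 <- tr$state[i0, ]
  brute <- rk4_integrate(two_ode_rhs, y0, 0, 20, 1e-4, p)
  fine <- simulate_two_ode(p, t_end = 20, dt = 0.1, initial_state = y0)
  expect_lt(max(abs(fine$state[nrow(fine$state), ] - brute)), 1e-3)
})

test_that("trajectories satisfy the phase-plane containment invariants", {
  tr <- simulate_two_ode(two_ode_params(), t_end = 500)
  expect_true(all(tr$state[, "cyc"] >= 0))
  expect_true(all(tr$state[, "cdk1a"] <= tr$state[, "cyc"] + 1e-6))
})

test_that("detect_period recovers known waveforms", {
  tt <- seq(0, 100, by = 0.05)
  sine <- make_trajectory(tt, 5 + sin(2 * pi * tt / 10))
  pr <- detect_period(sine)
  expect_true(pr$oscillating)
  expect_lt(abs(pr$period - 10), 0.05 + 1e-9)

  # 20% amplitude loss per 10-min cycle: a damped, not sustained, oscillation
  damped <- make_trajectory(tt, 0.8^(tt / 10) * (5 + sin(2 * pi * tt / 10)))
  expect_false(detect_period(damped)$oscillating)
})

test_that("empty trajectories are rejected", {
  empty <- make_trajectory(numeric(0), numeric(0))
  expect_error(detect_period(empty), "empty")
})

test_that("phase durations: symmetric wave splits evenly, sum equals period", {
  tt <- seq(0, 120, by = 0.05)
  tri <- make_trajectory(tt, 5 + abs((tt %% 12) - 6))
  pd <- model_phase_durations(tri)
  expect_true(all(abs(pd$rising - 6) <= 0.1))
  expect_true(all(abs(pd$falling - 6) <= 0.1))

  set.seed(11)
  for (i in 1:10) {
    p <- two_ode_params(ks = runif(1, 0.9, 1.6), kd = runif(1, 0.15, 0.4))
    tr <- simulate_two_ode(p, t_end = 400)
    pr <- detect_period(tr)
    if (!pr$oscillating) next
    pd <- model_phase_durations(tr)
    expect_lt(abs(median(pd$total) - pr$period), 0.2 + 1e-9)
  }
})

test_that("common rate rescaling divides the period by the same factor", {
  p <- two_ode_params()
  base <- detect_period(simulate_two_ode(p, t_end = 500))$period
  for (c_fac in c(0.5, 2)) {
    pc <- two_ode_params(ks = p$ks * c_fac, kd = p$kd * c_fac,
                         ka = p$ka * c_fac, ki = p$ki * c_fac,
                         eps = p$eps,
                         hill_d = p$hill_d, hill_a = p$hill_a,
                         hill_i = p$hill_i)
    per <- detect_period(simulate_two_ode(pc, t_end = 500 / c_fac))$period
    expect_rel_equal(per, base / c_fac, 0.01)
  }
})

test_that("period detection is stable under time-grid refinement", {
  p <- two_ode_params()
  p1 <- detect_period(simulate_two_ode(p, t_end = 400, dt = 0.1))$period
  p2 <- detect_period(simulate_two_ode(p, t_end = 400, dt = 0.02))$period
  expect_lt(abs(p1 - p2), 0.1)
})

test_that("nullclines have the documented closed forms and intersections", {
  p <- two_ode_params()
  nc <- nullclines(p, seq(0, 100, by = 0.5))
  # cyclin nullcline depends only on ks/kd
  p2 <- two_ode_params(ks = p$ks * 2, kd = p$kd * 2)
  nc2 <- nullclines(p2, seq(0, 100, by = 0.5))
  expect_equal(nc$curves$cyc_nullcline, nc2$curves$cyc_nullcline)

  # constant degradation response makes it the horizontal line ks/kd
  pflat <- two_ode_params(hill_d = hill_response(1, 1, 32, 15, "increasing"))
  ncf <- nullclines(pflat, seq(0, 50, by = 1))
  expect_equal(ncf$curves$cyc_nullcline,
               rep(pflat$ks / pflat$kd, 51))

  expect_gt(nrow(nc$intersections), 0)
})

test_that("arrest states: steady state matches the algebraic relation and nullcline crossing", {
  # large kd arrests the oscillator in interphase
  p <- two_ode_params(kd = 5)
  res <- classify_arrest(p)
  expect_equal(res$arrest_class, "low_cdk1")
  expect_lt(res$residual_norm, 1e-8)
  ss <- res$steady_state
  expect_lt(abs(ss[["cyc"]] -
                  p$ks / (p$kd * hill_value(p$hill_d, ss[["cdk1a"]]))),
            1e-6)
  nc <- nullclines(p, seq(max(ss[["cdk1a"]] - 2, 0), ss[["cdk1a"]] + 2,
                          by = 0.001))
  d <- sqrt((nc$intersections$cdk1a - ss[["cdk1a"]])^2 +
              (nc$intersections$cyc - ss[["cyc"]])^2)
  expect_lt(min(d), 1e-3)
  # oscillating input is rejected
  expect_error(classify_arrest(two_ode_params()), "detect_period")
})

test_that("five-ODE reference parameters oscillate; zero synthesis decays", {
  tr <- simulate_five_ode(five_ode_params(), t_end = 500)
  pr <- detect_period(tr)
  expect_true(pr$oscillating)
  expect_gt(pr$period, 20)
  expect_lt(pr$period, 40)

  p0 <- five_ode_params(ks = 0)
  start <- c(c = 20, g = 10, s = 50, y = 20, a = 10)
  tr0 <- simulate_five_ode(p0, t_end = 400, initial_state = start)
  expect_false(detect_period(tr0)$oscillating)
  cc <- tr0$state[, "cyc"]
  expect_true(all(diff(cc) <= 1e-8))
  expect_lt(cc[length(cc)], cc[1])
})

test_that("five-ODE reduction matches the fully expanded mass-action system", {
  # expanded system carries inactive Greatwall, unphosphorylated ENSA and
  # free PP2A as explicit states; their mass-action kinetics mirror the
  # reduced model without using the conservation shortcuts
  p <- five_ode_params()
  expanded_rhs <- function(t, v, q) {
    c_ <- v[1]; g <- v[2]; gi <- v[3]; s <- v[4]; su <- v[5]
    y <- v[6]; pf <- v[7]; a <- v[8]
    phos_g <- q$k1 * c_ * gi
    deph_g <- q$k2 * pf * g + q$kb * g
    phos_s <- q$k3 * g * su
    bind <- q$kass * s * pf
    release <- q$kcat * y
    act_a <- q$k5 * c_ * (q$Atot - a)
    inact_a <- q$k6 * pf * a
    list(c(q$ks - q$kd * a * c_,
           phos_g - deph_g, deph_g - phos_g,
           phos_s - bind, release - phos_s,
           bind - release, release - bind,
           act_a - inact_a))
  }
  v0 <- c(0, 0, p$Gtot, 0, p$Stot, 0, p$Ptot, 0)
  times <- seq(0, 150, by = 0.1)
  full <- deSolve::ode(v0, times, expanded_rhs, p, method = "lsoda",
                       rtol = 1e-10, atol = 1e-12)
  # conserved pools stay constant
  expect_lt(max(abs(full[, 3] + full[, 4] - p$Gtot)), 1e-6)
  expect_lt(max(abs(full[, 5] + full[, 6] + full[, 7] - p$Stot)), 1e-6)
  expect_lt(max(abs(full[, 7] + full[, 8] - p$Ptot)), 1e-6)
  # and the reduced model reproduces the expanded trajectory
  red <- simulate_five_ode(p, t_end = 150, dt = 0.1,
                           rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(red$state[, "cyc"] - full[, 2])), 1e-4)
  expect_lt(max(abs(red$state[, "apc"] - full[, 9])), 1e-4)
})
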