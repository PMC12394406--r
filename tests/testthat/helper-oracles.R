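# Shared fixtures and independent oracles, all built in code.

# wrap a hand-made time series in the trajectory container
make_trajectory <- function(times, cyc, cdk1a = cyc,
                            params = two_ode_params()) {
  structure(list(times = times,
                 state = cbind(cyc = cyc, cdk1a = cdk1a),
                 params = params, temperature = NA_real_,
                 model = "synthetic", solver = list()),
            class = "cc_trajectory")
}

# brute-force fixed-step RK4 integrator (oracle for the stiff solver)
rk4_integrate <- function(rhs, y0, t0, t1, dt, params) {
  n <- ceiling((t1 - t0) / dt)
  y <- y0
  t <- t0
  for (i in seq_len(n)) {
    h <- min(dt, t1 - t)
    k1 <- rhs(t, y, params)
    k2 <- rhs(t + h / 2, y + h / 2 * k1, params)
    k3 <- rhs(t + h / 2, y + h / 2 * k2, params)
    k4 <- rhs(t + h, y + h * k3, params)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

# autocorrelation-based period estimate (oracle for cycle annotation)
acf_period <- function(x, dt) {
  ac <- stats::acf(x, lag.max = length(x) - 2, plot = FALSE)$acf[, 1, 1]
  # first local max after the initial decay
  i <- 2
  while (i < length(ac) && ac[i + 1] <= ac[i]) i <- i + 1
  while (i < length(ac) && ac[i + 1] >= ac[i]) i <- i + 1
  (i - 1) * dt
}

# sawtooth FRET-like trace: linear rise over `rise` min, fall over `fall`
sawtooth_trace <- function(rise = 25, fall = 5, n_cycles = 6, dt = 0.5,
                           baseline = 1, amp = 0.5, id = "saw",
                           radius = 50, temp = 25) {
  period <- rise + fall
  tt <- seq(0, n_cycles * period, by = dt)
  ph <- tt %% period
  y <- ifelse(ph <= rise, ph / rise, 1 - (ph - rise) / fall)
  fret_trace(id, tt, baseline + amp * y, radius, temp)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / abs(expected)), tol)
}
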