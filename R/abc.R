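#' Uniform prior specification for ABC
#'
#' Independent uniform priors, one per inferred parameter.
#'
#' @param lower,upper Named numeric vectors of bounds (same names, all
#'   finite, `lower < upper`).
#' @return An object of class `"prior_spec"`.
#' @export
prior_spec <- function(lower, upper) {
  stopifnot(identical(names(lower), names(upper)))
  if (is.null(names(lower))) stop("bounds must be named")
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("bounds must be finite")
  if (any(lower >= upper)) stop("need lower < upper for every parameter")
  structure(list(lower = lower, upper = upper, names = names(lower)),
            class = "prior_spec")
}

prior_sample <- function(prior, n) {
  d <- length(prior$lower)
  m <- matrix(stats::runif(n * d, rep(prior$lower, each = n),
                           rep(prior$upper, each = n)), nrow = n)
  colnames(m) <- prior$names
  m
}

prior_contains <- function(prior, theta) {
  all(theta >= prior$lower & theta <= prior$upper)
}

#' Distance between simulated and observed phase-duration tables
#'
#' Mean squared difference of log durations over the temperatures and
#' phase components shared by the two tables. A simulation that fails to
#' oscillate (`NA` duration) at a temperature where an oscillation was
#' observed contributes a fixed penalty instead of a squared log
#' difference.
#'
#' @param simulated,observed data.frames with columns `temperature_C`,
#'   `phase` (`"rising"`, `"falling"`, `"total"`) and `duration_min`
#'   (`NA` = non-oscillating).
#' @param penalty Penalty per non-oscillating simulated entry.
#' @return Non-negative scalar distance.
#' @export
duration_distance <- function(simulated, observed, penalty = 10) {
  m <- merge(observed, simulated, by = c("temperature_C", "phase"),
             suffixes = c("_obs", "_sim"))
  m <- m[is.finite(m$duration_min_obs), ]
  if (!nrow(m)) stop("no shared (temperature, phase) support")
  sq <- ifelse(is.finite(m$duration_min_sim),
               (log(m$duration_min_obs) - log(m$duration_min_sim))^2,
               penalty)
  mean(sq)
}

#' Phase-duration forward model for a thermal oscillator
#'
#' Builds the simulator used inside ABC: given a parameter vector of
#' activation energies (and optionally double-exponential branch
#' energies), it constructs a [thermal_model()] around `base`, runs a
#' temperature-response curve on `T_grid`, and returns the tidy
#' phase-duration table that [duration_distance()] consumes.
#'
#' Two parameterizations are available:
#' * `mode = "se"`: pure Arrhenius scaling of synthesis and degradation;
#'   parameters `Ea_ks`, `Ea_kd` (kJ/mol).
#' * `mode = "de"`: synthesis and timescale separation follow U-shaped
#'   (duration-space) double exponentials while degradation stays
#'   Arrhenius, matching the finding that degradation is well described
#'   by a single exponential while synthesis and the switch timescale
#'   need a double exponential; parameters `ks_Ea1`, `ks_Ea2`, `Ea_kd`,
#'   `eps_Ea1`, `eps_Ea2` (branch-2 weight fixed at `weight2`).
#'
#' @param base A [two_ode_params()] (reference-temperature values).
#' @param T_grid Temperatures at which durations are simulated.
#' @param mode `"se"` or `"de"`.
#' @param fixed_laws Additional fixed scaling laws (e.g. for `ka`, `ki`)
#'   merged into every evaluated model.
#' @param ref_T Reference temperature, degrees Celsius.
#' @param weight2 DE branch-2 weight at `ref_T` (mode `"de"`).
#' @param t_end,dt Simulation length and sampling interval.
#' @return Function `theta -> data.frame(temperature_C, phase,
#'   duration_min)`.
#' @export
thermal_forward_model <- function(base, T_grid, mode = c("se", "de"),
                                  fixed_laws = list(), ref_T = 20,
                                  weight2 = 0.05, t_end = 400, dt = 0.2) {
  mode <- match.arg(mode)
  force(base); force(T_grid); force(fixed_laws)
  function(theta) {
    laws <- switch(mode,
      se = list(
        ks = rate_law("SE", "rate", Ea = theta[["Ea_ks"]],
                      ref_T = ref_T, ref_value = 1),
        kd = rate_law("SE", "rate", Ea = theta[["Ea_kd"]],
                      ref_T = ref_T, ref_value = 1)),
      de = list(
        ks = de_duration_law(theta[["ks_Ea1"]], theta[["ks_Ea2"]],
                             weight2 = weight2, ref_T = ref_T),
        kd = rate_law("SE", "rate", Ea = theta[["Ea_kd"]],
                      ref_T = ref_T, ref_value = 1),
        eps = de_duration_law(theta[["eps_Ea1"]], theta[["eps_Ea2"]],
                              weight2 = weight2, ref_T = ref_T)))
    tm <- thermal_model(base, laws = c(laws, fixed_laws), ref_T = ref_T)
    resp <- temperature_response_curve(tm, T_grid, t_end = t_end, dt = dt)
    response_to_durations(resp)
  }
}

#' Tidy phase-duration table from a temperature response
#'
#' @param resp A `"temp_response"`.
#' @return data.frame (`temperature_C`, `phase`, `duration_min`) with
#'   rising, falling and total rows per temperature (`NA` duration when
#'   not oscillating).
#' @export
response_to_durations <- function(resp) {
  data.frame(
    temperature_C = rep(resp$temperature_C, 3),
    phase = rep(c("rising", "falling", "total"),
                each = nrow(resp)),
    duration_min = c(resp$rising, resp$falling, resp$period))
}

#' Sequential Monte Carlo approximate Bayesian computation
#'
#' Standard SMC-ABC with an adaptive Gaussian perturbation kernel:
#' generation 0 is drawn from the prior and fully accepted; each later
#' generation resamples particles by weight, perturbs them with a
#' multivariate normal kernel whose covariance is twice the weighted
#' particle covariance, and accepts proposals whose distance falls below
#' the next epsilon - the stated quantile of the current generation's
#' distances, so epsilons decrease strictly. Importance weights use the
#' standard prior-over-kernel-mixture correction. Rather than a single
#' best fit, the result is a weighted population of well-fitting
#' parameter sets.
#'
#' @param forward Function mapping a named parameter vector to a
#'   simulated dataset.
#' @param prior A [prior_spec()].
#' @param observed Observed dataset, passed to `distance`.
#' @param distance Function `(simulated, observed) -> scalar`; defaults
#'   to [duration_distance()].
#' @param n_particles Particles per generation.
#' @param n_generations Number of generations (including generation 0).
#' @param quantile_level Epsilon quantile (default 0.5).
#' @param seed Integer seed; runs are fully reproducible.
#' @param max_oversample Early-stop guard: a generation aborts after
#'   `max_oversample * n_particles` proposals, returning the partial
#'   population with status `"stalled"`.
#' @return An object of class `"abc_posterior"`: list with `particles`
#'   (matrix), `weights`, `distances`, `epsilons`, `generation`, `ess`,
#'   `status`, `seed`, `n_simulations`.
#' @export
smc_abc <- function(forward, prior, observed,
                    distance = duration_distance,
                    n_particles = 256, n_generations = 6,
                    quantile_level = 0.5, seed = 1,
                    max_oversample = 50) {
  set.seed(seed)
  d <- length(prior$lower)
  theta <- prior_sample(prior, n_particles)
  dist0 <- apply(theta, 1, function(th) distance(forward(th), observed))
  w <- rep(1 / n_particles, n_particles)
  eps_hist <- numeric(0)
  n_sim <- n_particles
  status <- "converged"
  gen <- 0L
  eps <- unname(stats::quantile(dist0, quantile_level))
  for (g in seq_len(n_generations - 1)) {
    eps_hist <- c(eps_hist, eps)
    Sigma <- 2 * stats::cov.wt(theta, wt = w)$cov
    # regularize a degenerate kernel
    Sigma <- Sigma + diag(1e-12 * pmax(diag(Sigma), 1e-12), d)
    new_theta <- matrix(NA_real_, n_particles, d,
                        dimnames = list(NULL, prior$names))
    new_dist <- numeric(n_particles)
    accepted <- 0L
    attempts <- 0L
    while (accepted < n_particles) {
      attempts <- attempts + 1L
      if (attempts > max_oversample * n_particles) {
        status <- "stalled"
        break
      }
      j <- sample.int(n_particles, 1, prob = w)
      prop <- MASS::mvrnorm(1, theta[j, ], Sigma)
      if (!prior_contains(prior, prop)) next
      n_sim <- n_sim + 1L
      di <- distance(forward(prop), observed)
      if (di <= eps) {
        accepted <- accepted + 1L
        new_theta[accepted, ] <- prop
        new_dist[accepted] <- di
      }
    }
    if (status == "stalled") {
      if (accepted == 0L) break
      new_theta <- new_theta[seq_len(accepted), , drop = FALSE]
      new_dist <- new_dist[seq_len(accepted)]
    }
    # importance weights: uniform prior density cancels to a constant
    kdens <- vapply(seq_len(nrow(new_theta)), function(i) {
      dev <- sweep(theta, 2, new_theta[i, ])
      sum(w * mvn_density(dev, Sigma))
    }, numeric(1))
    new_w <- 1 / kdens
    new_w <- new_w / sum(new_w)
    theta <- new_theta
    dist0 <- new_dist
    w <- new_w
    gen <- g
    if (status == "stalled") break
    eps_new <- unname(stats::quantile(dist0, quantile_level))
    eps <- min(eps_new, eps * (1 - 1e-9))
  }
  structure(list(particles = theta, weights = w, distances = dist0,
                 epsilons = eps_hist, generation = gen,
                 ess = 1 / sum(w^2), status = status, seed = seed,
                 n_simulations = n_sim),
            class = "abc_posterior")
}

# multivariate normal density at rows of a deviation matrix
mvn_density <- function(dev, Sigma) {
  L <- chol(Sigma)
  z <- forwardsolve(t(L), t(dev))
  q <- colSums(z^2)
  exp(-0.5 * q) / ((2 * pi)^(ncol(dev) / 2) * prod(diag(L)))
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat(sprintf("<abc_posterior> %d particles after %d perturbation generation(s), status %s\n",
              nrow(x$particles), x$generation, x$status))
  cat(sprintf("  ESS %.1f, %d forward simulations, epsilons: %s\n",
              x$ess, x$n_simulations,
              paste(signif(x$epsilons, 3), collapse = " > ")))
  invisible(x)
}

#' Weighted posterior summaries
#'
#' Weighted mean, standard deviation, credible interval and
#' kernel-density mode (weighted Gaussian KDE, Silverman bandwidth) per
#' parameter.
#'
#' @param pop An `"abc_posterior"`.
#' @param cred_mass Credible-interval mass (default 0.95).
#' @return data.frame with one row per parameter: `mean`, `sd`, `mode`,
#'   `ci_lo`, `ci_hi`.
#' @export
posterior_summary <- function(pop, cred_mass = 0.95) {
  stopifnot(inherits(pop, "abc_posterior"))
  if (!nrow(pop$particles)) stop("empty posterior population")
  w <- pop$weights / sum(pop$weights)
  a <- (1 - cred_mass) / 2
  rows <- lapply(colnames(pop$particles), function(nm) {
    x <- pop$particles[, nm]
    mu <- sum(w * x)
    sdv <- sqrt(max(sum(w * (x - mu)^2), 0))
    if (length(unique(x)) == 1) {
      md <- x[1]
    } else {
      # Silverman bandwidth from weighted moments (effective sample size)
      n_eff <- 1 / sum(w^2)
      qs <- weighted_quantile(x, w, c(0.25, 0.75))
      spread <- min(sdv, (qs[2] - qs[1]) / 1.349)
      bw <- max(0.9 * spread * n_eff^(-1 / 5), 1e-8)
      dens <- stats::density(x, weights = w, bw = bw)
      md <- dens$x[which.max(dens$y)]
    }
    qs <- weighted_quantile(x, w, c(a, 1 - a))
    data.frame(parameter = nm, mean = mu, sd = sdv, mode = md,
               ci_lo = qs[1], ci_hi = qs[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}
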