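---
title: "Temperature scaling of the embryonic cell-cycle oscillator: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temperature scaling of the embryonic cell-cycle oscillator: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermocycle)
```

## The scientific problem

Early embryonic cell cycles in ectotherms are driven by a biochemical
oscillator built around the cyclin B–Cdk1 kinase. Like most
physiological rates, the cycle speeds up with temperature roughly
following the Arrhenius equation, `k(T) = A exp(-Ea/RT)`, with apparent
activation energies around 70–90 kJ/mol (a Q10 near 2.8 at 20 °C) — yet
the cycle also fails abruptly at both cold and hot extremes, and its
Arrhenius plot (ln duration vs `1/T`) is bowed rather than straight.
This package implements the modelling and analysis machinery needed to
study why: temperature-scaling laws and their fitting, ODE oscillator
models whose individual rate constants scale differently with
temperature, likelihood-free inference of those scalings from
phase-duration data, and the time-series analysis used on Cdk1-FRET
droplet recordings. Everything is exercisable on synthetic data, so the
full pipeline is testable without any external downloads.

## Scaling laws

Four functional forms are supported (`rate_law()`), each usable in
*rate* or *duration* orientation:

| kind | duration form | free parameters |
|------|--------------------------------------------|-----|
| SE | `A exp(+Ea/RT)` | 2 |
| DE | `A1 exp(+Ea1/RT) + A2 exp(+Ea2/RT)` | 4 |
| QE | `A exp((Ea/R)(1/T + B/T^2))` | 3 |
| PE | `A T^B exp(+Ea/RT)` | 3 |

A single sign convention is used throughout: in duration orientation the
exponent carries `+Ea/RT`, in rate orientation `-Ea/RT`, so that a
positive activation energy always means "faster when warmer". This
makes the DE/QE/PE forms nest the SE form exactly (`A2 -> 0`, `B -> 0`),
which in turn guarantees that the more flexible fits can never score a
worse mean squared log-error than the Arrhenius fit. DE activation
energies are deliberately unconstrained in sign: a duration-space DE
with `Ea1 > 0 > Ea2` is U-shaped, and its reciprocal is a biphasic rate
with a thermal optimum — the shape used for heat-labile cyclin
synthesis.

Q10 values are always computed on rates (duration laws are
reciprocated) as the forward-interval ratio
`(rate(T+10)/rate(T))`. A derivative-based "local" variant
(`q10_interval(..., method = "derivative")`) is exposed as an option;
the interval definition is the package's default because it is the one
that corresponds directly to the printed 10-degree convention.

Internally all temperatures are Kelvin; every public interface takes
degrees Celsius, because the field mixes both and silent unit mistakes
are the dominant failure mode. Model rates use the anchored
parameterization `k(T) = k_ref exp(-Ea/R (1/T - 1/T_ref))`
(`T_ref = 20` °C by default), which decorrelates the pre-exponential
factor from `Ea` during fitting and ABC.

## The two-ODE relaxation oscillator

`simulate_two_ode()` integrates

```
 d cyc/dt   = ks - kd * d(cdk1a) * cyc
 eps * d cdk1a/dt = ka * a(cdk1a) * (cyc - cdk1a) - ki * i(cdk1a) * cdk1a
```

where `d`, `a`, `i` are Hill responses standing in for APC/C, Cdc25 and
Wee1 after the fast phosphorylation reactions are assumed instantaneous.
With a small timescale-separation factor `eps`, the system is a
relaxation oscillator: cyclin accumulates slowly along the low-Cdk1
branch of the S-shaped Cdk1 nullcline, jumps to the high-activity
branch, and is reset by degradation — sawtooth cyclin oscillations with
a long rising (interphase) and short falling (mitotic-exit) phase.

The default parameterization is the package's own calibration, chosen
once so that the reference model oscillates with a realistic period of
about 30 minutes at 20 °C with interphase occupying most of the cycle:
`ks = 1.1` nM/min, `kd = 0.2` /min, `ka = ki = 1` /min, `eps = 0.05`,
and Hill responses `d`: (basal 0.01, max 1, ec50 32 nM, n 15),
`a`: (0.16, 0.8, 35 nM, 11), `i` (decreasing): (0.08, 0.4, 30 nM, 5).
Hill coefficients lie in the 5–15 range typical of the strongly
ultrasensitive mitotic switches, and the ec50s sit mid-range of the
cyclin amplitude. An exact property of this structure worth knowing:
multiplying `ks, kd, ka, ki` by a common factor `c` (holding `eps` and
the Hill responses fixed) rescales time by `1/c` exactly, so equal
Arrhenius scaling of all four rates yields an exactly Arrhenius period.

## The five-ODE mass-action model

To check that conclusions are not artifacts of the Hill nonlinearities,
`simulate_five_ode()` provides a structurally different oscillator with
strictly mass-action kinetics: Cdk1 activity (proportional to cyclin;
no Wee1/Cdc25 loop) activates Greatwall; Greatwall phosphorylates ENSA;
phospho-ENSA sequesters PP2A in a tight complex that is only slowly
resolved by catalytic dephosphorylation ("unfair competition"); and
free PP2A opposes both Greatwall and APC/C activation. The switch
memory lives in the phospho-ENSA pool: after Cdk1 activity collapses,
PP2A stays sequestered until the pool drains at the catalytic rate,
which is what makes the oscillation relaxation-like. A pseudo-first-order
basal Greatwall dephosphorylation (`kb`, absorbing phosphatases other
than PP2A-B55) lets Greatwall shut off even while PP2A is fully
sequestered; without it the switch can lock on permanently. The ten
kinetic constants and four totals default to the package's own
calibration producing sustained ~30-minute oscillations; the test suite
cross-checks the reduced model against the fully expanded
(conservation-free) mass-action system.

## Thermal models, response curves and arrest states

`thermal_model()` maps parameter names to scaling laws; every mapped
parameter is scaled multiplicatively relative to the law's value at the
reference temperature, so the base parameter set is recovered exactly
at `T_ref` however the law is normalized. Rate-like parameters follow
the law's rate equivalent; `eps` is time-like and scales inversely.

`temperature_response_curve()` runs one simulation plus period
detection per grid point. Period detection follows the last-two-peaks
rule: peaks of the cyclin variable are located by local maxima with a
minimum prominence of 10% of the observed amplitude and a minimum
separation of 2 min (defaults; both config-exposed), a 100-min initial
transient is discarded on long runs, the period is the spacing of the
last two peaks, and the oscillation counts as sustained only when those
two peak heights agree within 5% (relative; config-exposed) — otherwise
the run is classified as damped. Non-oscillating parameter sets are
classified by `classify_arrest()` into interphase-like (`low_cdk1`) or
M-phase-like (`high_cdk1`) steady states by comparing the steady
active-Cdk1 level (long integration plus Newton refinement) with the
activation response's ec50.

The viable temperature range is the maximal contiguous run of
oscillating grid points containing the reference temperature, with
endpoints at midpoints between the last oscillating and first
non-oscillating grid point; ranges touching the grid edge are flagged
censored. The default scenario grids use 1–2 °C spacing to keep a full
scenario run in seconds; the 0.25 °C default mentioned for
production-quality endpoint localization is available by passing a
finer grid.

Four canonical scenarios (`run_case_scenarios()`) map enzyme-level
scaling onto system behaviour: equal activation energies (Case 1,
exactly Arrhenius period), pairwise-equal energies with strong
timescale separation (Case 2, period inherits the synthesis/degradation
energy; the scenario uses `eps = 0.005` because the Case-2 equivalence
is an `eps -> 0` statement), an `Ea(ks)` vs `Ea(kd)` imbalance (Case 3,
30 vs 120 kJ/mol, which bows the Arrhenius plot concave-up and creates
finite thermal limits inside 0–45 °C with low-Cdk1 arrest beyond the
hot limit, or high-Cdk1 when the imbalance is reversed), and a biphasic
synthesis rate (Case 4, DE branches 80 and −150 kJ/mol with a 5%
hot branch at 20 °C, giving an interior period minimum near 27 °C and a
high-temperature limit). The Case-3/4 energies are the package's own
choices, fixed once so the qualitative regimes all appear within the
physically meaningful 0–45 °C window; `eps` is held
temperature-independent in the scenarios, while the ABC `"de"` mode
scales it.

## Fitting scaling laws to duration data

`fit_scaling_law()` implements the standard recipe: durations are
binned per integer °C and the per-bin median taken (`bin_median()`,
idempotent); fits operate on the binned log-durations only. SE/QE/PE
are ordinary least squares in log space; DE uses the two-step
initialization — an SE fit on a designated Arrhenius sub-interval
(default: the coldest half of the occupied bins, where the curves are
most Arrhenius-like), then an SE fit on the positive residual
differences elsewhere (negative differences floored at
`1e-6 * median(duration)`; the floor only seeds the optimizer) —
followed by a full Levenberg–Marquardt refinement of all four
parameters on log-durations, started both from the two-step solution
and from an SE-degenerate point so the refined DE can never do worse
than the SE fit. Goodness of fit is the mean squared error on
log-durations (`mse_log()`). A per-dataset `exclude_bins` argument
reproduces documented outlier exclusions without hard-coding any
species logic. For DE fits the headline activation energy is the branch
dominant at the coldest fitted temperature.

`bootstrap_activation_energy()` resamples observations with replacement
within each integer bin, re-bins, refits, and summarizes the fitted
energies with the sample mean and the percentile 90% interval
(default 1000 replicates; fully seed-reproducible). The resampling unit
is the individual observation (embryo or droplet cycle) because that is
the replicate structure of the data; residual resampling is not
offered. One property to be aware of: with ~10 observations per bin the
bootstrap dispersion of a bin median overestimates its sampling
dispersion — a known small-sample property of bootstrapping medians —
so the nominal 90% percentile interval is mildly conservative, with
empirical coverage in the low-to-mid 90s under the synthetic-data
conditions exercised by the test suite and the acceptance script. This
is inherent to the prescribed procedure and is left as-is.

## SMC-ABC inference

`smc_abc()` is a standard sequential Monte Carlo ABC: generation 0 is
drawn from independent uniform priors (defaults: `Ea` in 0–200 kJ/mol);
each later generation resamples by weight, perturbs with a Gaussian
kernel whose covariance is twice the weighted particle covariance,
accepts below the next epsilon (the 0.5 quantile of current distances,
so epsilons decrease strictly), and reweights with the standard
prior-over-kernel-mixture correction. A stall guard (50× oversampling)
returns a partial population with an explicit status instead of
spinning. The default budget of 256 particles × 6 generations is a
desk-scale choice that recovers two activation energies from noise-free
phase-duration data within the tolerances exercised by the test suite;
all sizes are arguments.

The distance (`duration_distance()`) is the equal-weight mean squared
difference of log durations over the shared (temperature, phase)
support, with a fixed penalty (default 10) per temperature where the
simulation fails to oscillate but an oscillation was observed. The
equal weighting and penalty value are package choices; they are
config-exposed.

The forward model (`thermal_forward_model()`) simulates the two-ODE
oscillator across the observation temperatures and extracts rising and
falling phase durations from the last complete cycle. Its `"se"` mode
infers pure Arrhenius energies for synthesis and degradation; its
`"de"` mode gives synthesis and the timescale separation U-shaped
duration-space DE laws (hot-branch weight fixed at 5% at 20 °C) while
degradation stays single-exponential, matching the finding that
degradation needs only one exponential while synthesis and the switch
timescale need two. Forward simulations use 400 min at 0.2-min
sampling — long enough for at least four post-transient cycles at the
coldest inference temperatures while keeping a full ABC run within
minutes on one core.

## Droplet FRET analysis

`annotate_cycles()` auto-selects peaks and troughs with prominence at
least 20% of the trace's interquartile range and 5-min minimum
separation (suited to 3–7-min sampling), after a centered 3-sample
running-mean smoothing; alternation is enforced by merging same-kind
neighbours, keeping the more extreme one. The smoothing plus
deterministic merge rules are this package's replacement for the
interactive manual correction step used in image-analysis pipelines;
without smoothing, measurement noise near 2% of the signal amplitude
can dominate prominence on slow-ramp/narrow-spike Cdk1 waveforms,
whose interquartile range is much smaller than their amplitude.
`filter_droplets()` applies the strict quality cuts (radius < 100 μm,
track start < 60 min). Cycle selection supports both the cycles-2-to-4
and the first-300-min conventions so their agreement can be checked on
any dataset. `interphase_slope()` (a cyclin-synthesis proxy) fits an
OLS slope over the central 60% of each rising segment — the trimming
fraction is a package choice, documented rather than inherited.
`average_waveform()` rescales each trough-to-trough cycle to unit phase
and unit amplitude and averages on a 100-point grid; this normalization
is likewise an assumption, stated here. `fit_assay_rate()` uses the
initial-rate convention (OLS slope) for synthesis/kinase/phosphatase
assays and a single-exponential decay after normalization to the
starting intensity for APC/C degradation assays.

## What the synthetic generators emulate — and what they do not

`gen_species_periods()` draws durations as `law(T) * exp(sigma Z)`:
multiplicative lognormal noise, because all fits operate on
log-durations. `gen_droplet_traces()` simulates each droplet's Cdk1
dynamics at its position on a linear temperature gradient, applies a
uniform time dilation `1 + gamma t` to mimic the gradual slowing of
aging extracts (the simplest mechanism consistent with that
observation; a modelling convenience, not a mechanistic claim), maps
activity to a FRET ratio (`baseline + gain * cdk1a`) with additive
Gaussian noise, and draws radii/start times so the quality filter sees
both passing and failing droplets. `gen_assay_panel()` produces linear
(slope = rate law at `T`) or exponential-decay series with Gaussian
noise. Defaults (e.g. 200 droplets, 13 temperature bins, 10 replicates
per bin) are sized so every generator runs in seconds to minutes.

The generators deliberately do not emulate photophysics (bleaching,
crosstalk), droplet coalescence or evaporation, segmentation or
tracking errors, baseline drift beyond the uniform slowdown, or
between-extract biological variability. Consequently, passing tests
demonstrate that the analysis machinery is faithful — that it recovers
known generating parameters under the statistical structure the
analysis assumes — not that real embryos or extracts obey those
assumptions.

## Numerical choices and degenerate inputs

Integration uses `deSolve`'s stiff implicit multistep solver (lsoda,
which switches to a BDF method on stiff stretches) with
`rtol = 1e-8` / `atol = 1e-10` and compiled right-hand sides; one test
cross-checks a stiff instance against fixed-step RK4 at `dt = 1e-4`.
Negative state excursions beyond 1e-6 nM abort with an integrity error;
smaller ones are clipped to zero. Trajectories default to 1000
simulated minutes at 0.1-min sampling; scenario and pipeline code uses
400–1000 min depending on the coldest (slowest) temperature it must
resolve. Degenerate inputs are handled explicitly: empty trajectories,
non-oscillating inputs to phase segmentation, featureless (constant)
traces, single-particle posteriors, unidentifiable DE branches (whose
pre-exponential underflows are floored rather than failed), and
bootstrap refit failures (warn above 10%, error above 50%).

## Known limitations

* No bifurcation continuation: thermal limits are located by grid
  scanning, so endpoint accuracy is grid-resolution bound.
* The five-ODE parameterization is this package's own; it reproduces
  the qualitative architecture (mass-action Greatwall/PP2A switch,
  realistic period), not any published constant set.
* ABC with the `"de"` mode (5 parameters) at the default desk-scale
  budget yields broader posteriors than the `"se"` mode exercised in
  the acceptance suite; production inference should raise the particle
  count.
* The bootstrap interval's mild conservatism (above) is inherent to
  median re-binning at ~10 observations per bin.
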