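#' @useDynLib thermocycle, .registration = TRUE
NULL

#' Universal gas constant (J mol^-1 K^-1)
#'
#' Module-level constant used in all activation-energy computations.
#' @export
GAS_CONSTANT <- 8.314

# Celsius <-> Kelvin. All public interfaces take degrees Celsius; Kelvin is
# the internal unit.
celsius_to_kelvin <- function(temp_c) temp_c + 273.15
kelvin_to_celsius <- function(temp_k) temp_k - 273.15

#' Temperature-scaling laws for rates and durations
#'
#' Constructs a tagged temperature-scaling law mapping absolute temperature
#' to a positive rate or duration. Four functional forms are supported:
#'
#' * `"SE"` (single exponential, Arrhenius): rate `k(T) = A exp(-Ea/(R T))`,
#'   duration `dt(T) = A exp(+Ea/(R T))` (the rearranged Arrhenius form).
#' * `"DE"` (double exponential): the sum of two SE components with
#'   independent `(A1, Ea1)` and `(A2, Ea2)`. Activation energies are
#'   unconstrained in sign so a duration-space DE can be U-shaped, with one
#'   branch dominating at each temperature extreme.
#' * `"QE"` (quadratic exponential): exponent `(Ea/R) (1/T + B/T^2)`
#'   (sign as for SE per orientation); `B` has units of Kelvin.
#' * `"PE"` (power-law exponential): `A T^B` times the SE exponential.
#'
#' The `orientation` flag records whether the law describes a rate
#' (increasing with temperature for `Ea > 0`) or a duration (decreasing).
#' Q10 computations always operate on rates, taking the reciprocal of
#' duration laws.
#'
#' A law may alternatively be anchored at a reference temperature:
#' `k(T) = ref_value * exp(-Ea/R (1/T - 1/ref_T))` for SE (and analogously
#' for QE/PE). This decorrelates the pre-exponential factor from `Ea`
#' and guarantees that evaluation at `ref_T` returns `ref_value` exactly.
#'
#' @param kind One of `"SE"`, `"DE"`, `"QE"`, `"PE"`.
#' @param orientation `"rate"` or `"duration"`.
#' @param A,Ea Pre-exponential factor (`A > 0`) and activation energy
#'   (kJ/mol) for SE/QE/PE laws.
#' @param A1,Ea1,A2,Ea2 The two components of a DE law (`A1, A2 > 0`;
#'   `Ea1`, `Ea2` in kJ/mol, sign unconstrained).
#' @param B QE curvature parameter (K) or PE power-law exponent
#'   (dimensionless).
#' @param ref_T Optional reference temperature in degrees Celsius; when
#'   given together with `ref_value` the law is parameterized as
#'   value-at-reference and `A` must be omitted.
#' @param ref_value Value of the law at `ref_T`.
#' @return An object of class `"rate_law"`.
#' @examples
#' arr <- rate_law("SE", "rate", Ea = 75, ref_T = 20, ref_value = 1)
#' evaluate_law(arr, 30) / evaluate_law(arr, 20) # ~2.76, the Q10 at 20 C
#' @export
rate_law <- function(kind = c("SE", "DE", "QE", "PE"),
                     orientation = c("rate", "duration"),
                     A = NULL, Ea = NULL,
                     A1 = NULL, Ea1 = NULL, A2 = NULL, Ea2 = NULL,
                     B = NULL, ref_T = NULL, ref_value = NULL) {
  kind <- match.arg(kind)
  orientation <- match.arg(orientation)
  law <- structure(list(kind = kind, orientation = orientation),
                   class = "rate_law")
  if (!is.null(ref_T)) {
    if (is.null(ref_value) || !is.finite(ref_value) || ref_value <= 0)
      stop("'ref_value' must be a positive number when 'ref_T' is given")
    if (!is.null(A) || !is.null(A1))
      stop("give either 'A' (or 'A1'/'A2') or a reference parameterization, not both")
    law$ref_T <- celsius_to_kelvin(ref_T)
    law$ref_value <- ref_value
  }
  if (kind == "DE") {
    if (is.null(A1) || is.null(Ea1) || is.null(A2) || is.null(Ea2))
      stop("DE laws need A1, Ea1, A2, Ea2")
    if (A1 <= 0 || A2 <= 0) stop("DE laws require A1 > 0 and A2 > 0")
    law[c("A1", "Ea1", "A2", "Ea2")] <- list(A1, Ea1, A2, Ea2)
  } else {
    if (is.null(Ea)) stop(kind, " laws need Ea")
    if (is.null(law$ref_T)) {
      if (is.null(A)) stop(kind, " laws need A (or ref_T/ref_value)")
      if (A <= 0) stop("A must be > 0")
      law$A <- A
    }
    law$Ea <- Ea
    if (kind %in% c("QE", "PE")) {
      if (is.null(B)) stop(kind, " laws need B")
      law$B <- B
    }
  }
  law
}

# Sign of the exponential argument: rates speed up with temperature for
# Ea > 0 (exponent -Ea/RT), durations shorten (exponent +Ea/RT).
law_sign <- function(law) if (law$orientation == "rate") -1 else 1

# Exponent structure per kind, on the 1/T scale (Ea in J/mol internally).
law_exponent <- function(law, temp_k, Ea, B = NULL) {
  x <- 1 / temp_k
  if (law$kind == "QE") x <- x + B / temp_k^2
  law_sign(law) * (Ea * 1000 / GAS_CONSTANT) * x
}

law_value_kelvin <- function(law, temp_k) {
  if (any(!is.finite(temp_k)) || any(temp_k <= 0))
    stop("temperature must be finite and above 0 K")
  if (law$kind == "DE") {
    se1 <- structure(list(kind = "SE", orientation = law$orientation),
                     class = "rate_law")
    v <- law$A1 * exp(law_exponent(se1, temp_k, law$Ea1)) +
      law$A2 * exp(law_exponent(se1, temp_k, law$Ea2))
    return(v)
  }
  expo <- law_exponent(law, temp_k, law$Ea, law$B)
  if (!is.null(law$ref_T)) {
    ref_expo <- law_exponent(law, law$ref_T, law$Ea, law$B)
    pe_fac <- if (law$kind == "PE") (temp_k / law$ref_T)^law$B else 1
    ifelse(temp_k == law$ref_T, law$ref_value,
           law$ref_value * pe_fac * exp(expo - ref_expo))
  } else {
    pe_fac <- if (law$kind == "PE") temp_k^law$B else 1
    law$A * pe_fac * exp(expo)
  }
}

#' Evaluate a temperature-scaling law
#'
#' @param law A [rate_law()].
#' @param temp_c Temperature(s) in degrees Celsius.
#' @return The law's value (rate or duration, per its orientation); always
#'   strictly positive.
#' @export
evaluate_law <- function(law, temp_c) {
  stopifnot(inherits(law, "rate_law"))
  law_value_kelvin(law, celsius_to_kelvin(temp_c))
}

# Evaluate as a *rate*, reciprocating duration-orientation laws.
law_rate <- function(law, temp_c) {
  v <- evaluate_law(law, temp_c)
  if (law$orientation == "duration") 1 / v else v
}

#' @export
print.rate_law <- function(x, ...) {
  pars <- x[setdiff(names(x), c("kind", "orientation"))]
  cat(sprintf("<rate_law> %s (%s)\n", x$kind, x$orientation))
  if (!is.null(x$ref_T))
    cat(sprintf("  anchored: value %.4g at %.2f C\n", x$ref_value,
                kelvin_to_celsius(x$ref_T)))
  nm <- intersect(c("A", "Ea", "A1", "Ea1", "A2", "Ea2", "B"), names(pars))
  for (p in nm) cat(sprintf("  %s = %.6g\n", p, x[[p]]))
  invisible(x)
}

#' Forward-interval Q10 of a scaling law
#'
#' Computes `(rate(T + width) / rate(T))^(10 / width)`; with the default
#' `width = 10` this is the plain forward 10-degree-interval Q10. Duration
#' laws are reciprocated first so that Q10 always describes a rate. A
#' derivative-based local variant (`method = "derivative"`,
#' `exp(10 * d ln rate / dT)`) is also available.
#'
#' @param law A [rate_law()].
#' @param temp_c Temperature(s), degrees Celsius.
#' @param width Interval width in Kelvin (must be positive).
#' @param method `"interval"` (default) or `"derivative"`.
#' @return Q10 value(s).
#' @export
q10_interval <- function(law, temp_c, width = 10,
                         method = c("interval", "derivative")) {
  method <- match.arg(method)
  if (!is.finite(width) || width <= 0) stop("'width' must be positive")
  if (method == "interval") {
    (law_rate(law, temp_c + width) / law_rate(law, temp_c))^(10 / width)
  } else {
    h <- 1e-4
    dlnr <- (log(law_rate(law, temp_c + h)) - log(law_rate(law, temp_c - h))) / (2 * h)
    exp(10 * dlnr)
  }
}

#' Convert between activation energy and Q10
#'
#' Closed-form interconversion for a single-exponential (Arrhenius) rate
#' law over a forward 10-degree interval:
#' `Q10 = exp(Ea/R (1/T - 1/(T+10)))` at absolute temperature `T`.
#'
#' @param ea Activation energy, kJ/mol.
#' @param q10 Q10 value (> 0).
#' @param temp_c Temperature at the start of the 10-degree interval (C).
#' @return The converted quantity.
#' @examples
#' ea_to_q10(75, 20) # ~2.76, rounds to 2.8
#' @export
ea_to_q10 <- function(ea, temp_c) {
  tk <- celsius_to_kelvin(temp_c)
  exp(ea * 1000 / GAS_CONSTANT * (1 / tk - 1 / (tk + 10)))
}

#' @rdname ea_to_q10
#' @export
q10_to_ea <- function(q10, temp_c) {
  if (any(!is.finite(q10)) || any(q10 <= 0)) stop("'q10' must be positive")
  tk <- celsius_to_kelvin(temp_c)
  log(q10) * GAS_CONSTANT / (1 / tk - 1 / (tk + 10)) / 1000
}

#' Anchored double-exponential duration law
#'
#' Convenience constructor for a U-shaped duration-space DE law expressed
#' by the activation energies of its two branches and the fractional
#' contribution of the second branch at a reference temperature. With
#' `Ea1 > 0` the first branch dominates at cold temperatures (durations
#' shorten as it warms); with `Ea2 < 0` the second branch grows at hot
#' temperatures, producing a duration minimum. The reciprocal of such a
#' law is a biphasic rate with a thermal optimum.
#'
#' @param Ea1,Ea2 Branch activation energies, kJ/mol.
#' @param weight2 Fraction of the total duration contributed by the
#'   second branch at `ref_T` (0 < weight2 < 1).
#' @param ref_T Reference temperature, degrees Celsius.
#' @param ref_value Total duration at `ref_T` (sets the absolute scale).
#' @return A `"rate_law"` of kind `"DE"`, orientation `"duration"`.
#' @examples
#' ks_law <- de_duration_law(80, -150, weight2 = 0.05)
#' # biphasic rate: rises, peaks near 27-28 C, then falls
#' plot(seq(10, 40, 0.5), 1 / evaluate_law(ks_law, seq(10, 40, 0.5)), type = "l")
#' @export
de_duration_law <- function(Ea1, Ea2, weight2 = 0.05, ref_T = 20,
                            ref_value = 1) {
  if (weight2 <= 0 || weight2 >= 1) stop("weight2 must be in (0, 1)")
  tk <- celsius_to_kelvin(ref_T)
  A1 <- (1 - weight2) * ref_value * exp(-Ea1 * 1000 / (GAS_CONSTANT * tk))
  A2 <- weight2 * ref_value * exp(-Ea2 * 1000 / (GAS_CONSTANT * tk))
  rate_law("DE", "duration", A1 = A1, Ea1 = Ea1, A2 = A2, Ea2 = Ea2)
}

#' Serialize / deserialize a scaling law
#'
#' Laws flatten to a plain named list `{kind, orientation, parameters,
#' ref_T (C), ref_value}` suitable for structured config files, and can be
#' rebuilt from such a record.
#'
#' @param law A [rate_law()].
#' @param record A list as produced by `law_to_record()`.
#' @return `law_to_record()`: a named list; `law_from_record()`: a
#'   [rate_law()].
#' @export
law_to_record <- function(law) {
  stopifnot(inherits(law, "rate_law"))
  rec <- unclass(law)
  if (!is.null(rec$ref_T)) rec$ref_T <- kelvin_to_celsius(rec$ref_T)
  rec
}

#' @rdname law_to_record
#' @export
law_from_record <- function(record) {
  do.call(rate_law, record)
}
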