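#' One hourly step of Dynamic Model chill kinetics
#'
#' Advances the precursor/chill state by one hour at temperature
#' `temp_K`. The precursor relaxes toward its temperature-dependent
#' steady state `xs = (A0/A1) * exp((E1 - E0)/T)` at rate
#' `k1 = A1 * exp(-E1/T)`; if the updated precursor level reaches 1, a
#' fraction `xi = s/(1+s)` with `s = exp(slope * TfK * (T - TfK)/T)` is
#' converted to permanent chill and removed from the precursor pool.
#'
#' @param state List with elements `x` (precursor level) and `y`
#'   (accumulated chill).
#' @param temp_K Temperature in Kelvin.
#' @param params A [chill_params()] object.
#' @return Updated state list.
#' @export
chill_step <- function(state, temp_K, params) {
  stopifnot(inherits(params, "chill_params"))
  if (!is.finite(temp_K) || temp_K <= 0)
    stop("temperature must be finite and positive (Kelvin)")
  xs <- (params$A0 / params$A1) * exp((params$E1 - params$E0) / temp_K)
  k1 <- params$A1 * exp(-params$E1 / temp_K)
  xt <- xs - (xs - state$x) * exp(-k1)
  if (xt >= 1) {
    xi <- conversion_fraction(temp_K, params)
    list(x = xt * (1 - xi), y = state$y + xi * xt)
  } else {
    list(x = xt, y = state$y)
  }
}

#' Precursor-to-chill conversion fraction
#'
#' Logistic in temperature, equal to 0.5 at `Tf` and strictly increasing.
#'
#' @param temp_K Temperature(s) in Kelvin.
#' @param params A [chill_params()] object.
#' @return Conversion fraction(s) in (0, 1).
#' @export
conversion_fraction <- function(temp_K, params) {
  TfK <- params$Tf + .KELVIN
  stats::plogis(params$slope * TfK * (temp_K - TfK) / temp_K)
}

#' Accumulate chill over an hourly temperature series
#'
#' Runs the Dynamic Model recursion from `x = 0, y = 0` over hourly
#' temperatures in degrees Celsius and returns the full chill
#' trajectory.
#'
#' @param hourly Numeric vector of hourly temperatures (degC).
#' @param params A [chill_params()] object.
#' @return Numeric vector of accumulated chill (nondecreasing), one value
#'   per input hour; length 0 for empty input.
#' @export
accumulate_chill <- function(hourly, params) {
  stopifnot(inherits(params, "chill_params"))
  if (length(hourly) == 0) return(numeric(0))
  if (any(!is.finite(hourly))) stop("hourly temperatures must be finite")
  cpp_chill_accumulate(as.numeric(hourly), params$E0, params$E1, params$A0,
                       params$A1, params$Tf, params$slope)
}

# Internal pieces of the intermediate -> canonical mapping. All work in
# Kelvin; DeltaE = E1 - E0.
#
# Given DeltaE, the remaining canonical parameters follow from three
# defining conditions:
#   * E1 from requiring the time-to-first-portion be minimal at
#     theta_star (optimality of the fixed 279 K),
#   * A1 from the timing condition: starting at x = 0 under constant
#     theta_star, x reaches 1 exactly at hour tau,
#   * A0 from the steady-state condition xs(theta_c) = 1 (no chill at or
#     above theta_c).
.canonical_given_deltaE <- function(dE, theta_star, theta_c, tau) {
  u <- exp(-dE * (1 / theta_star - 1 / theta_c))   # 1/xs at theta_star
  if (u >= 1 || u <= 0) return(NULL)
  g <- -log1p(-u)                                   # k1(theta_star) * tau
  E1 <- dE * u / ((1 - u) * g)
  E0 <- E1 - dE
  A1 <- g / tau * exp(E1 / theta_star)
  # one-ulp-down guard so xs(theta_c) <= 1 holds under floating point
  A0 <- A1 * exp(-dE / theta_c) * (1 - 1e-12)
  list(E0 = E0, E1 = E1, A0 = A0, A1 = A1, u = u)
}

# Peak precursor level in the periodic steady state of a square-wave
# temperature cycle (cold_hours at theta_star, warm_hours at theta_w),
# continuous-time solution of the same kinetics.
.cycle_peak <- function(cn, dE, theta_star, theta_c, theta_w, cold_hours,
                        warm_hours) {
  k1c <- cn$A1 * exp(-cn$E1 / theta_star)
  k1w <- cn$A1 * exp(-cn$E1 / theta_w)
  xsc <- 1 / cn$u
  xsw <- exp(dE * (1 / theta_w - 1 / theta_c))
  Ec <- exp(-k1c * cold_hours)
  Ew <- exp(-k1w * warm_hours)
  (xsc * (1 - Ec) + xsw * (1 - Ew) * Ec) / (1 - Ec * Ew)
}

#' Convert intermediate chill parameters to canonical form
#'
#' Solves for (E0, E1, A0, A1) from the intermediate parameterization.
#' Three conditions hold exactly by construction: the steady-state
#' precursor level equals 1 at `theta_c` (so constant exposure at or
#' above `theta_c` never completes a Chill Portion), the first portion
#' under constant `theta_star` completes at hour `tau`, and `theta_star`
#' is the constant temperature of fastest portion accumulation. The
#' remaining degree of freedom, `DeltaE = E1 - E0`, is pinned by `pie_c`:
#' in a square-wave cycle alternating equal spells at `theta_star` and a
#' warm negating temperature, the cyclic steady-state precursor peak
#' reaches exactly 1 when the cycle period equals `pie_c`. The warm-cycle
#' temperature is a convention of the cycle construction, not a fitted
#' quantity, and is configurable.
#'
#' @param ip An [intermediate_chill_params()] object.
#' @param Tf Transition temperature (degC) carried into the returned
#'   canonical set.
#' @param slope Transition slope carried into the returned canonical set.
#' @param theta_w Warm temperature (K) of the negation cycle; default
#'   297 K (24 degC).
#' @param cold_fraction Fraction of the cycle spent at `theta_star`
#'   (default 0.5). The cold spell is additionally capped at
#'   `0.9 * tau`: a cold spell at `theta_star` longer than `tau` would
#'   complete a Chill Portion on its own, making negation impossible and
#'   the critical period undefined.
#' @return A [chill_params()] object.
#' @export
intermediate_to_canonical <- function(ip, Tf = 4, slope = 1.6,
                                      theta_w = 297, cold_fraction = 0.5) {
  stopifnot(inherits(ip, "intermediate_chill_params"))
  ts <- ip$theta_star
  tc <- ip$theta_c
  cold <- min(ip$pie_c * cold_fraction, 0.9 * ip$tau)
  warm <- ip$pie_c - cold
  fn <- function(dE) {
    cn <- .canonical_given_deltaE(dE, ts, tc, ip$tau)
    if (is.null(cn)) return(NA_real_)
    .cycle_peak(cn, dE, ts, tc, theta_w, cold, warm) - 1
  }
  # bracket the root on a log grid; the peak is monotone decreasing in
  # DeltaE over the admissible box
  grid <- exp(seq(log(200), log(60000), length.out = 80))
  vals <- vapply(grid, fn, numeric(1))
  ok <- which(is.finite(vals))
  if (length(ok) < 2)
    stop("intermediate_to_canonical: cycle condition not evaluable for these parameters")
  sgn <- sign(vals[ok])
  flip <- which(diff(sgn) != 0)
  if (length(flip) == 0)
    stop("intermediate_to_canonical: no DeltaE satisfies the pie_c cycle condition within numeric bounds")
  lo <- grid[ok[flip[1]]]
  hi <- grid[ok[flip[1] + 1]]
  dE <- uniroot(fn, c(lo, hi), tol = 1e-10)$root
  cn <- .canonical_given_deltaE(dE, ts, tc, ip$tau)
  chill_params(E0 = cn$E0, E1 = cn$E1, A0 = cn$A0, A1 = cn$A1, Tf = Tf,
               slope = slope)
}
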