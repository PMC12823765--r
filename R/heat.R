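#' Growing Degree Hours for a single temperature
#'
#' Piecewise-cosine forcing response: zero at or below `Tb` and at or
#' above `Tc`, rising half-cosine to a maximum of `Tu - Tb` heat units at
#' `Tu`, falling half-cosine back to zero at `Tc`. Continuous at all
#' three cardinal temperatures.
#'
#' @param temp_C Temperature(s) in degrees Celsius.
#' @param params A [heat_params()] object.
#' @return Heat units (GDH) accrued in one hour at each temperature.
#' @export
gdh_hour <- function(temp_C, params) {
  stopifnot(inherits(params, "heat_params"))
  if (any(!is.finite(temp_C))) stop("temperature must be finite")
  cpp_gdh_hour(as.numeric(temp_C), params$Tb, params$Tu, params$Tc)
}

#' Accumulate Growing Degree Hours over an hourly series
#'
#' @param hourly Numeric vector of hourly temperatures (degC).
#' @param params A [heat_params()] object.
#' @param weights Optional per-hour multipliers in `[0, 1]` (the
#'   chill-dependent effectiveness weights); default all 1.
#' @return Nondecreasing cumulative heat trajectory, one value per hour.
#' @export
accumulate_gdh <- function(hourly, params, weights = NULL) {
  stopifnot(inherits(params, "heat_params"))
  if (length(hourly) == 0) return(numeric(0))
  if (is.null(weights)) weights <- rep(1, length(hourly))
  if (length(weights) != length(hourly))
    stop("weights must have the same length as the temperature series")
  if (any(!is.finite(hourly))) stop("hourly temperatures must be finite")
  cpp_gdh_accumulate(as.numeric(hourly), params$Tb, params$Tu, params$Tc,
                     as.numeric(weights))
}
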