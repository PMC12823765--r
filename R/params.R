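#' Dynamic Model chill submodel parameters
#'
#' Canonical six-parameter description of the two-step chill kinetics:
#' a temperature-dependent precursor (PDBF) forms at rate
#' `A0 * exp(-E0/T)` and is destroyed at rate `A1 * exp(-E1/T)`; once the
#' precursor level reaches 1 it is partially converted into permanent
#' chill (a Chill Portion variant), with the converted fraction governed
#' by `Tf` and `slope`.
#'
#' @param E0 Activation energy for forming the precursor (K).
#' @param E1 Activation energy for destroying the precursor (K); must
#'   exceed `E0`.
#' @param A0 Formation amplitude (1/h), positive.
#' @param A1 Destruction amplitude (1/h), positive.
#' @param Tf Transition temperature of the precursor-to-chill conversion
#'   (degrees Celsius).
#' @param slope Slope of the conversion transition (unitless, positive).
#' @return An object of class `chill_params`.
#' @export
chill_params <- function(E0, E1, A0, A1, Tf, slope) {
  vals <- c(E0 = unname(E0), E1 = unname(E1), A0 = unname(A0),
            A1 = unname(A1), Tf = unname(Tf), slope = unname(slope))
  if (any(!is.finite(vals))) stop("chill parameters must be finite")
  if (A0 <= 0 || A1 <= 0) stop("A0 and A1 must be positive")
  if (E1 <= E0) stop("E1 must exceed E0")
  if (slope <= 0) stop("slope must be positive")
  structure(as.list(vals), class = "chill_params")
}

#' Default chill submodel parameters
#'
#' The standard Dynamic Model parameter set used by the baseline
#' calibration scheme.
#'
#' @return A [chill_params()] object with E0 = 3372.8, E1 = 9900.3,
#'   A0 = 6319.5, A1 = 5.939917e13, Tf = 4, slope = 1.6.
#' @export
default_chill_params <- function() {
  chill_params(E0 = 3372.8, E1 = 9900.3, A0 = 6319.5, A1 = 5.939917e13,
               Tf = 4, slope = 1.6)
}

#' @export
print.chill_params <- function(x, ...) {
  cat("Dynamic Model chill parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' Growing Degree Hours heat submodel parameters
#'
#' Cardinal temperatures of the piecewise-cosine forcing response: zero
#' at or below `Tb`, maximal (`Tu - Tb` heat units per hour) at `Tu`,
#' zero again at or above `Tc`.
#'
#' @param Tb Base temperature (degC).
#' @param Tu Optimal temperature (degC).
#' @param Tc Critical temperature (degC); fixed at 36 throughout
#'   calibration.
#' @return An object of class `heat_params`.
#' @export
heat_params <- function(Tb, Tu, Tc = framework_constants()$Tc) {
  vals <- c(Tb = unname(Tb), Tu = unname(Tu), Tc = unname(Tc))
  if (any(!is.finite(vals))) stop("heat parameters must be finite")
  if (!(Tb < Tu && Tu < Tc)) stop("heat parameters must satisfy Tb < Tu < Tc")
  structure(as.list(vals), class = "heat_params")
}

#' Default heat submodel parameters
#'
#' @return A [heat_params()] object with Tb = 4, Tu = 26, Tc = 36.
#' @export
default_heat_params <- function() heat_params(Tb = 4, Tu = 26, Tc = 36)

#' @export
print.heat_params <- function(x, ...) {
  cat("GDH heat parameters:\n")
  print(unlist(x))
  invisible(x)
}

#' Cultivar-specific agroclimatic requirements
#'
#' @param yc Chill requirement (Chill Portion variant) that must
#'   accumulate before heat becomes fully effective.
#' @param zc Heat requirement (GDH variant) whose attainment triggers
#'   predicted bloom.
#' @param s1 Slope of the chill-to-heat transition; large values enforce
#'   sequential chill-then-heat accumulation, small values allow the two
#'   phases to overlap.
#' @return An object of class `cultivar_requirements`.
#' @export
cultivar_requirements <- function(yc, zc, s1) {
  vals <- c(yc = unname(yc), zc = unname(zc), s1 = unname(s1))
  if (any(!is.finite(vals))) stop("requirements must be finite")
  if (yc <= 0 || zc <= 0 || s1 <= 0) stop("requirements must be positive")
  structure(as.list(vals), class = "cultivar_requirements")
}

#' @export
print.cultivar_requirements <- function(x, ...) {
  cat(sprintf("Cultivar requirements: yc = %.3g CP, zc = %.4g GDH, s1 = %.3g\n",
              x$yc, x$zc, x$s1))
  invisible(x)
}

#' Intermediate chill submodel parameters
#'
#' Reparameterization of (E0, E1, A0, A1) into quantities with narrow,
#' interpretable bounds: the optimal constant chill temperature
#' `theta_star` (fixed at 279 K), the critical constant temperature
#' `theta_c` above which no chill accumulates, the time `tau` needed to
#' accumulate one Chill Portion at `theta_star`, and the critical period
#' `pie_c` of a combined temperature cycle at which chill negation sets
#' in.
#'
#' @param theta_c Critical constant temperature (K).
#' @param tau Hours to the first Chill Portion at `theta_star`.
#' @param pie_c Critical cycle period for chill negation (h).
#' @param theta_star Optimal constant chill temperature (K), fixed.
#' @return An object of class `intermediate_chill_params`.
#' @seealso [intermediate_to_canonical()]
#' @export
intermediate_chill_params <- function(theta_c, tau, pie_c,
                                      theta_star = framework_constants()$theta_star) {
  vals <- c(theta_star = unname(theta_star), theta_c = unname(theta_c),
            tau = unname(tau), pie_c = unname(pie_c))
  if (any(!is.finite(vals))) stop("intermediate parameters must be finite")
  if (theta_star >= theta_c)
    stop("theta_star must lie below theta_c")
  if (tau <= 0 || pie_c <= 0) stop("tau and pie_c must be positive")
  structure(as.list(vals), class = "intermediate_chill_params")
}

#' @export
print.intermediate_chill_params <- function(x, ...) {
  cat("Intermediate chill parameters:\n")
  print(unlist(x))
  invisible(x)
}
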