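#' Thermal constants of the subthreshold MOSFET characteristic curves
#'
#' The sigmoidal V-I curves of the analog silicon neurons are parameterized by
#' the thermal voltage `U_T` (about 26 mV at room temperature) and the
#' capacitive-coupling ratio `kappa` (about 0.7 for the target process). The
#' exponential steepness of every curve is `kappa / U_T` per volt.
#'
#' @param U_T Thermal voltage in volts. Must be positive.
#' @param kappa Capacitive-coupling ratio, in (0, 1].
#' @return An object of class `thermal_constants`.
#' @examples
#' thermal_constants()            # room-temperature defaults
#' thermal_constants(U_T = 0.025)
#' @export
thermal_constants <- function(U_T = 0.026, kappa = 0.7) {
  stopifnot(is.numeric(U_T), length(U_T) == 1L, is.finite(U_T), U_T > 0,
            is.numeric(kappa), length(kappa) == 1L, is.finite(kappa),
            kappa > 0, kappa <= 1)
  structure(list(U_T = U_T, kappa = kappa), class = "thermal_constants")
}

# steepness kappa/U_T in 1/volts
.k_over_ut <- function(consts) consts$kappa / consts$U_T

#' @export
print.thermal_constants <- function(x, ...) {
  cat(sprintf("thermal_constants: U_T = %g V, kappa = %g (kappa/U_T = %.3f /V)\n",
              x$U_T, x$kappa, .k_over_ut(x)))
  invisible(x)
}
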