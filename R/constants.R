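#' @useDynLib RepeatPull, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

## Internal unit conventions: coordinates in Angstrom, time in ps, force in
## pN, work in pN*A.  Thermal energies are reported in units of kBT.

#' Thermal energy in pN Angstrom
#'
#' Boltzmann constant times temperature expressed in the package's internal
#' units (pN A).  At the default simulation temperature of 300 K this is
#' 41.419 pN A, the conversion factor between mechanical work in pN A and
#' work in units of kBT.
#'
#' @param temperature Temperature in Kelvin.
#' @return Thermal energy kB*T in pN A.
#' @examples
#' kBT()          # 41.419 pN A at 300 K
#' 1000 / kBT()   # 1000 pN A expressed in kBT
#' @export
kBT <- function(temperature = 300) {
  ## CODATA kB = 1.380649e-23 J/K; 1 pN A = 1e-22 J
  0.1380649 * temperature
}

## shared numeric guards -----------------------------------------------------

.assertScalarPositive <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(what, " must be a single positive number", call. = FALSE)
  invisible(x)
}

.assertStrictlyIncreasing <- function(x, what) {
  if (length(x) > 1L && any(diff(x) <= 0))
    stop(what, " must be strictly increasing", call. = FALSE)
  invisible(x)
}
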