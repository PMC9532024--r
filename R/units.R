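#' Unit conversion constants
#'
#' The solver works internally in SI (Pa, m, m^3/s); the interfaces use the
#' conventional clinical units (mm, mmHg, ml/s, Pa s/ml). These constants
#' are the exact conversion factors used everywhere in the package.
#'
#' @format Named numeric constants:
#' * `MMHG_TO_PA`: 133.322 Pa per mmHg
#' * `MM_TO_M`: 1e-3
#' * `ML_TO_M3`: 1e-6
#' * `PASML_TO_PASM3`: 1e6 (Pa s/ml expressed in Pa s/m^3)
#' @name units
#' @keywords internal
NULL

MMHG_TO_PA <- 133.322
MM_TO_M <- 1e-3
ML_TO_M3 <- 1e-6
PASML_TO_PASM3 <- 1e6

#' Convert between mmHg and Pa
#'
#' @param x numeric vector of pressures.
#' @return Numeric vector in the target unit.
#' @examples
#' mmhg_to_pa(100) # 13332.2
#' @export
mmhg_to_pa <- function(x) x * MMHG_TO_PA

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(x) x / MMHG_TO_PA
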