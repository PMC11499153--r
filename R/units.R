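## Unit conversions. All model internals run in cm / s / mol/cm^3 / A;
## user-facing interfaces take micrometres and millimolar.

#' Unit converters for the RTI model
#'
#' The diffusion model computes internally in cm, s, mol/cm^3 and A, the
#' units in which the free diffusion coefficient D (cm^2/s) is reported in
#' the iontophoresis literature. Interfaces accept micrometres and
#' millimolar; these converters make the mapping explicit.
#'
#' 1 mM = 1e-6 mol/cm^3; 1 um = 1e-4 cm; 1 nA = 1e-9 A.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @examples
#' umToCm(100)        # 0.01 cm
#' mMToMolPerCm3(0.1) # 1e-7 mol/cm^3
#' @name units
NULL

#' @rdname units
#' @export
umToCm <- function(x) x * 1e-4

#' @rdname units
#' @export
cmToUm <- function(x) x * 1e4

#' @rdname units
#' @export
mMToMolPerCm3 <- function(x) x * 1e-6

#' @rdname units
#' @export
molPerCm3ToMM <- function(x) x * 1e6

#' @rdname units
#' @export
nAToA <- function(x) x * 1e-9

## Faraday constant, C/mol
.FARADAY <- 96485
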