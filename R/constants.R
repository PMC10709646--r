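## Physical constants and unit conversions. Internal units throughout:
## energy eV, length Angstrom, time fs, temperature K.

#' Physical constants used throughout the package
#'
#' @format A list with elements:
#' \describe{
#'   \item{kB}{Boltzmann constant, eV/K.}
#'   \item{amu}{One atomic mass unit expressed in eV fs^2/A^2, so that
#'     kinetic energy (1/2) m v^2 is in eV when v is in A/fs.}
#'   \item{eV_per_kJmol}{Conversion factor: energies in kJ/mol divided by
#'     this give eV.}
#' }
#' @export
dpt_constants <- list(
  kB           = 8.617333262e-5,   # eV/K
  amu          = 103.642696,       # eV fs^2 / A^2
  eV_per_kJmol = 96.48533212       # kJ/mol per eV
)

## default umbrella force constant: 20000 kJ/mol/nm^2 per distance coordinate
.default_bias_k_kJmolnm2 <- 20000

#' Convert an umbrella force constant from kJ/mol/nm^2 to eV/A^2
#'
#' @param k force constant in kJ/mol/nm^2 (the field's conventional unit)
#' @return force constant in eV/A^2
#' @export
bias_k_to_eV <- function(k) k / dpt_constants$eV_per_kJmol / 100
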