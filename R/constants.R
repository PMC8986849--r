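#' Physical constants used by the thermodynamic conversions
#'
#' Returns the immutable registry of physical constants used throughout the
#' package: the gas constant in kcal and cal units, the Boltzmann and Planck
#' constants (2019 SI exact values), and the transmission coefficient used in
#' the Eyring relation (kappa = 1, standard transition-state theory).
#'
#' @return A named list with elements `R_kcal` (kcal mol^-1 K^-1), `R_cal`
#'   (cal mol^-1 K^-1), `kB` (J K^-1), `h` (J s) and `kappa`.
#' @examples
#' pre_constants()$R_kcal
#' @export
pre_constants <- function() .pre_constants

.pre_constants <- list(
  R_kcal = 1.98720425e-3, # gas constant, kcal mol^-1 K^-1
  R_cal  = 1.98720425,    # gas constant, cal mol^-1 K^-1
  kB     = 1.380649e-23,  # Boltzmann constant, J K^-1
  h      = 6.62607015e-34,# Planck constant, J s
  kappa  = 1              # transmission coefficient
)
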