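#' Physical constants used throughout the package
#'
#' CODATA 2018 values. All internal energies are in units of kBT, lengths in
#' Angstrom and charges in elementary charges; SI conversion happens only in
#' [debye_length()], [bjerrum_length()] and [gc_gamma0()]. The full table is
#' embedded in every run summary so results can be traced to the constants
#' they were computed with.
#'
#' @return Named list with elements `e` (elementary charge, C), `kB`
#'   (Boltzmann constant, J/K), `NA_` (Avogadro constant, 1/mol), `eps0`
#'   (vacuum permittivity, F/m).
#' @export
#' @examples
#' physical_constants()$kB
physical_constants <- function() {
  list(
    e    = 1.602176634e-19,
    kB   = 1.380649e-23,
    NA_  = 6.02214076e23,
    eps0 = 8.8541878128e-12
  )
}

## internal shorthand (fixed copy so hot loops avoid repeated list construction)
.const <- list(
  e    = 1.602176634e-19,
  kB   = 1.380649e-23,
  NA_  = 6.02214076e23,
  eps0 = 8.8541878128e-12
)
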