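#' Solution conditions for screened electrostatics
#'
#' Bundles temperature, solvent relative permittivity and 1:1 salt
#' concentration. For a pure 1:1 electrolyte the ionic strength equals the
#' salt concentration; a different ionic strength can be supplied for mixed
#' electrolytes. These conditions are the single source of the Debye
#' screening length and the Bjerrum length.
#'
#' @param salt_M 1:1 salt concentration in mol/L (default 0.025 M).
#' @param temperature Absolute temperature in K (default 298.15 K).
#' @param epsilon_r Relative permittivity of the solvent (default 78.5,
#'   water at room temperature).
#' @param ionic_strength Ionic strength in mol/L; defaults to `salt_M`.
#' @return An object of class `solution_conditions`.
#' @export
#' @examples
#' cond <- solution_conditions(salt_M = 0.025)
#' debye_length(cond) # about 19.2 Angstrom
solution_conditions <- function(salt_M = 0.025, temperature = 298.15,
                                epsilon_r = 78.5, ionic_strength = salt_M) {
  stopifnot(temperature > 0, epsilon_r > 0, salt_M >= 0)
  x <- list(
    salt_M = salt_M,
    temperature = temperature,
    epsilon_r = epsilon_r,
    ionic_strength = ionic_strength
  )
  class(x) <- "solution_conditions"
  x
}

#' @export
print.solution_conditions <- function(x, ...) {
  cat(sprintf(
    "Solution conditions: T = %.2f K, eps_r = %.1f, c0 = %g M (I = %g M)\n",
    x$temperature, x$epsilon_r, x$salt_M, x$ionic_strength))
  if (x$ionic_strength > 0)
    cat(sprintf("  Debye length: %.2f A, Bjerrum length: %.2f A\n",
                debye_length(x), bjerrum_length(x)))
  invisible(x)
}

#' Debye screening length
#'
#' kappa^-1 = sqrt(eps0 eps_r kB T / (2e3 NA e^2 I)), returned in Angstrom.
#'
#' @param cond A [solution_conditions()] object.
#' @return Debye length in Angstrom.
#' @export
debye_length <- function(cond) {
  if (cond$ionic_strength <= 0)
    stop("ionic strength must be > 0 to define a Debye length")
  k <- .const
  m <- sqrt(k$eps0 * cond$epsilon_r * k$kB * cond$temperature /
              (2e3 * k$NA_ * k$e^2 * cond$ionic_strength))
  m * 1e10
}

#' Bjerrum length
#'
#' lB = e^2 / (4 pi eps0 eps_r kB T), the separation at which two unit
#' charges interact with thermal energy kBT. Returned in Angstrom
#' (about 7.1 A in water at 298 K).
#'
#' @inheritParams debye_length
#' @return Bjerrum length in Angstrom.
#' @export
bjerrum_length <- function(cond) {
  k <- .const
  m <- k$e^2 / (4 * pi * k$eps0 * cond$epsilon_r * k$kB * cond$temperature)
  m * 1e10
}
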