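# Pairwise and surface interaction energies. All energies in kBT, lengths
# in Angstrom, charges in elementary charges.

#' Harmonic bond parameters
#'
#' @param kh Spring constant in kBT/Angstrom^2 (default 0.76).
#' @param Req Equilibrium bond length in Angstrom (default 4.1).
#' @return An object of class `bond_spec`.
#' @export
bond_spec <- function(kh = 0.76, Req = 4.1) {
  stopifnot(kh > 0, Req > 0)
  structure(list(kh = kh, Req = Req), class = "bond_spec")
}

#' Lennard-Jones pair parameters
#'
#' @param eps_nb Interaction strength in kBT (default 0.05).
#' @return An object of class `pair_params`.
#' @export
pair_params <- function(eps_nb = 0.05) {
  stopifnot(eps_nb >= 0)
  structure(list(eps_nb = eps_nb), class = "pair_params")
}

#' Screened-Coulomb (Debye-Hueckel) pair energy with hard core
#'
#' w = lB zi zj exp(-kappa (r - sigma)) / (r (1 + kappa sigma)) for
#' r >= sigma, and +Inf inside the hard core (r < sigma). The size term
#' (1 + kappa sigma) accounts for the finite particle diameters; in the
#' kappa -> 0 limit the bare Coulomb form lB zi zj / r is recovered.
#' Vectorized over `rij`.
#'
#' @param zi,zj Charge numbers (elementary charges).
#' @param rij Center-to-center distance(s), Angstrom.
#' @param sigma_ij Contact distance (sum of radii), Angstrom.
#' @param kappa Inverse Debye length, 1/Angstrom.
#' @param cond A [solution_conditions()] (source of the Bjerrum length).
#' @return Energy in kBT (same length as `rij`).
#' @export
#' @examples
#' cond <- solution_conditions()
#' dh_pair_energy(1, 1, 5, 5, 1 / debye_length(cond), cond)
dh_pair_energy <- function(zi, zj, rij, sigma_ij, kappa, cond) {
  lB <- bjerrum_length(cond)
  w <- lB * zi * zj * exp(-kappa * (rij - sigma_ij)) /
    (rij * (1 + kappa * sigma_ij))
  w[rij < sigma_ij] <- Inf
  w
}

#' Harmonic bond energy
#'
#' kh (Rb - Req)^2 in kBT; symmetric about the equilibrium length.
#'
#' @param Rb Bond length(s), Angstrom.
#' @param spec A [bond_spec()].
#' @return Energy in kBT.
#' @export
bond_energy <- function(Rb, spec = bond_spec()) {
  spec$kh * (Rb - spec$Req)^2
}

#' Lennard-Jones energy
#'
#' 4 eps_nb ((sigma/r)^12 - (sigma/r)^6); zero at contact, minimum -eps_nb
#' at r = 2^(1/6) sigma. The hard core below sigma is handled by
#' [dh_pair_energy()], so this term is only evaluated at r >= sigma.
#'
#' @param rij Distance(s), Angstrom.
#' @param sigma_ij Contact distance, Angstrom.
#' @param pp A [pair_params()].
#' @return Energy in kBT.
#' @export
lj_energy <- function(rij, sigma_ij, pp = pair_params()) {
  sr6 <- (sigma_ij / rij)^6
  4 * pp$eps_nb * (sr6 * sr6 - sr6)
}

#' Gouy-Chapman reduced surface potential
#'
#' Gamma0 = tanh( asinh( sigma_SI / sqrt(8e3 NA kB T c0 eps0 eps_r) ) / 2 )
#' for a uniformly charged plane in contact with a 1:1 electrolyte
#' (Grahame relation). Odd in the surface charge density.
#'
#' @param rho Surface charge density in e/Angstrom^2 (signed).
#' @param c0 1:1 salt concentration, mol/L; defaults to the conditions'.
#' @param cond A [solution_conditions()].
#' @return Dimensionless Gamma0 in (-1, 1).
#' @export
#' @examples
#' gc_gamma0(-0.005) # about -0.80
gc_gamma0 <- function(rho, c0 = NULL, cond = solution_conditions()) {
  if (is.null(c0)) c0 <- cond$salt_M
  if (c0 <= 0) stop("salt concentration must be > 0")
  k <- .const
  sigma_SI <- rho * k$e / 1e-20                      # e/A^2 -> C/m^2
  denom <- sqrt(8e3 * c0 * k$NA_ * k$eps0 * cond$epsilon_r *
                  k$kB * cond$temperature)
  tanh(0.5 * asinh(sigma_SI / denom))
}

#' Charged flat surface (Gouy-Chapman field)
#'
#' Precomputes the reduced surface potential and screening constant for a
#' uniformly charged plane at z = 0.
#'
#' @param rho Surface charge density, e/Angstrom^2 (signed).
#' @param cond A [solution_conditions()].
#' @return Object of class `surface_field` with `rho`, `gamma0`, `kappa`.
#' @export
surface_field <- function(rho, cond = solution_conditions()) {
  structure(list(rho = rho, gamma0 = gc_gamma0(rho, cond = cond),
                 kappa = 1 / debye_length(cond)),
            class = "surface_field")
}

#' Gouy-Chapman energy of a point charge above a charged plane
#'
#' w = 2 zi ln( (1 + Gamma0 exp(-kappa rs)) / (1 - Gamma0 exp(-kappa rs)) )
#' in kBT, where rs is the distance from the surface plane to the bead
#' center. Attractive for charges opposite in sign to the surface; decays
#' with the Debye length. The hard wall (rs below the bead radius) returns
#' +Inf. Vectorized over `rs`.
#'
#' @param zi Charge number.
#' @param rs Distance(s) from the plane to the bead center, Angstrom.
#' @param field A [surface_field()].
#' @param hard_wall_at Hard-wall contact distance (bead radius); rs below
#'   it gives +Inf. Use 0 to disable.
#' @return Energy in kBT.
#' @export
gc_energy <- function(zi, rs, field, hard_wall_at = 0) {
  g <- field$gamma0 * exp(-field$kappa * rs)
  w <- 2 * zi * log((1 + g) / (1 - g))
  w[rs < hard_wall_at] <- Inf
  w
}

#' Nanoparticle charge matching a surface charge density
#'
#' Z = round(4 pi R^2 rho): the sphere carries the same surface charge
#' density as the flat substrate, concentrated as a point charge at its
#' center.
#'
#' @param rho Surface charge density, e/Angstrom^2.
#' @param R Nanoparticle radius, Angstrom.
#' @return Integer-valued charge in elementary charges.
#' @export
#' @examples
#' np_charge(-0.001, 200) # -503
np_charge <- function(rho, R) {
  stopifnot(R > 0)
  round(4 * pi * R^2 * rho)
}

#' Nanoparticle-bead interaction energy
#'
#' Screened Coulomb interaction between a nanoparticle's central point
#' charge and a bead, with the size-corrected contact distance
#' sigma = R + bead radius: [dh_pair_energy()] applied to the pair. The
#' distance is the center-to-center separation (minimum image in xy if a
#' cell is given).
#'
#' @param np List/row with `x`, `y`, `z`, `radius`, `charge`.
#' @param bead_pos Length-3 bead center.
#' @param bead_charge,bead_radius Bead charge (e) and radius (Angstrom).
#' @param cond A [solution_conditions()].
#' @param cell Optional [simulation_cell()] for xy minimum image.
#' @return Energy in kBT (+Inf if the bead overlaps the nanoparticle).
#' @export
np_bead_energy <- function(np, bead_pos, bead_charge, bead_radius,
                           cond = solution_conditions(), cell = NULL) {
  d <- bead_pos - c(np$x, np$y, np$z)
  if (!is.null(cell)) {
    d[1] <- d[1] - cell$Lx * round(d[1] / cell$Lx)
    d[2] <- d[2] - cell$Ly * round(d[2] / cell$Ly)
  }
  r <- sqrt(sum(d^2))
  dh_pair_energy(np$charge, bead_charge, r, np$radius + bead_radius,
                 1 / debye_length(cond), cond)
}
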