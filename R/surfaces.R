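# Simulation cell and surface layouts: flat wall, flat wall with a
# hexagonal nanoparticle lattice, and a single free nanoparticle.

#' Simulation cell
#'
#' Periodic in x and y; non-periodic in z with a hard floor at z = 0 (the
#' charged substrate plane, where applicable) and a hard ceiling at z = Lz.
#'
#' @param Lx,Ly,Lz Side lengths in Angstrom.
#' @return Object of class `simulation_cell`.
#' @export
simulation_cell <- function(Lx, Ly = Lx, Lz = 1500) {
  stopifnot(Lx > 0, Ly > 0, Lz > 0)
  structure(list(Lx = Lx, Ly = Ly, Lz = Lz), class = "simulation_cell")
}

#' Minimum-image displacement
#'
#' Displacement `a - b` with the x and y components wrapped into
#' (-L/2, L/2]; z is not periodic and is returned unwrapped.
#'
#' @param a,b Length-3 vectors (or N x 3 matrices, rowwise).
#' @param cell A [simulation_cell()].
#' @return Displacement of the same shape as the inputs.
#' @export
min_image_displacement <- function(a, b, cell) {
  d <- a - b
  if (is.matrix(d)) {
    d[, 1] <- d[, 1] - cell$Lx * round(d[, 1] / cell$Lx)
    d[, 2] <- d[, 2] - cell$Ly * round(d[, 2] / cell$Ly)
  } else {
    d[1] <- d[1] - cell$Lx * round(d[1] / cell$Lx)
    d[2] <- d[2] - cell$Ly * round(d[2] / cell$Ly)
  }
  d
}

#' Projected surface coverage of a hexagonal sphere lattice
#'
#' Fraction of the substrate area occluded by the nanoparticles' projected
#' disks: 2 pi R^2 / (sqrt(3) d^2) for a triangular lattice with
#' nearest-neighbor distance d, capped at 1 where the disks overlap.
#'
#' @param R Nanoparticle radius, Angstrom.
#' @param d Nearest-neighbor center-to-center distance, Angstrom.
#' @return Coverage fraction in `[0, 1]`.
#' @export
#' @examples
#' coverage(200, 600) # ~0.40
coverage <- function(R, d) {
  stopifnot(d > 0)
  min(2 * pi * R^2 / (sqrt(3) * d^2), 1)
}

#' Lattice spacing for a target surface coverage
#'
#' Inverts [coverage()]: d = R sqrt(2 pi / (sqrt(3) phi)). Valid up to the
#' hexagonal close packing of disks (phi = 0.9069).
#'
#' @param R Nanoparticle radius, Angstrom.
#' @param phi Target coverage fraction in (0, 0.9069].
#' @return Nearest-neighbor distance in Angstrom.
#' @export
#' @examples
#' spacing_from_coverage(200, 0.40) # ~602
spacing_from_coverage <- function(R, phi) {
  if (phi <= 0 || phi > pi / (2 * sqrt(3)) + 1e-9)
    stop("coverage must be in (0, 0.9069] (hexagonal close packing of disks)")
  R * sqrt(2 * pi / (sqrt(3) * phi))
}

.new_layout <- function(kind, rho, cell, nanoparticles = NULL, spacing = NA,
                        wall = TRUE, shell_outer = NA) {
  if (is.null(nanoparticles))
    nanoparticles <- data.frame(x = numeric(0), y = numeric(0),
                                z = numeric(0), radius = numeric(0),
                                charge = numeric(0))
  structure(list(kind = kind, rho = rho, cell = cell,
                 nanoparticles = nanoparticles, spacing = spacing,
                 wall = wall, shell_outer = shell_outer),
            class = "surface_layout")
}

#' Flat charged surface layout
#'
#' A uniformly charged plane at z = 0 spanning the periodic cell.
#'
#' @param rho Surface charge density, e/Angstrom^2 (signed).
#' @param cell A [simulation_cell()].
#' @return Object of class `surface_layout`, kind `"flat"`.
#' @export
flat_surface <- function(rho, cell) .new_layout("flat", rho, cell)

#' Hexagonal nanoparticle lattice on a flat surface
#'
#' Spheres of radius `R` resting on the substrate (center height `R`) on a
#' triangular lattice with nearest-neighbor distance `d`, alternate rows
#' offset by `d/2`. Each sphere carries the point charge [np_charge()]
#' matching the substrate's charge density. The cell must be commensurate:
#' `Lx = n d` and `Ly = m sqrt(3) d` for integers n, m.
#'
#' @param R Nanoparticle radius, Angstrom.
#' @param d Nearest-neighbor center distance, Angstrom (d < 2R is allowed:
#'   spheres may touch or interpenetrate; hard-core tests use the union of
#'   spheres).
#' @param cell A [simulation_cell()].
#' @param rho Surface charge density, e/Angstrom^2.
#' @return Object of class `surface_layout`, kind `"flat+lattice"`.
#' @export
#' @examples
#' cell <- simulation_cell(1200, sqrt(3) * 600)
#' lay <- hex_lattice(200, 600, cell, -0.005)
#' nrow(lay$nanoparticles) # 4
hex_lattice <- function(R, d, cell, rho) {
  stopifnot(R > 0, d > 0)
  n <- cell$Lx / d
  m <- cell$Ly / (sqrt(3) * d)
  if (abs(n - round(n)) > 1e-6 || abs(m - round(m)) > 1e-6)
    stop(sprintf(paste0(
      "cell is not commensurate with the lattice: need Lx = n*d, ",
      "Ly = m*sqrt(3)*d; nearest valid Lx = %.4f, Ly = %.4f"),
      round(n) * d, round(m) * sqrt(3) * d))
  n <- round(n); m <- round(m)
  if (n < 1 || m < 1) stop("cell too small for one lattice repeat")
  Z <- np_charge(rho, R)
  ij <- expand.grid(i = seq_len(n) - 1, j = seq_len(2 * m) - 1)
  nps <- data.frame(
    x = ij$i * d + (ij$j %% 2) * d / 2,
    y = ij$j * sqrt(3) * d / 2,
    z = R,
    radius = R,
    charge = Z)
  .new_layout("flat+lattice", rho, cell, nps, spacing = d)
}

#' Single free nanoparticle layout
#'
#' One charged sphere fixed at the cell center, no flat wall; the protein
#' is confined (by its center of mass) to a spherical shell of outer radius
#' `Lx/2` around the nanoparticle, emulating adsorption onto free
#' nanoparticles in solution.
#'
#' @param R Nanoparticle radius, Angstrom.
#' @param cell A [simulation_cell()] (use `Lx` comfortably larger than
#'   `2R` plus the protein extent plus several Debye lengths).
#' @param rho Surface charge density the sphere mimics, e/Angstrom^2.
#' @return Object of class `surface_layout`, kind `"single_np"`.
#' @export
single_nanoparticle <- function(R, cell, rho) {
  stopifnot(R > 0, cell$Lx / 2 > R)
  nps <- data.frame(x = cell$Lx / 2, y = cell$Ly / 2, z = cell$Lz / 2,
                    radius = R, charge = np_charge(rho, R))
  .new_layout("single_np", rho, cell, nps, wall = FALSE,
              shell_outer = cell$Lx / 2)
}

#' @export
print.surface_layout <- function(x, ...) {
  cat(sprintf("Surface layout '%s': rho = %g e/A^2", x$kind, x$rho))
  if (nrow(x$nanoparticles))
    cat(sprintf(", %d nanoparticle(s) R = %g A, Z = %g e",
                nrow(x$nanoparticles), x$nanoparticles$radius[1],
                x$nanoparticles$charge[1]))
  if (!is.na(x$spacing)) cat(sprintf(", spacing %g A", x$spacing))
  cat(sprintf("\n  cell %g x %g x %g A\n", x$cell$Lx, x$cell$Ly, x$cell$Lz))
  invisible(x)
}

#' Write nanoparticle centers to TSV
#'
#' @param layout A `surface_layout`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_layout_tsv <- function(layout, path) {
  utils::write.table(layout$nanoparticles, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
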