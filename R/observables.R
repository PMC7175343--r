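# Analysis of sampled configurations: free-energy profiles, orientation
# distributions, radial distribution functions, adsorbed fractions, and
# polymer shape descriptors.

#' Center-of-mass heights of a sample set
#' @param samples A `sample_set`.
#' @return Numeric vector of COM z coordinates (Angstrom).
#' @export
com_heights <- function(samples) {
  m <- samples$sys$mass
  vapply(samples$positions, function(p) sum(p[, 3] * m) / sum(m), numeric(1))
}

#' Adsorption free-energy profile F(z)
#'
#' Histograms the protein center-of-mass height above a flat surface and
#' converts the probability to a potential of mean force
#' F(z) = -ln P(z) + C (kBT), with C fixed so that the mean over the outer
#' plateau region (the outer 20% of the sampled z range by default) is
#' zero. Empty bins are masked (NA). If no samples fall in the plateau
#' region, the outermost populated quartile is used with a warning.
#'
#' @param samples A `sample_set` from a flat-surface system.
#' @param bin_width Bin width in Angstrom (default 2).
#' @param plateau_fraction Outer fraction of the sampled range used to
#'   anchor F = 0 (default 0.2).
#' @return A [new_profile()] with `free_energy_kBT` normalization.
#' @export
free_energy_profile <- function(samples, bin_width = 2,
                                plateau_fraction = 0.2) {
  z <- com_heights(samples)
  edges <- seq(floor(min(z)), max(z) + bin_width, by = bin_width)
  counts <- graphics::hist(z, breaks = edges, plot = FALSE)$counts
  P <- counts / sum(counts)
  F <- -log(P)
  F[counts == 0] <- NA_real_
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  zmax <- max(z); zmin <- min(z)
  plateau <- mid >= zmax - plateau_fraction * (zmax - zmin)
  ok <- plateau & !is.na(F)
  if (!any(ok)) {
    warning("no populated plateau bins; anchoring on the outermost quartile")
    ok <- !is.na(F) & mid >= stats::quantile(z, 0.75)
  }
  F <- F - mean(F[ok])
  new_profile(edges, F, "free_energy_kBT", n_samples = length(z))
}

#' Radial distribution function around a single nanoparticle
#'
#' g(r) of the protein center of mass at distance r from the nanoparticle
#' *surface*: counts per spherical shell, divided by the shell volume and
#' by the overall concentration of the molecule in the accessible volume
#' (one molecule in the confinement shell), not by a local bulk estimate.
#' For a non-interacting molecule g(r) = 1 everywhere accessible.
#'
#' @param samples A `sample_set` from a single-nanoparticle system.
#' @param bin_width Shell width in Angstrom (default 2).
#' @return A [new_profile()] with `g_of_r` normalization; bin edges are
#'   distances from the nanoparticle surface.
#' @export
radial_g <- function(samples, bin_width = 2) {
  sys <- samples$sys
  if (!nrow(sys$layout$nanoparticles))
    stop("radial_g needs a nanoparticle in the layout")
  ctr <- c(sys$np_x[1], sys$np_y[1], sys$np_z[1])
  R <- sys$np_R[1]
  m <- sys$mass
  r <- vapply(samples$positions, function(p) {
    cm <- colSums(p * m) / sum(m)
    sqrt(sum((cm - ctr)^2)) - R
  }, numeric(1))
  rmax <- if (!is.na(sys$shell_outer)) sys$shell_outer - R else
    max(r) + bin_width
  edges <- seq(0, rmax + bin_width, by = bin_width)
  nb <- length(edges) - 1L
  idx <- findInterval(pmax(r, 0), edges, rightmost.closed = TRUE)
  counts <- tabulate(pmin(idx, nb), nbins = nb)
  shell_vol <- 4 / 3 * pi * ((edges[-1] + R)^3 - (edges[-length(edges)] + R)^3)
  V <- 4 / 3 * pi * ((rmax + R)^3 - R^3)
  g <- (counts / length(r)) / (shell_vol / V)
  new_profile(edges, g, "g_of_r", n_samples = length(r))
}

#' Long axis of a rigid configuration
#'
#' The principal gyration axis (largest-eigenvalue eigenvector of the
#' mass-weighted gyration tensor), sign fixed so the z component is
#' non-negative. Errors for sphere-like bodies with degenerate top
#' eigenvalues; rod-like bodies are always well defined.
#'
#' @param pos N x 3 configuration (or [bead_model()]).
#' @param mass Optional masses.
#' @return Unit length-3 vector.
#' @export
axis_vector <- function(pos, mass = NULL) principal_axis(pos, mass)

#' Cosine of the angle between the protein axis and the surface normal
#'
#' `|axis . z|` in `[0, 1]`: 0 for a protein lying flat on the surface, 1
#' for a protein standing up along the surface normal.
#'
#' @param pos Configuration or [bead_model()].
#' @param mass Optional masses.
#' @return Value in `[0, 1]`.
#' @export
cos_to_surface_normal <- function(pos, mass = NULL) {
  abs(axis_vector(pos, mass)[3])
}

#' Cosine of the angle between the protein axis and the nanoparticle
#' direction
#'
#' The direction is the line from the nanoparticle center to the protein
#' center of mass (minimum image in xy): `|axis . u|`, 1 for a protein
#' pointing radially away from the particle, 0 for a tangential pose.
#'
#' @param pos Configuration.
#' @param np One-row data.frame or list with `x`, `y`, `z` (nanoparticle
#'   center).
#' @param mass Optional masses.
#' @param cell Optional [simulation_cell()] for minimum image.
#' @return Value in `[0, 1]`.
#' @export
cos_to_np <- function(pos, np, mass = NULL, cell = NULL) {
  if (inherits(pos, "bead_model")) { mass <- pos$mass; pos <- pos$pos }
  if (is.null(mass)) mass <- rep(1, nrow(pos))
  cm <- colSums(pos * mass) / sum(mass)
  u <- cm - c(np$x, np$y, np$z)
  if (!is.null(cell)) u <- min_image_displacement(cm, c(np$x, np$y, np$z), cell)
  u <- u / sqrt(sum(u^2))
  abs(sum(axis_vector(pos, mass) * u))
}

#' Minimum bead-to-surface separation of a configuration
#'
#' Smallest surface-to-surface distance between any bead and the flat wall
#' or any nanoparticle (bead surface to substrate surface).
#'
#' @param pos N x 3 configuration.
#' @param sys The [cg_system()].
#' @return Distance in Angstrom (can be negative only for overlapping
#'   inputs).
#' @export
min_surface_separation <- function(pos, sys) {
  d <- Inf
  if (sys$wall) d <- min(d, min(pos[, 3] - sys$rad))
  for (j in seq_along(sys$np_R)) {
    dx <- pos[, 1] - sys$np_x[j]; dx <- dx - sys$Lx * round(dx / sys$Lx)
    dy <- pos[, 2] - sys$np_y[j]; dy <- dy - sys$Ly * round(dy / sys$Ly)
    dz <- pos[, 3] - sys$np_z[j]
    d <- min(d, min(sqrt(dx^2 + dy^2 + dz^2) - sys$np_R[j] - sys$rad))
  }
  d
}

#' Adsorbed fraction of a sample set
#'
#' Fraction of snapshots in which the molecule is within `cutoff` of a
#' surface (minimum bead-to-surface separation, flat wall or any
#' nanoparticle). The default cutoff is two Debye lengths, covering the
#' width of the screened-electrostatic free-energy well; absolute adsorbed
#' fractions also depend on the box height, so the cutoff and cell are
#' reported alongside every number.
#'
#' @param samples A `sample_set`.
#' @param cutoff Adsorption cutoff in Angstrom (default `2 / kappa`).
#' @return List with `fraction`, `cutoff`, and per-sample logical `flags`.
#' @export
adsorbed_fraction <- function(samples, cutoff = NULL) {
  sys <- samples$sys
  if (is.null(cutoff)) cutoff <- 2 / sys$kappa
  sep <- vapply(samples$positions, min_surface_separation, numeric(1),
                sys = sys)
  flags <- sep <= cutoff
  list(fraction = mean(flags), cutoff = cutoff, flags = flags,
       separation = sep)
}

#' Radius of gyration
#'
#' Mass-weighted: Rg^2 = sum(mi (ri - rcm)^2) / sum(mi).
#'
#' @param pos N x 3 configuration or [bead_model()].
#' @param mass Masses (default: model masses or unit).
#' @return Rg in Angstrom.
#' @export
#' @examples
#' rg(rbind(c(0, 0, 0), c(0, 0, 10))) # 5
rg <- function(pos, mass = NULL) {
  if (inherits(pos, "bead_model")) {
    if (is.null(mass)) mass <- pos$mass
    pos <- pos$pos
  }
  if (is.null(mass)) mass <- rep(1, nrow(pos))
  cm <- colSums(pos * mass) / sum(mass)
  sqrt(sum(mass * rowSums(sweep(pos, 2, cm)^2)) / sum(mass))
}

#' End-to-end distance
#'
#' Distance between the first and last *residue* beads: terminal charge
#' beads (labels NTERM/CTERM) are excluded when a [bead_model()] is given.
#'
#' @param pos Configuration or [bead_model()].
#' @param model Optional model carrying labels when `pos` is a matrix.
#' @return Ree in Angstrom.
#' @export
end_to_end <- function(pos, model = NULL) {
  lab <- NULL
  if (inherits(pos, "bead_model")) { lab <- pos$label; pos <- pos$pos }
  else if (!is.null(model)) lab <- model$label
  idx <- seq_len(nrow(pos))
  if (!is.null(lab)) idx <- idx[!lab %in% c("NTERM", "CTERM")]
  sqrt(sum((pos[idx[length(idx)], ] - pos[idx[1], ])^2))
}

#' Shape factor Ree^2 / Rg^2
#'
#' 6 for a Gaussian (ideal) chain, 12 for a rigid rod in the large-N
#' limit; a straight chain of N equally spaced beads gives exactly
#' 12 (N - 1) / (N + 1).
#'
#' @param pos Configuration or [bead_model()].
#' @param mass Optional masses.
#' @param model Optional model carrying labels when `pos` is a matrix.
#' @return Dimensionless shape factor.
#' @export
shape_factor <- function(pos, mass = NULL, model = NULL) {
  end_to_end(pos, model)^2 / rg(pos, mass)^2
}

#' Cosine distribution over a sample set
#'
#' Histogram of the orientation cosine (to the surface normal, or to the
#' nanoparticle direction if the layout is a single nanoparticle) over the
#' adsorbed snapshots.
#'
#' @param samples A `sample_set`.
#' @param bin_width Cosine bin width (default 0.02).
#' @param adsorbed_only Restrict to adsorbed snapshots (default TRUE).
#' @param cutoff Adsorption cutoff passed to [adsorbed_fraction()].
#' @return A [new_profile()] with `probability` normalization (bin
#'   probabilities summing to 1).
#' @export
cosine_distribution <- function(samples, bin_width = 0.02,
                                adsorbed_only = TRUE, cutoff = NULL) {
  sys <- samples$sys
  keep <- if (adsorbed_only) adsorbed_fraction(samples, cutoff)$flags else
    rep(TRUE, length(samples$positions))
  if (!any(keep)) stop("no adsorbed snapshots to analyze")
  single_np <- sys$layout$kind == "single_np"
  np <- if (single_np) sys$layout$nanoparticles[1, ] else NULL
  cosv <- vapply(samples$positions[keep], function(p) {
    if (single_np) cos_to_np(p, np, sys$mass, sys$layout$cell)
    else cos_to_surface_normal(p, sys$mass)
  }, numeric(1))
  edges <- seq(0, 1, by = bin_width)
  if (max(edges) < 1) edges <- c(edges, 1)
  counts <- graphics::hist(cosv, breaks = edges, plot = FALSE)$counts
  new_profile(edges, counts / sum(counts), "probability",
              n_samples = sum(keep))
}

#' Block-averaged mean and standard error
#'
#' Splits a correlated series into `n_blocks` contiguous blocks and
#' reports the mean and the standard error of the block means.
#'
#' @param x Numeric series.
#' @param n_blocks Number of blocks (default 10).
#' @return List with `mean`, `se`, `n_blocks`.
#' @export
block_average <- function(x, n_blocks = 10) {
  n <- length(x)
  n_blocks <- max(2L, min(n_blocks, n))
  idx <- cut(seq_len(n), n_blocks, labels = FALSE)
  bm <- tapply(x, idx, mean)
  list(mean = mean(x), se = stats::sd(bm) / sqrt(length(bm)),
       n_blocks = length(bm))
}
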