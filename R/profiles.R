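# Binned observables: generic profile container plus the longitudinal
# structure-characterization profiles.

#' Construct a binned profile
#'
#' Shared container for every binned observable in the package: free-energy
#' profiles, cosine distributions, radial distribution functions, and
#' per-bin charge or hydrophobicity counts.
#'
#' @param edges Bin edges (length `length(values) + 1`).
#' @param values Per-bin values (NA for empty/masked bins).
#' @param normalization One of `"probability"`, `"free_energy_kBT"`,
#'   `"g_of_r"`, `"raw_count"`.
#' @param n_samples Number of samples the profile was built from.
#' @param stderr Optional per-bin standard errors.
#' @return An object of class `cg_profile`.
#' @export
new_profile <- function(edges, values, normalization = "raw_count",
                        n_samples = NA_integer_, stderr = NULL) {
  stopifnot(length(edges) == length(values) + 1)
  normalization <- match.arg(normalization,
    c("probability", "free_energy_kBT", "g_of_r", "raw_count"))
  x <- list(edges = as.numeric(edges), values = as.numeric(values),
            normalization = normalization, n_samples = n_samples,
            stderr = stderr)
  class(x) <- "cg_profile"
  x
}

#' @export
print.cg_profile <- function(x, ...) {
  cat(sprintf("Profile (%s): %d bins over [%g, %g], n = %s\n",
              x$normalization, length(x$values), min(x$edges), max(x$edges),
              format(x$n_samples)))
  invisible(x)
}

#' @export
as.data.frame.cg_profile <- function(x, ...) {
  nb <- length(x$values)
  data.frame(bin_left = x$edges[-(nb + 1)], bin_right = x$edges[-1],
             value = x$values,
             stderr = if (is.null(x$stderr)) NA_real_ else x$stderr)
}

#' Bin centers of a profile
#' @param x A [new_profile()] object.
#' @return Numeric vector of bin midpoints.
#' @export
profile_midpoints <- function(x) (x$edges[-1] + x$edges[-length(x$edges)]) / 2

#' Principal (longitudinal) axis of a configuration
#'
#' Eigenvector of the mass-weighted gyration tensor with the largest
#' eigenvalue, with the sign chosen so the z-component is non-negative
#' (falling back to the first non-zero component for in-plane axes). For a
#' rod-like body this is the rod direction.
#'
#' @param pos N x 3 position matrix or a [bead_model()].
#' @param mass Optional masses.
#' @param tol Relative eigenvalue gap below which the axis is declared
#'   degenerate (sphere-like body) and an error is raised.
#' @return Unit length-3 vector.
#' @export
principal_axis <- function(pos, mass = NULL, tol = 1e-8) {
  if (inherits(pos, "bead_model")) {
    if (is.null(mass)) mass <- pos$mass
    pos <- pos$pos
  }
  if (is.null(mass)) mass <- rep(1, nrow(pos))
  cm <- colSums(pos * mass) / sum(mass)
  pc <- sweep(pos, 2, cm)
  S <- crossprod(pc, pc * mass) / sum(mass)
  eg <- eigen(S, symmetric = TRUE)
  if ((eg$values[1] - eg$values[2]) <= tol * max(eg$values[1], .Machine$double.eps))
    stop("degenerate top eigenvalues: principal axis undefined for this body")
  v <- eg$vectors[, 1]
  pivot <- if (abs(v[3]) > 1e-12) v[3] else v[which(abs(v) > 1e-12)[1]]
  if (pivot < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Longitudinal per-bin charge or hydrophobicity profile
#'
#' Projects all beads onto the model's principal axis and splits the span
#' between the extreme projections into `n_bins` equal-width bins. Returns
#' the per-bin summed charge or the per-bin count of hydrophobic residues
#' (Ala, Gly, Ile, Leu, Met, Phe, Pro, Val). The charge profile sums to the
#' model's net charge for any bin count.
#'
#' @param model A [bead_model()] with charges assigned.
#' @param n_bins Number of bins (default 20).
#' @param property `"charge"` or `"hydrophobic_count"`.
#' @return A [new_profile()] with `raw_count` normalization; edges are in
#'   Angstrom along the principal axis (origin at the low extreme).
#' @export
longitudinal_profile <- function(model, n_bins = 20,
                                 property = c("charge", "hydrophobic_count")) {
  property <- match.arg(property)
  if (n_bins < 1) stop("n_bins must be >= 1")
  if (n_beads(model) < n_bins)
    stop("model must have at least n_bins beads")
  axis <- principal_axis(model)
  proj <- drop(model$pos %*% axis)
  proj <- proj - min(proj)
  edges <- seq(0, max(proj), length.out = n_bins + 1)
  idx <- pmin(findInterval(proj, edges, rightmost.closed = TRUE), n_bins)
  w <- if (property == "charge") model$charge else
    as.numeric(model$label %in% .hydrophobic_set)
  vals <- vapply(seq_len(n_bins), function(b) sum(w[idx == b]), numeric(1))
  new_profile(edges, vals, "raw_count", n_samples = n_beads(model))
}

#' Longitudinal profile of the hydrophobic fraction of the solvent-
#' accessible surface
#'
#' Computes per-residue relative solvent accessibility with the
#' Shrake-Rupley algorithm on heavy atoms (960 points per atom, probe
#' 1.4 Angstrom, Bondi radii), normalized by the residue's maximum
#' accessibility in an extended Gly-X-Gly reference (Tien et al. values).
#' Residues at or above the threshold count as surface-accessible; the
#' profile reports, per longitudinal bin, the fraction of accessible
#' residues that are hydrophobic. Bins without accessible residues are NA.
#'
#' @param records A [load_structure()] result with atomistic coordinates.
#' @param rel_sasa_threshold Relative accessibility threshold (default 0.20).
#' @param n_bins Number of longitudinal bins (default 20).
#' @param exclude_chains Chains to drop.
#' @return A [new_profile()]; values are fractions in `[0, 1]` or NA.
#' @export
hydrophobic_surface_fraction <- function(records, rel_sasa_threshold = 0.20,
                                         n_bins = 20, exclude_chains = NULL) {
  atoms <- records$atoms
  atoms <- atoms[!atoms$is_ion & !atoms$chain %in% exclude_chains, ,
                 drop = FALSE]
  atoms <- atoms[atoms$element %in% names(.vdw_radius), , drop = FALSE]
  if (!nrow(atoms)) stop("no heavy atoms with coordinates")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  area <- shrake_rupley(xyz, atoms$element)

  key <- paste(atoms$chain, atoms$resno)
  res_sasa <- tapply(area, key, sum)
  res_name <- tapply(atoms$resid, key, function(v) v[1])
  keep <- res_name %in% names(.max_sasa)
  if (any(!keep))
    warning("skipping residues without reference accessibility: ",
            paste(unique(res_name[!keep]), collapse = ", "))
  rel <- res_sasa[keep] / .max_sasa[res_name[keep]]
  accessible <- rel >= rel_sasa_threshold
  hydro <- res_name[keep] %in% .hydrophobic_set

  ## residue positions (C-alpha, falling back to the residue centroid)
  res_keys <- names(res_sasa)[keep]
  rp <- t(vapply(res_keys, function(k) {
    sel <- key == k
    ca <- sel & atoms$elety == "CA"
    if (any(ca)) as.numeric(atoms[which(ca)[1], c("x", "y", "z")])
    else colMeans(xyz[sel, , drop = FALSE])
  }, numeric(3)))

  axis <- principal_axis(rp)
  proj <- drop(rp %*% axis); proj <- proj - min(proj)
  edges <- seq(0, max(proj), length.out = n_bins + 1)
  idx <- pmin(findInterval(proj, edges, rightmost.closed = TRUE), n_bins)
  vals <- vapply(seq_len(n_bins), function(b) {
    acc <- accessible & idx == b
    if (!any(acc)) NA_real_ else mean(hydro[acc])
  }, numeric(1))
  new_profile(edges, vals, "raw_count", n_samples = length(res_keys))
}
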