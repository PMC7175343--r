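#' Coarse-grained bead model
#'
#' An ordered set of spherical beads, each with a position, radius, point
#' charge (at the sphere center), mass and label, plus an optional bond
#' topology. Rigid bodies (one bead per resolved residue of a crystal
#' structure) have no bonds and their internal geometry is never altered;
#' flexible chains bond consecutive beads.
#'
#' @param pos Numeric N x 3 matrix of bead centers (Angstrom).
#' @param radius Bead radii (Angstrom), recycled to N.
#' @param charge Bead point charges (elementary charges), recycled.
#' @param mass Bead masses (Da), recycled.
#' @param label Bead labels: 3-letter residue codes, ion species, or
#'   `"NTERM"`/`"CTERM"` for terminal charge beads.
#' @param bonds Integer M x 2 matrix of bonded bead index pairs, or NULL.
#' @param rigid Logical; rigid bodies must have no bonds.
#' @param chain Optional per-bead chain identifier.
#' @return An object of class `bead_model`.
#' @export
#' @examples
#' rod <- bead_model(cbind(0, 0, seq(0, 20, by = 5)), radius = 2.5)
#' n_beads(rod)
bead_model <- function(pos, radius = 2.5, charge = 0, mass = 1,
                       label = "UNK", bonds = NULL, rigid = is.null(bonds),
                       chain = NULL) {
  pos <- as.matrix(pos)
  if (ncol(pos) != 3) stop("pos must be an N x 3 matrix")
  storage.mode(pos) <- "double"
  dimnames(pos) <- list(NULL, c("x", "y", "z"))
  n <- nrow(pos)
  m <- list(
    pos = pos,
    radius = rep_len(as.numeric(radius), n),
    charge = rep_len(as.numeric(charge), n),
    mass = rep_len(as.numeric(mass), n),
    label = rep_len(as.character(label), n),
    bonds = if (is.null(bonds)) matrix(integer(0), 0, 2) else {
      b <- as.matrix(bonds); storage.mode(b) <- "integer"; b
    },
    rigid = isTRUE(rigid),
    chain = if (is.null(chain)) rep_len(NA_character_, n) else
      rep_len(as.character(chain), n)
  )
  class(m) <- "bead_model"
  validate_bead_model(m)
}

#' Validate a bead model's invariants
#'
#' Checks that radii are positive, that rigid bodies carry no bonds, and
#' that in a flexible chain every interior bead has exactly two bonds.
#'
#' @param m A [bead_model()].
#' @return `m`, invisibly usable, after passing all checks.
#' @export
validate_bead_model <- function(m) {
  if (any(m$radius <= 0)) stop("all bead radii must be > 0")
  if (m$rigid && nrow(m$bonds) > 0) stop("rigid models must have no bonds")
  if (nrow(m$bonds) > 0) {
    if (any(m$bonds < 1L | m$bonds > n_beads(m)))
      stop("bond indices out of range")
    deg <- tabulate(c(m$bonds), nbins = n_beads(m))
    if (any(deg > 2)) stop("chain beads may have at most 2 bonds")
  }
  m
}

#' Number of beads in a model
#' @param m A [bead_model()].
#' @return Integer bead count.
#' @export
n_beads <- function(m) nrow(m$pos)

#' Net charge of a bead model
#'
#' Sum of all bead point charges, in elementary charges.
#'
#' @param m A [bead_model()].
#' @return Signed numeric net charge.
#' @export
#' @examples
#' m <- bead_model(diag(3), charge = c(1, -1, 2))
#' net_charge(m) # 2
net_charge <- function(m) sum(m$charge)

#' Center of mass of a configuration
#'
#' @param pos N x 3 position matrix (or a [bead_model()], using its positions).
#' @param mass Optional masses; defaults to the model's masses or unit mass.
#' @return Numeric length-3 vector.
#' @export
center_of_mass <- function(pos, mass = NULL) {
  if (inherits(pos, "bead_model")) {
    if (is.null(mass)) mass <- pos$mass
    pos <- pos$pos
  }
  if (is.null(mass)) mass <- rep(1, nrow(pos))
  colSums(pos * mass) / sum(mass)
}

#' Maximum pairwise bead separation
#'
#' The largest center-to-center distance between any two beads; a measure of
#' the model's longest dimension (about 450 Angstrom for the fibrinogen
#' main body).
#'
#' @param m A [bead_model()] or an N x 3 position matrix.
#' @return Distance in Angstrom.
#' @export
max_extent <- function(m) {
  pos <- if (inherits(m, "bead_model")) m$pos else as.matrix(m)
  if (nrow(pos) < 2) return(0)
  ## extremes lie on the convex hull along the principal axis for rods, but
  ## we keep the exact O(N^2) answer; N is at most a few thousand here
  max(stats::dist(pos))
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("Coarse-grained bead model: %d beads (%s), net charge %+g e\n",
              n_beads(x), if (x$rigid) "rigid" else
                sprintf("flexible, %d bonds", nrow(x$bonds)),
              net_charge(x)))
  tab <- sort(table(x$label), decreasing = TRUE)
  cat("  labels:", paste(sprintf("%s:%d", names(tab)[seq_len(min(8, length(tab)))],
                                 tab[seq_len(min(8, length(tab)))]),
                         collapse = " "),
      if (length(tab) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
as.data.frame.bead_model <- function(x, ...) {
  data.frame(index = seq_len(n_beads(x)), label = x$label, chain = x$chain,
             x = x$pos[, 1], y = x$pos[, 2], z = x$pos[, 3],
             radius = x$radius, charge = x$charge, mass = x$mass,
             stringsAsFactors = FALSE)
}

#' Replace the configuration of a bead model
#'
#' @param m A [bead_model()].
#' @param pos New N x 3 position matrix (same bead count).
#' @return The model with updated positions.
#' @export
set_positions <- function(m, pos) {
  pos <- as.matrix(pos)
  stopifnot(nrow(pos) == n_beads(m), ncol(pos) == 3)
  dimnames(pos) <- dimnames(m$pos)
  m$pos <- pos
  m
}
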