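# The simulated system: bead model + solution conditions + surface layout,
# with cached parameter vectors for fast energy evaluation.

#' Assemble a simulation system
#'
#' Combines a bead model, solution conditions and a surface layout into one
#' object, pre-computing the screening constant, Bjerrum length and surface
#' potential. Energy terms: every bead interacts with the Gouy-Chapman wall
#' (if present) and with each nanoparticle's central charge via the
#' size-corrected screened Coulomb pair potential. Flexible chains add
#' harmonic bonds plus screened Coulomb and Lennard-Jones terms between
#' non-bonded bead pairs (nearest bonded neighbors excluded). Rigid bodies
#' have no intramolecular terms. Hard cores (bead-bead, bead-wall,
#' bead-nanoparticle, ceiling, confinement shell) give +Inf.
#'
#' @param model A [bead_model()] with charges assigned.
#' @param layout A `surface_layout`.
#' @param conditions A [solution_conditions()].
#' @param bond A [bond_spec()] (flexible chains).
#' @param pair A [pair_params()] (flexible chains).
#' @param use_dh,use_lj Enable intramolecular screened-Coulomb /
#'   Lennard-Jones terms in chains (disable both for ideal-chain reference
#'   runs).
#' @param hard_core Enforce hard-sphere exclusion (disable for ideal
#'   chains).
#' @param cutoff Optional interaction cutoff in Angstrom (default Inf:
#'   no cutoff).
#' @return An object of class `cg_system`.
#' @export
cg_system <- function(model, layout, conditions = solution_conditions(),
                      bond = bond_spec(), pair = pair_params(),
                      use_dh = TRUE, use_lj = !model$rigid,
                      hard_core = TRUE, cutoff = Inf) {
  field <- if (layout$wall) surface_field(layout$rho, conditions) else NULL
  nps <- layout$nanoparticles
  sys <- list(
    model = model, layout = layout, conditions = conditions,
    bond = bond, pair = pair,
    use_dh = use_dh, use_lj = use_lj, hard_core = hard_core,
    cutoff = cutoff,
    kappa = 1 / debye_length(conditions),
    lB = bjerrum_length(conditions),
    gamma0 = if (is.null(field)) 0 else field$gamma0,
    wall = layout$wall,
    Lx = layout$cell$Lx, Ly = layout$cell$Ly, Lz = layout$cell$Lz,
    shell_outer = layout$shell_outer,
    np_x = nps$x, np_y = nps$y, np_z = nps$z,
    np_R = nps$radius, np_Z = nps$charge,
    q = model$charge, rad = model$radius, mass = model$mass
  )
  class(sys) <- "cg_system"
  sys
}

#' @export
print.cg_system <- function(x, ...) {
  cat(sprintf("cg_system: %d beads (%s) on layout '%s'\n",
              n_beads(x$model), if (x$model$rigid) "rigid" else "flexible",
              x$layout$kind))
  cat(sprintf("  kappa^-1 = %.2f A, lB = %.2f A, Gamma0 = %.3f\n",
              1 / x$kappa, x$lB, x$gamma0))
  invisible(x)
}

## External (wall + nanoparticle) energy of the beads in `idx` (NULL = all),
## given full configuration `pos`. Returns a scalar, possibly +Inf.
## Hot path: fields localized once, no which()/sweep allocations.
.ext_energy <- function(sys, pos, idx = NULL) {
  rad <- sys$rad; q <- sys$q
  if (!is.null(idx) && length(idx) < nrow(pos)) {
    pos <- pos[idx, , drop = FALSE]; rad <- rad[idx]; q <- q[idx]
  }
  hard <- sys$hard_core
  kappa <- sys$kappa
  cutoff <- sys$cutoff
  E <- 0
  z <- pos[, 3]
  if (sys$wall) {
    if (hard && (min(z - rad) < 0 || max(z + rad) > sys$Lz)) return(Inf)
    g0 <- sys$gamma0
    if (g0 != 0) {
      gz <- g0 * exp(-kappa * z)
      w <- 2 * q * log((1 + gz) / (1 - gz))
      if (is.finite(cutoff)) w[z > cutoff] <- 0
      E <- sum(w)
    }
  }
  npR <- sys$np_R
  if (length(npR)) {
    lB <- sys$lB; Lx <- sys$Lx; Ly <- sys$Ly
    npx <- sys$np_x; npy <- sys$np_y; npz <- sys$np_z; npZ <- sys$np_Z
    x <- pos[, 1]; y <- pos[, 2]
    for (j in seq_along(npR)) {
      dx <- x - npx[j]; dx <- dx - Lx * round(dx / Lx)
      dy <- y - npy[j]; dy <- dy - Ly * round(dy / Ly)
      dz <- z - npz[j]
      sig <- npR[j] + rad
      r2 <- dx * dx + dy * dy + dz * dz
      if (hard && any(r2 < sig * sig)) return(Inf)
      if (npZ[j] != 0) {
        r <- sqrt(r2)
        w <- (lB * npZ[j]) * q * exp(-kappa * (r - sig)) /
          (r * (1 + kappa * sig))
        if (is.finite(cutoff)) w[r - sig > cutoff] <- 0
        E <- E + sum(w)
      }
    }
  }
  E
}

## confinement shell (single free nanoparticle): center-of-mass constraint
.shell_violation <- function(sys, pos) {
  if (is.na(sys$shell_outer)) return(FALSE)
  cm <- colSums(pos * sys$mass) / sum(sys$mass)
  ctr <- c(sys$np_x[1], sys$np_y[1], sys$np_z[1])
  sum((cm - ctr)^2) > sys$shell_outer^2
}

## Non-bonded (DH + LJ) energy between bead sets A and B of a linear chain.
## Nearest bonded neighbors (|i - j| == 1) are excluded. Scalar, may be Inf.
.nb_pair_sum <- function(sys, pos, idxA, idxB) {
  if (!length(idxA) || !length(idxB)) return(0)
  pA <- pos[idxA, , drop = FALSE]; pB <- pos[idxB, , drop = FALSE]
  dx <- outer(pA[, 1], pB[, 1], "-"); dx <- dx - sys$Lx * round(dx / sys$Lx)
  dy <- outer(pA[, 2], pB[, 2], "-"); dy <- dy - sys$Ly * round(dy / sys$Ly)
  dz <- outer(pA[, 3], pB[, 3], "-")
  r2 <- dx * dx + dy * dy + dz * dz
  keep <- abs(outer(idxA, idxB, "-")) > 1L  # exclude self/bonded neighbors
  sig <- outer(sys$rad[idxA], sys$rad[idxB], "+")
  if (sys$hard_core && any(r2[keep] < (sig * sig)[keep])) return(Inf)
  E <- 0
  r <- sqrt(r2)
  if (sys$use_dh) {
    qq <- outer(sys$q[idxA], sys$q[idxB])
    m <- keep & qq != 0
    if (any(m)) {
      w <- sys$lB * qq[m] * exp(-sys$kappa * (r[m] - sig[m])) /
        (r[m] * (1 + sys$kappa * sig[m]))
      if (is.finite(sys$cutoff)) w[(r[m] - sig[m]) > sys$cutoff] <- 0
      E <- E + sum(w)
    }
  }
  if (sys$use_lj) {
    sr6 <- (sig[keep] / r[keep])^6
    E <- E + sum(4 * sys$pair$eps_nb * (sr6 * sr6 - sr6))
  }
  E
}

## total bonded energy for bonds with at least one end in `moved`
## (or all bonds if `moved` is NULL)
.bond_sum <- function(sys, pos, moved = NULL) {
  b <- sys$model$bonds
  if (!nrow(b)) return(0)
  if (!is.null(moved)) {
    inv <- logical(nrow(pos)); inv[moved] <- TRUE
    b <- b[inv[b[, 1]] | inv[b[, 2]], , drop = FALSE]
    if (!nrow(b)) return(0)
  }
  d <- pos[b[, 1], , drop = FALSE] - pos[b[, 2], , drop = FALSE]
  sum(bond_energy(sqrt(rowSums(d * d)), sys$bond))
}

#' Total potential energy of a configuration
#'
#' Sum of all energy terms for the given configuration: Gouy-Chapman wall
#' terms, nanoparticle screened-Coulomb terms and hard-core checks for
#' every bead; plus, for flexible chains, harmonic bonds and non-bonded
#' screened-Coulomb + Lennard-Jones pair terms. xy minimum image
#' throughout; +Inf propagates from any hard-core violation.
#'
#' @param sys A [cg_system()].
#' @param pos Configuration (defaults to the model's positions).
#' @return Energy in kBT (possibly +Inf).
#' @export
total_energy <- function(sys, pos = sys$model$pos) {
  if (.shell_violation(sys, pos)) return(Inf)
  E <- .ext_energy(sys, pos)
  if (!is.finite(E)) return(Inf)
  if (!sys$model$rigid) {
    E <- E + .bond_sum(sys, pos)
    n <- nrow(pos)
    if (n > 1 && (sys$use_dh || sys$use_lj || sys$hard_core)) {
      ## accumulate the strict upper triangle in row blocks
      for (i in seq_len(n - 1)) {
        Ei <- .nb_pair_sum(sys, pos, i, (i + 1):n)
        if (!is.finite(Ei)) return(Inf)
        E <- E + Ei
      }
    }
  }
  E
}

## Energy difference for a trial move of bead set `moved`. Relies on chain
## moves being rigid-segment transformations (distances within the moved
## set unchanged), which holds for all move types in this package; the
## periodic full recompute in mc_run() guards the bookkeeping.
.delta_energy <- function(sys, pos_old, pos_new, moved, ext_old = NULL) {
  if (.shell_violation(sys, pos_new)) return(Inf)
  En <- .ext_energy(sys, pos_new, moved)
  if (!is.finite(En)) return(Inf)
  dE <- En - (if (is.null(ext_old)) .ext_energy(sys, pos_old, moved) else
    ext_old)
  if (!sys$model$rigid) {
    n <- nrow(pos_old)
    rest <- setdiff(seq_len(n), moved)
    if (sys$use_dh || sys$use_lj || sys$hard_core) {
      Enb <- .nb_pair_sum(sys, pos_new, moved, rest)
      if (!is.finite(Enb)) return(Inf)
      dE <- dE + Enb - .nb_pair_sum(sys, pos_old, moved, rest)
    }
    dE <- dE + .bond_sum(sys, pos_new, moved) - .bond_sum(sys, pos_old, moved)
  }
  dE
}
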