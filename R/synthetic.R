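# Synthetic structures and reference systems: freely-jointed chains,
# charged model rods, toy PDB fixtures and a two-state sampler toy.
# All generators are deterministic given their seed and arguments.

#' Freely-jointed (ideal) chain configuration
#'
#' N beads connected by fixed-length bonds with directions uniform on the
#' sphere: the classic ideal-chain reference with <Ree^2> = (N-1) b^2 and
#' shape-factor ratio <Ree^2>/<Rg^2> -> 6 for large N.
#'
#' @param n_beads Number of beads (>= 2).
#' @param bond_length Bond length b, Angstrom (default 4.1).
#' @param seed Optional RNG seed (uses the current RNG state if NULL).
#' @return N x 3 position matrix.
#' @export
#' @examples
#' ch <- make_ideal_chain(100, seed = 1)
#' shape_factor(ch)
make_ideal_chain <- function(n_beads, bond_length = 4.1, seed = NULL) {
  stopifnot(n_beads >= 2)
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(stats::rnorm(3 * (n_beads - 1)), ncol = 3)
  v <- v / sqrt(rowSums(v * v))
  pos <- rbind(0, apply(v * bond_length, 2, cumsum))
  dimnames(pos) <- list(NULL, c("x", "y", "z"))
  pos
}

#' Specification of a charged rigid rod
#'
#' Collinear beads at fixed spacing with a longitudinal charge pattern
#' given as consecutive segments: each segment is a fraction of the chain
#' with one per-bead charge. Fractions must partition `[0, 1]`.
#'
#' @param n_beads Number of beads.
#' @param spacing Center-to-center bead spacing, Angstrom.
#' @param pattern data.frame with columns `fraction` and `charge`.
#' @param radius Bead radius, Angstrom (default 2.5).
#' @return Object of class `rod_spec`.
#' @export
rod_spec <- function(n_beads, spacing, pattern, radius = 2.5) {
  stopifnot(n_beads >= 1, spacing > 0,
            all(c("fraction", "charge") %in% names(pattern)))
  if (abs(sum(pattern$fraction) - 1) > 1e-9)
    stop("pattern fractions must sum to 1")
  structure(list(n_beads = n_beads, spacing = spacing,
                 pattern = pattern, radius = radius), class = "rod_spec")
}

#' Build a charged rigid rod
#'
#' Collinear beads along +z with the per-segment charges of the spec.
#' Segment boundaries are placed at the cumulative fractions of the bead
#' count (rounded); every bead belongs to exactly one segment.
#'
#' @param spec A [rod_spec()].
#' @return A rigid [bead_model()] centered at the origin along z.
#' @export
make_charged_rod <- function(spec) {
  n <- spec$n_beads
  bounds <- round(cumsum(spec$pattern$fraction) * n)
  bounds[length(bounds)] <- n
  q <- numeric(n)
  lo <- 1L
  for (k in seq_len(nrow(spec$pattern))) {
    hi <- bounds[k]
    if (hi >= lo) q[lo:hi] <- spec$pattern$charge[k]
    lo <- hi + 1L
  }
  z <- (seq_len(n) - (n + 1) / 2) * spec$spacing
  bead_model(cbind(0, 0, z), radius = spec$radius, charge = q,
             mass = mean(.residue_mass), label = "ROD", rigid = TRUE)
}

#' Fibrinogen-mimic charged rod
#'
#' A 450-Angstrom rigid rod (90 beads at 5 Angstrom spacing by default)
#' emulating the longitudinal charge architecture of the fibrinogen main
#' body: each end region is charge-rich but near-neutral, with the
#' positive charges at the outermost tip and the compensating negative
#' charges further inboard, and the long middle carries a distributed net
#' charge of -8, giving the molecule's overall net charge of -8. The
#' positive tips make end-on attachment to negatively charged surfaces
#' favorable while the net-negative body is repelled, the mechanism behind
#' the curvature-dependent orientation of the adsorbed molecule. This is a
#' synthetic stand-in: beads are uniform, so the thickness variation of
#' the real molecule (D and E domains) is not represented.
#'
#' @param n_beads Number of beads (default 90).
#' @param spacing Bead spacing, Angstrom (default 5).
#' @return A rigid [bead_model()] with net charge -8.
#' @export
#' @examples
#' rod <- fibrinogen_mimic_rod()
#' net_charge(rod) # -8
fibrinogen_mimic_rod <- function(n_beads = 90, spacing = 5) {
  n <- n_beads
  stopifnot(n >= 40)
  q <- numeric(n)
  t_ <- max(2L, round(n / 18))          # positive tip block
  g_ <- max(1L, round(n / 30))          # neutral gap
  q[1:t_] <- +1
  q[(t_ + g_ + 1):(2 * t_ + g_)] <- -1  # compensating block, net-0 end
  q[(n - t_ + 1):n] <- +1
  q[(n - 2 * t_ - g_ + 1):(n - t_ - g_)] <- -1
  mid <- round(seq(0.22 * n, 0.78 * n, length.out = 8))
  q[mid] <- q[mid] - 1                  # distributed middle charge, net -8
  z <- (seq_len(n) - (n + 1) / 2) * spacing
  bead_model(cbind(0, 0, z), radius = 2.5, charge = q,
             mass = mean(.residue_mass), label = "ROD", rigid = TRUE)
}

#' Toy PDB fixture text
#'
#' Generates a small, well-formed PDB file for exercising the structure
#' pipeline: one or more chains with SEQRES records, backbone heavy atoms
#' (N, CA, C, O) for the resolved residues, optional unresolved residues
#' (present in SEQRES only), optional hetero ions, TER records and element
#' columns. Coordinates follow a gently curved extended trace, distinct
#' per chain.
#'
#' @param chains Named list; each element is a list with `sequence`
#'   (one-letter string) and optional `unresolved` (integer positions in
#'   the sequence that get no coordinates).
#' @param ions Optional data.frame with columns `resid` (e.g. "CA"), `x`,
#'   `y`, `z`.
#' @return A single string of PDB text (parseable by [load_structure()]).
#' @export
#' @examples
#' txt <- make_toy_pdb(list(A = list(sequence = "DKE")))
#' rec <- load_structure(txt)
make_toy_pdb <- function(chains = list(A = list(sequence = "DKEAG",
                                                unresolved = 5L)),
                         ions = NULL) {
  lines <- c("HEADER    SYNTHETIC FIXTURE")
  ## SEQRES
  for (ch in names(chains)) {
    codes <- .seq_to_codes(chains[[ch]]$sequence)
    n <- length(codes)
    rows <- split(codes, ceiling(seq_along(codes) / 13))
    for (k in seq_along(rows))
      lines <- c(lines, sprintf("SEQRES %3d %s %4d  %s", k, ch, n,
                                paste(rows[[k]], collapse = " ")))
  }
  serial <- 0L
  fmt_atom <- function(rec, name, resid, ch, resno, p, elem) {
    serial <<- serial + 1L
    sprintf("%-6s%5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial, name, resid, ch, resno, p[1], p[2], p[3],
            1.00, 10.00, elem)
  }
  chain_offset <- 0
  for (ch in names(chains)) {
    codes <- .seq_to_codes(chains[[ch]]$sequence)
    unres <- chains[[ch]]$unresolved
    for (i in seq_along(codes)) {
      if (i %in% unres) next
      ## gently curved trace, 3.8 A steps, chains stacked 20 A apart in y
      ca <- c(3.8 * i + 0.3 * sin(i), chain_offset + 0.4 * cos(i),
              1.5 * sin(i / 3))
      lines <- c(lines,
        fmt_atom("ATOM", "N", codes[i], ch, i, ca + c(-1.2, 0.4, 0.3), "N"),
        fmt_atom("ATOM", "CA", codes[i], ch, i, ca, "C"),
        fmt_atom("ATOM", "C", codes[i], ch, i, ca + c(1.2, 0.5, -0.2), "C"),
        fmt_atom("ATOM", "O", codes[i], ch, i, ca + c(1.4, 1.6, -0.4), "O"))
    }
    lines <- c(lines, "TER")
    chain_offset <- chain_offset + 20
  }
  if (!is.null(ions)) {
    for (k in seq_len(nrow(ions))) {
      lines <- c(lines, fmt_atom("HETATM", ions$resid[k], ions$resid[k], "Z",
                                 900 + k,
                                 c(ions$x[k], ions$y[k], ions$z[k]),
                                 ions$resid[k]))
    }
  }
  paste(c(lines, "END"), collapse = "\n")
}

#' Two-state sampler toy
#'
#' One bead hopping between two discrete sites with a fixed energy gap:
#' the minimal system with a known Boltzmann distribution, used to
#' validate the Metropolis acceptance rule. Occupancies are
#' `1 / (1 + exp(-gap))` for the ground state.
#'
#' @param gap Energy gap in kBT (default 1).
#' @return Object of class `two_state_toy`.
#' @export
make_two_state_toy <- function(gap = 1) {
  structure(list(energies = c(0, gap),
                 sites = rbind(c(0, 0, 0), c(10, 0, 0))),
            class = "two_state_toy")
}

#' Sample a two-state toy with Metropolis Monte Carlo
#'
#' Proposes a hop to the other site at every step and applies
#' [metropolis_accept()].
#'
#' @param toy A [make_two_state_toy()].
#' @param n_steps Number of attempted hops.
#' @param seed RNG seed.
#' @return Integer vector of visited states (1 = ground state).
#' @export
#' @examples
#' s <- sample_two_state(make_two_state_toy(1), 2000, seed = 1)
#' mean(s == 1) # about 1 / (1 + exp(-1)) = 0.731
sample_two_state <- function(toy, n_steps, seed = 1) {
  set.seed(seed)
  draws <- stats::runif(n_steps)
  out <- integer(n_steps)
  s <- 1L
  E <- toy$energies
  for (k in seq_len(n_steps)) {
    other <- 3L - s
    dE <- E[other] - E[s]
    if (dE <= 0 || (is.finite(dE) && draws[k] < exp(-dE))) s <- other
    out[k] <- s
  }
  out
}
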