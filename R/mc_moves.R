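# Monte Carlo trial moves. All proposals are symmetric, as required for
# Metropolis sampling with acceptance min(1, exp(-dE)).

#' Metropolis acceptance rule
#'
#' Accept iff `draw < min(1, exp(-dE))` with dE in kBT; an infinite energy
#' change is always rejected.
#'
#' @param dE Energy change in kBT.
#' @param draw Uniform(0,1) random number (drawn from the session RNG by
#'   default).
#' @return Logical.
#' @export
#' @examples
#' metropolis_accept(-3, 0.999) # TRUE: downhill moves always accepted
metropolis_accept <- function(dE, draw = stats::runif(1)) {
  if (!is.finite(dE)) return(dE < 0)   # +Inf rejected, -Inf accepted
  if (dE <= 0) return(TRUE)
  draw < exp(-dE)
}

#' Move specification
#'
#' @param type One of `"rigid_translate"`, `"rigid_rotate"`,
#'   `"crankshaft"`, `"pivot"`, `"bead_translate"`.
#' @param step Maximum displacement (Angstrom) for translations or maximum
#'   rotation angle (rad) for rotations.
#' @param weight Relative selection weight (> 0).
#' @return Object of class `move_spec`.
#' @export
move_spec <- function(type, step, weight = 1) {
  type <- match.arg(type, c("rigid_translate", "rigid_rotate", "crankshaft",
                            "pivot", "bead_translate"))
  stopifnot(step >= 0, weight > 0)
  structure(list(type = type, step = step, weight = weight),
            class = "move_spec")
}

#' Default move set for a system
#'
#' Rigid bodies: whole-body translation (5 Angstrom) and rotation about
#' the center of mass (0.3 rad), equal weights. Flexible chains:
#' crankshaft (1 rad), pivot (1 rad) and single-bead translation
#' (2 Angstrom), equal weights.
#'
#' @param sys A [cg_system()] (or a [bead_model()]).
#' @return List of [move_spec()]s.
#' @export
default_moves <- function(sys) {
  model <- if (inherits(sys, "cg_system")) sys$model else sys
  if (model$rigid)
    list(move_spec("rigid_translate", 5), move_spec("rigid_rotate", 0.3))
  else
    list(move_spec("crankshaft", 1.0), move_spec("pivot", 1.0),
         move_spec("bead_translate", 2.0))
}

## Rodrigues rotation matrix about unit axis u by angle a
.rotation_matrix <- function(u, a) {
  c_ <- cos(a); s_ <- sin(a); C <- 1 - c_
  matrix(c(
    c_ + u[1]^2 * C,        u[1] * u[2] * C - u[3] * s_, u[1] * u[3] * C + u[2] * s_,
    u[2] * u[1] * C + u[3] * s_, c_ + u[2]^2 * C,        u[2] * u[3] * C - u[1] * s_,
    u[3] * u[1] * C - u[2] * s_, u[3] * u[2] * C + u[1] * s_, c_ + u[3]^2 * C),
    3, 3, byrow = TRUE)
}

.random_axis <- function() {
  repeat {
    v <- stats::rnorm(3)
    n2 <- sum(v^2)
    if (n2 > 1e-12) return(v / sqrt(n2))
  }
}

## rotate rows `idx` of pos about the axis through point p0 with unit
## direction u by angle a
.rotate_segment <- function(pos, idx, p0, u, a) {
  Rm <- .rotation_matrix(u, a)
  seg <- sweep(pos[idx, , drop = FALSE], 2, p0)
  pos[idx, ] <- seg %*% t(Rm) + rep(p0, each = length(idx))
  pos
}

#' Rigid-body translation proposal
#'
#' Displaces all beads by a vector drawn uniformly from the cube
#' `[-max_disp, max_disp]^3`.
#'
#' @param pos N x 3 configuration.
#' @param max_disp Maximum per-axis displacement, Angstrom.
#' @return List with `pos` (proposed configuration) and `moved` (indices).
#' @export
rigid_translate <- function(pos, max_disp) {
  d <- stats::runif(3, -max_disp, max_disp)
  list(pos = pos + rep(d, each = nrow(pos)), moved = seq_len(nrow(pos)))
}

#' Rigid-body rotation proposal
#'
#' Rotates all beads about a uniformly random axis through the center of
#' mass by an angle uniform in `[-max_angle, max_angle]`. Internal
#' geometry is preserved exactly.
#'
#' @param pos N x 3 configuration.
#' @param max_angle Maximum rotation angle, rad.
#' @param mass Bead masses for the center of mass (default equal).
#' @return List with `pos` and `moved`.
#' @export
rigid_rotate <- function(pos, max_angle, mass = rep(1, nrow(pos))) {
  cm <- colSums(pos * mass) / sum(mass)
  u <- .random_axis()
  a <- stats::runif(1, -max_angle, max_angle)
  list(pos = .rotate_segment(pos, seq_len(nrow(pos)), cm, u, a),
       moved = seq_len(nrow(pos)))
}

#' Crankshaft move proposal
#'
#' Picks two distinct beads uniformly at random, takes the line through
#' them as rotation axis, and rotates the beads strictly between them by
#' an angle uniform in `[-max_angle, max_angle]`. The picked beads do not
#' move; all bond lengths are preserved. Adjacent picks give the identity.
#'
#' @param pos N x 3 configuration (N >= 3).
#' @param max_angle Maximum rotation angle, rad.
#' @return List with `pos` and `moved` (possibly empty for the identity).
#' @export
crankshaft <- function(pos, max_angle) {
  n <- nrow(pos)
  ij <- sort(sample.int(n, 2))
  a <- stats::runif(1, -max_angle, max_angle)  # drawn even for identity moves
  if (ij[2] - ij[1] < 2) return(list(pos = pos, moved = integer(0)))
  axis <- pos[ij[2], ] - pos[ij[1], ]
  nn <- sqrt(sum(axis^2))
  if (nn < 1e-12) return(list(pos = pos, moved = integer(0)))
  idx <- (ij[1] + 1):(ij[2] - 1)
  list(pos = .rotate_segment(pos, idx, pos[ij[1], ], axis / nn, a),
       moved = idx)
}

#' Pivot move proposal
#'
#' Defines the rotation axis through two randomly picked beads (as in the
#' crankshaft move) and rotates all beads from one randomly chosen chain
#' end up to (but excluding) the nearer picked bead. Bond lengths are
#' preserved because the boundary bead lies on the axis.
#'
#' @param pos N x 3 configuration (N >= 2).
#' @param max_angle Maximum rotation angle, rad.
#' @return List with `pos` and `moved`.
#' @export
pivot <- function(pos, max_angle) {
  n <- nrow(pos)
  ij <- sort(sample.int(n, 2))
  a <- stats::runif(1, -max_angle, max_angle)
  axis <- pos[ij[2], ] - pos[ij[1], ]
  nn <- sqrt(sum(axis^2))
  if (nn < 1e-12) return(list(pos = pos, moved = integer(0)))
  left <- stats::runif(1) < 0.5
  idx <- if (left) seq_len(ij[1] - 1) else
    if (ij[2] < n) (ij[2] + 1):n else integer(0)
  if (!length(idx)) return(list(pos = pos, moved = integer(0)))
  p0 <- pos[if (left) ij[1] else ij[2], ]
  list(pos = .rotate_segment(pos, idx, p0, axis / nn, a), moved = idx)
}

#' Single-bead translation proposal
#'
#' Displaces one uniformly chosen bead by a vector uniform in
#' `[-max_disp, max_disp]^3`.
#'
#' @param pos N x 3 configuration.
#' @param max_disp Maximum per-axis displacement, Angstrom.
#' @return List with `pos` and `moved` (one index).
#' @export
bead_translate <- function(pos, max_disp) {
  i <- sample.int(nrow(pos), 1)
  pos[i, ] <- pos[i, ] + stats::runif(3, -max_disp, max_disp)
  list(pos = pos, moved = i)
}

.propose <- function(sys, pos, mv) {
  switch(mv$type,
         rigid_translate = rigid_translate(pos, mv$step),
         rigid_rotate = rigid_rotate(pos, mv$step, sys$mass),
         crankshaft = crankshaft(pos, mv$step),
         pivot = pivot(pos, mv$step),
         bead_translate = bead_translate(pos, mv$step))
}
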