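# Metropolis Monte Carlo driver (NVT, single molecule per box).

#' Run schedule for a Monte Carlo simulation
#'
#' A sweep is N attempted moves for a flexible N-bead chain and 2 attempted
#' moves for a rigid body (one translation-scale and one rotation-scale
#' attempt on average).
#'
#' @param equilibration Equilibration sweeps (not sampled).
#' @param production Production sweeps.
#' @param sample_every Sampling interval in sweeps.
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @param check_every Interval (sweeps) for validating the incremental
#'   energy bookkeeping against a full recompute.
#' @param adapt Tune step sizes toward 30-50% acceptance during
#'   equilibration only (production proposals are never altered, preserving
#'   detailed balance).
#' @return Object of class `run_schedule`.
#' @export
run_schedule <- function(equilibration = 1000, production = 10000,
                         sample_every = 10, seed = 1,
                         check_every = 1000, adapt = FALSE) {
  stopifnot(equilibration >= 0, production >= 0, sample_every >= 1,
            check_every >= 1)
  structure(list(equilibration = equilibration, production = production,
                 sample_every = sample_every, seed = as.integer(seed),
                 check_every = check_every, adapt = isTRUE(adapt)),
            class = "run_schedule")
}

#' Metropolis Monte Carlo sampling of a system
#'
#' Samples the canonical (NVT) distribution of the system with the given
#' move set: whole-body translations/rotations for rigid models;
#' crankshaft, pivot and single-bead moves for flexible chains. Energy is
#' tracked incrementally and validated against a full recompute every
#' `check_every` sweeps (drift recorded in the result). Runs are exactly
#' reproducible given the schedule seed.
#'
#' @param sys A [cg_system()].
#' @param schedule A [run_schedule()].
#' @param moves List of [move_spec()]s applicable to the model type
#'   (defaults to [default_moves()]).
#' @param start Optional starting configuration (defaults to the model's
#'   positions; see [initialize_configuration()] for crowded setups).
#' @return Object of class `sample_set`: list with `positions` (list of
#'   N x 3 matrices), `energy`, `sweep`, `acceptance` (per move type),
#'   `max_drift`, and provenance (`sys`, `schedule`).
#' @export
mc_run <- function(sys, schedule, moves = default_moves(sys), start = NULL) {
  rigid <- sys$model$rigid
  types <- vapply(moves, `[[`, character(1), "type")
  rigid_types <- c("rigid_translate", "rigid_rotate")
  if (rigid && any(!types %in% rigid_types))
    stop("chain moves are not applicable to rigid models: ",
         paste(setdiff(types, rigid_types), collapse = ", "))
  if (!rigid && any(types %in% rigid_types))
    stop("rigid-body moves are not applicable to flexible chains: ",
         paste(intersect(types, rigid_types), collapse = ", "))

  set.seed(schedule$seed)
  pos <- if (is.null(start)) sys$model$pos else as.matrix(start)
  E <- total_energy(sys, pos)
  if (!is.finite(E))
    stop("non-finite starting energy; re-initialize the configuration ",
         "(see initialize_configuration())")

  per_sweep <- if (rigid) 2L else n_beads(sys$model)
  wt <- vapply(moves, `[[`, numeric(1), "weight"); wt <- wt / sum(wt)
  steps <- vapply(moves, `[[`, numeric(1), "step")
  n_tot <- schedule$equilibration + schedule$production
  n_samp <- schedule$production %/% schedule$sample_every
  samples <- vector("list", n_samp)
  energies <- sweeps_at <- numeric(n_samp)
  att <- acc <- numeric(length(moves))
  si <- 0L; max_drift <- 0

  Eext <- if (rigid) .ext_energy(sys, pos) else NA_real_

  for (sweep in seq_len(n_tot)) {
    for (k in seq_len(per_sweep)) {
      mi <- if (length(moves) == 1L) 1L else
        sample.int(length(moves), 1L, prob = wt)
      mv <- moves[[mi]]
      if (mv$step != steps[mi]) mv$step <- steps[mi]
      prop <- .propose(sys, pos, mv)
      att[mi] <- att[mi] + 1
      if (!length(prop$moved)) { acc[mi] <- acc[mi] + 1; next } # identity
      if (rigid) {
        ## whole-body move: the external energy is the total energy, and
        ## the old value is cached across attempts
        En <- if (.shell_violation(sys, prop$pos)) Inf else
          .ext_energy(sys, prop$pos)
        dE <- En - Eext
        if (metropolis_accept(dE)) {
          pos <- prop$pos; E <- E + dE; Eext <- En; acc[mi] <- acc[mi] + 1
        }
      } else {
        dE <- .delta_energy(sys, pos, prop$pos, prop$moved)
        if (metropolis_accept(dE)) {
          pos <- prop$pos; E <- E + dE; acc[mi] <- acc[mi] + 1
        }
      }
    }
    if (sweep %% schedule$check_every == 0L) {
      Efull <- total_energy(sys, pos)
      max_drift <- max(max_drift, abs(Efull - E))
      E <- Efull
      if (rigid) Eext <- .ext_energy(sys, pos)
    }
    if (schedule$adapt && sweep <= schedule$equilibration &&
        sweep %% 200L == 0L) {
      rate <- ifelse(att > 0, acc / att, 0.4)
      steps <- steps * ifelse(rate > 0.5, 1.15, ifelse(rate < 0.3, 0.87, 1))
    }
    if (sweep > schedule$equilibration) {
      k <- sweep - schedule$equilibration
      if (k %% schedule$sample_every == 0L) {
        si <- si + 1L
        samples[[si]] <- pos
        energies[si] <- E
        sweeps_at[si] <- sweep
      }
    }
  }

  structure(list(
    positions = samples[seq_len(si)],
    energy = energies[seq_len(si)],
    sweep = sweeps_at[seq_len(si)],
    acceptance = data.frame(type = types, step = steps,
                            attempts = att, accepted = acc,
                            rate = ifelse(att > 0, acc / att, NA_real_)),
    max_drift = max_drift,
    sys = sys, schedule = schedule),
    class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf(
    "sample_set: %d snapshots (%d beads), seed %d, max energy drift %.2e kBT\n",
    length(x$positions), n_beads(x$sys$model), x$schedule$seed, x$max_drift))
  print(x$acceptance, row.names = FALSE)
  invisible(x)
}

#' Find a finite-energy starting configuration
#'
#' Rigid bodies are placed at random positions/orientations in the cell;
#' flexible chains are regrown as random walks at the equilibrium bond
#' length with hard-core retries. Errors after `max_tries` failures.
#'
#' @param sys A [cg_system()].
#' @param seed RNG seed.
#' @param max_tries Attempts before giving up.
#' @return An N x 3 configuration with finite [total_energy()].
#' @export
initialize_configuration <- function(sys, seed = 1, max_tries = 200) {
  set.seed(seed)
  n <- n_beads(sys$model)
  for (try in seq_len(max_tries)) {
    if (sys$model$rigid) {
      pos <- sys$model$pos
      cm <- center_of_mass(pos, sys$mass)
      pos <- .rotate_segment(pos, seq_len(n), cm, .random_axis(),
                             stats::runif(1, 0, 2 * pi))
      ext <- max(abs(sweep(pos, 2, center_of_mass(pos, sys$mass))[, 3]))
      if (is.na(sys$shell_outer)) {
        zlim <- c(ext + max(sys$rad) + 1, sys$Lz - ext - max(sys$rad) - 1)
        tgt <- c(stats::runif(1, 0, sys$Lx), stats::runif(1, 0, sys$Ly),
                 stats::runif(1, zlim[1], zlim[2]))
      } else {
        ctr <- c(sys$np_x[1], sys$np_y[1], sys$np_z[1])
        u <- .random_axis()
        rr <- stats::runif(1, sys$np_R[1] + ext, sys$shell_outer)
        tgt <- ctr + u * rr
      }
      pos <- pos + rep(tgt - center_of_mass(pos, sys$mass), each = n)
    } else {
      b <- sys$bond$Req
      start <- c(stats::runif(1, 0, sys$Lx), stats::runif(1, 0, sys$Ly),
                 stats::runif(1, min(sys$Lz * 0.3, 50) + max(sys$rad),
                              sys$Lz - max(sys$rad) - 1))
      pos <- matrix(NA_real_, n, 3)
      pos[1, ] <- start
      ok <- TRUE
      for (i in 2:n) {
        placed <- FALSE
        for (k in seq_len(50)) {
          cand <- pos[i - 1, ] + .random_axis() * b
          if (sys$wall && (cand[3] < sys$rad[i] ||
                           cand[3] > sys$Lz - sys$rad[i])) next
          if (sys$hard_core && i > 2) {
            d2 <- rowSums(sweep(pos[seq_len(i - 2), , drop = FALSE], 2,
                                cand)^2)
            if (any(d2 < (sys$rad[seq_len(i - 2)] + sys$rad[i])^2)) next
          }
          pos[i, ] <- cand; placed <- TRUE; break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (!ok) next
    }
    if (is.finite(total_energy(sys, pos))) return(pos)
  }
  stop("could not find a finite-energy starting configuration")
}
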