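# Shared builders and memoised simulation runs. All fixtures are generated
# in code; simulations are cached per test session so several tests can
# analyze the same sampled trajectories.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

## standard move set for rigid adsorption runs: fine + coarse translations
## (the coarse one carries the molecule across the box), fine + coarse
## rotations
rigid_moves <- function() list(
  move_spec("rigid_translate", 5, 2), move_spec("rigid_translate", 200, 1),
  move_spec("rigid_rotate", 0.3, 2), move_spec("rigid_rotate", 1.5, 1))

run_rigid <- function(layout, seed, eq = 4000, prod = 50000, every = 50) {
  sys <- cg_system(fibrinogen_mimic_rod(), layout)
  start <- initialize_configuration(sys, seed = seed)
  mc_run(sys, run_schedule(eq, prod, every, seed = seed,
                           check_every = 10000),
         moves = rigid_moves(), start = start)
}

## the toy-scale adsorption campaign reused across acceptance tests
campaign_flat <- function(rho) memo(paste0("flat", rho), {
  run_rigid(flat_surface(rho, simulation_cell(600, 600, 1500)),
            seed = 11 + round(1000 * abs(rho)))
})

campaign_nano <- function(rho, d = 600) memo(paste0("nano", rho, "_", d), {
  cell <- simulation_cell(d, sqrt(3) * d, 1500)
  run_rigid(hex_lattice(200, d, cell, rho),
            seed = 21 + round(1000 * abs(rho)) + round(d / 100))
})

campaign_single_np <- function(R) memo(paste0("snp", R), {
  cell <- simulation_cell(2 * R + 1200, 2 * R + 1200, 2 * R + 1200)
  run_rigid(single_nanoparticle(R, cell, -0.005), seed = 30 + R / 100)
})

frac_se <- function(samples) {
  b <- block_average(as.numeric(adsorbed_fraction(samples)$flags))
  c(mean = b$mean, se = b$se)
}

mean_cos_np <- function(samples) {
  sys <- samples$sys
  flags <- adsorbed_fraction(samples)$flags
  np <- sys$layout$nanoparticles[1, ]
  v <- vapply(samples$positions[flags], cos_to_np, numeric(1),
              np = np, mass = sys$mass, cell = sys$layout$cell)
  b <- block_average(v)
  c(mean = b$mean, se = b$se)
}

mean_cos_flat <- function(samples) {
  flags <- adsorbed_fraction(samples)$flags
  v <- vapply(samples$positions[flags], cos_to_surface_normal, numeric(1),
              mass = samples$sys$mass)
  b <- block_average(v)
  c(mean = b$mean, se = b$se)
}

## small interacting chain system above a charged wall (fast unit tests)
toy_chain_system <- function(n = 20, rho = -0.005, Lz = 300) {
  set.seed(101)
  seq_ <- paste(sample(c("K", "D", "A", "G", "E", "S"), n, TRUE),
                collapse = "")
  model <- assign_charges(build_flexible_chain(seq_))
  cg_system(model, flat_surface(rho, simulation_cell(200, 200, Lz)))
}

## ideal (non-interacting) chain system in open space
ideal_chain_system <- function(n_residues) {
  model <- build_flexible_chain(paste(rep("G", n_residues), collapse = ""))
  lay <- flat_surface(0, simulation_cell(1e6, 1e6, 1e6))
  lay$wall <- FALSE
  cg_system(model, lay, use_dh = FALSE, use_lj = FALSE, hard_core = FALSE)
}

## independent brute-force total energy: direct double loop over the
## exported scalar energy terms (the oracle for total_energy)
brute_force_energy <- function(sys, pos) {
  n <- nrow(pos)
  cond <- sys$conditions
  kappa <- 1 / debye_length(cond)
  E <- 0
  lay <- sys$layout
  if (lay$wall) {
    f <- surface_field(lay$rho, cond)
    for (i in seq_len(n)) {
      if (pos[i, 3] < sys$rad[i] || pos[i, 3] > lay$cell$Lz - sys$rad[i])
        return(Inf)
      E <- E + gc_energy(sys$q[i], pos[i, 3], f)
    }
  }
  nps <- lay$nanoparticles
  for (j in seq_len(nrow(nps))) for (i in seq_len(n)) {
    w <- np_bead_energy(nps[j, ], pos[i, ], sys$q[i], sys$rad[i], cond,
                        lay$cell)
    if (!is.finite(w)) return(Inf)
    E <- E + w
  }
  if (!sys$model$rigid) {
    b <- sys$model$bonds
    for (k in seq_len(nrow(b)))
      E <- E + bond_energy(sqrt(sum((pos[b[k, 1], ] - pos[b[k, 2], ])^2)),
                           sys$bond)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (j - i == 1) next
      d <- min_image_displacement(pos[i, ], pos[j, ], lay$cell)
      r <- sqrt(sum(d^2))
      sig <- sys$rad[i] + sys$rad[j]
      if (r < sig) return(Inf)
      E <- E + dh_pair_energy(sys$q[i], sys$q[j], r, sig, kappa, cond) +
        lj_energy(r, sig, sys$pair)
    }
  }
  E
}
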