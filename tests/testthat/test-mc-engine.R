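# Metropolis sampling: acceptance rule, proposal properties, detailed
# balance on analytically solvable systems, and energy bookkeeping.

test_that("Metropolis rule: downhill always, +Inf never, e^-dE threshold", {
  expect_true(metropolis_accept(-3, 0.999999))
  expect_false(metropolis_accept(Inf, 0))
  expect_true(metropolis_accept(log(2), 0.49))
  expect_false(metropolis_accept(log(2), 0.51))
})

test_that("rigid-body proposals preserve internal geometry exactly", {
  rod <- fibrinogen_mimic_rod(40)
  pos <- rod$pos
  d0 <- dist(pos)
  set.seed(3)
  for (k in 1:200) pos <- rigid_rotate(pos, 1.5, rod$mass)$pos
  expect_equal(max(abs(dist(pos) - d0)), 0, tolerance = 1e-9)
  ## zero step size is the identity
  set.seed(1)
  expect_equal(rigid_translate(pos, 0)$pos, pos)
  expect_equal(rigid_rotate(pos, 0)$pos, pos, tolerance = 1e-12)
  ## symmetric proposal: mean displacement ~ 0
  set.seed(4)
  disp <- colMeans(t(vapply(1:2000, function(i)
    rigid_translate(pos, 5)$pos[1, ] - pos[1, ], numeric(3))))
  expect_true(all(abs(disp) < 0.2))
})

test_that("crankshaft and pivot preserve bond lengths and are reversible", {
  set.seed(11)
  pos <- make_ideal_chain(30, 4.1)
  blen <- function(p) sqrt(rowSums(diff(p)^2))
  b0 <- blen(pos)
  for (k in 1:50) {
    set.seed(100 + k)
    pr <- crankshaft(pos, 2.5)
    expect_equal(blen(pr$pos), b0, tolerance = 1e-9)
    set.seed(200 + k)
    pv <- pivot(pos, 2.5)
    expect_equal(blen(pv$pos), b0, tolerance = 1e-9)
  }
  ## reversibility: applying the inverse rotation restores the chain
  set.seed(42); pr <- crankshaft(pos, 2.0)
  if (length(pr$moved)) {
    ## recover pick and angle by replaying the RNG stream
    set.seed(42); ij <- sort(sample.int(nrow(pos), 2))
    a <- runif(1, -2, 2)
    axis <- pos[ij[2], ] - pos[ij[1], ]; axis <- axis / sqrt(sum(axis^2))
    th <- -a
    Rm <- matrix(c(
      cos(th) + axis[1]^2 * (1 - cos(th)),
      axis[1] * axis[2] * (1 - cos(th)) - axis[3] * sin(th),
      axis[1] * axis[3] * (1 - cos(th)) + axis[2] * sin(th),
      axis[2] * axis[1] * (1 - cos(th)) + axis[3] * sin(th),
      cos(th) + axis[2]^2 * (1 - cos(th)),
      axis[2] * axis[3] * (1 - cos(th)) - axis[1] * sin(th),
      axis[3] * axis[1] * (1 - cos(th)) - axis[2] * sin(th),
      axis[3] * axis[2] * (1 - cos(th)) + axis[1] * sin(th),
      cos(th) + axis[3]^2 * (1 - cos(th))), 3, 3, byrow = TRUE)
    back <- pr$pos
    seg <- sweep(back[pr$moved, , drop = FALSE], 2, pos[ij[1], ])
    back[pr$moved, ] <- seg %*% t(Rm) +
      rep(pos[ij[1], ], each = length(pr$moved))
    expect_equal(back, pos, tolerance = 1e-9)
  }
  ## adjacent picked beads give the identity (no interior)
  p3 <- make_ideal_chain(3, 4.1, seed = 5)
  found_identity <- FALSE
  for (k in 1:20) {
    pr <- crankshaft(p3, 2)
    if (!length(pr$moved)) { found_identity <- TRUE
      expect_equal(pr$pos, p3) }
  }
  expect_true(found_identity)
})

test_that("single-bead translation moves exactly one bead", {
  set.seed(9)
  pos <- make_ideal_chain(20, 4.1)
  pr <- bead_translate(pos, 2)
  changed <- which(rowSums(abs(pr$pos - pos)) > 0)
  expect_equal(changed, pr$moved)
  expect_length(changed, 1)
})

test_that("identical seeds give bit-identical sample sets", {
  sys <- toy_chain_system(n = 8)
  st <- initialize_configuration(sys, seed = 2)
  sch <- run_schedule(50, 200, 10, seed = 77, check_every = 100)
  s1 <- mc_run(sys, sch, start = st)
  s2 <- mc_run(sys, sch, start = st)
  expect_identical(s1$positions, s2$positions)
  expect_identical(s1$energy, s2$energy)
})

test_that("move sets are validated against the model type", {
  sys <- toy_chain_system(n = 8)
  expect_error(mc_run(sys, run_schedule(10, 10, 5, 1),
                      moves = list(move_spec("rigid_translate", 5))),
               "not applicable")
  rsys <- cg_system(fibrinogen_mimic_rod(40),
                    flat_surface(-0.001, simulation_cell(400, 400, 800)))
  expect_error(mc_run(rsys, run_schedule(10, 10, 5, 1),
                      moves = list(move_spec("crankshaft", 1))),
               "not applicable")
  expect_error(run_schedule(10, 10, 0, 1))
})

test_that("a non-finite starting energy is rejected with advice", {
  rod <- fibrinogen_mimic_rod(40)
  sys <- cg_system(rod, flat_surface(-0.001, simulation_cell(400, 400, 800)))
  ## the rod model is centered at the origin: it sticks through the floor
  expect_error(mc_run(sys, run_schedule(10, 10, 5, 1)), "re-initialize")
})

test_that("two-state toy reproduces Boltzmann occupancies", {
  s <- sample_two_state(make_two_state_toy(1), 200000, seed = 5)
  p1 <- mean(s == 1)
  exact <- 1 / (1 + exp(-1))
  se <- sd(s == 1) / sqrt(length(s) / 10)  # generous correlation allowance
  expect_lt(abs(p1 - exact), 3 * se + 0.005)
  ## zero gap: 50/50
  s0 <- sample_two_state(make_two_state_toy(0), 100000, seed = 6)
  expect_lt(abs(mean(s0 == 1) - 0.5), 0.01)
  ## infinite gap: ground state only
  sInf <- sample_two_state(make_two_state_toy(Inf), 2000, seed = 7)
  expect_true(all(sInf == 1L))
})

test_that("single-bead sampling above an uncharged wall is uniform in z", {
  bead <- bead_model(matrix(c(10, 10, 100), 1), radius = 2, charge = 0,
                     rigid = FALSE)
  sys <- cg_system(bead, flat_surface(0, simulation_cell(200, 200, 202)),
                   use_lj = FALSE)
  s <- mc_run(sys, run_schedule(200, 40000, 20, seed = 4,
                                check_every = 10000),
              moves = list(move_spec("bead_translate", 60)))
  z <- vapply(s$positions, function(p) p[1, 3], numeric(1))
  ks <- suppressWarnings(stats::ks.test(z, "punif", 2, 200))
  expect_gt(ks$p.value, 0.01)
})

test_that("incremental energy bookkeeping tracks the full recompute", {
  sys <- toy_chain_system(n = 50, rho = -0.005)
  st <- initialize_configuration(sys, seed = 12)
  s <- mc_run(sys, run_schedule(100, 400, 20, seed = 13, check_every = 50),
              start = st)
  expect_lt(s$max_drift, 1e-8)
  ## energies stored with the samples match a from-scratch recompute
  k <- length(s$positions)
  expect_equal(s$energy[k], total_energy(sys, s$positions[[k]]),
               tolerance = 1e-8)
})

test_that("no accepted configuration contains a hard-core overlap", {
  sys <- toy_chain_system(n = 15, rho = -0.01)
  st <- initialize_configuration(sys, seed = 3)
  s <- mc_run(sys, run_schedule(200, 1000, 10, seed = 9, check_every = 200),
              start = st)
  min_pair_gap <- vapply(s$positions, function(p) {
    d <- as.matrix(dist(p))
    sig <- outer(sys$rad, sys$rad, "+")
    excl <- abs(outer(seq_len(nrow(p)), seq_len(nrow(p)), "-")) <= 1
    min((d - sig)[!excl])
  }, numeric(1))
  expect_true(all(min_pair_gap >= 0))
  expect_true(all(vapply(s$positions, min_surface_separation, numeric(1),
                         sys = sys) >= 0))
  expect_true(all(is.finite(s$energy)))
})

test_that("ideal-chain sampling matches the freely-jointed closed form", {
  sys <- ideal_chain_system(98)   # 100 beads
  st <- initialize_configuration(sys, seed = 9)
  s <- mc_run(sys, run_schedule(100, 700, 4, seed = 2, check_every = 400),
              start = st)
  ree2 <- vapply(s$positions, function(p) end_to_end(p, sys$model)^2,
                 numeric(1))
  rg2 <- vapply(s$positions, function(p) rg(p, sys$mass)^2, numeric(1))
  ratio <- mean(ree2) / mean(rg2)
  expect_equal(ratio, 6 * 100 / 101, tolerance = 0.05)
  ## bond lengths fluctuate about the harmonic minimum
  rb <- vapply(s$positions, function(p) mean(sqrt(rowSums(diff(p)^2))),
               numeric(1))
  expect_equal(mean(rb), 4.1, tolerance = 0.12)
})
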