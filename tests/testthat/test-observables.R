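# Observables: shape descriptors, orientations, profiles, g(r),
# adsorbed fractions.

test_that("radius of gyration and shape factor: closed forms", {
  ## two equal beads at separation d: Rg = d/2
  expect_equal(rg(rbind(c(0, 0, 0), c(0, 0, 17))), 8.5)
  ## mass weighting: all mass on one bead -> Rg ~ 0
  expect_lt(rg(rbind(c(0, 0, 0), c(0, 0, 17)), mass = c(1e12, 1)), 1e-4)
  ## 3 collinear equally spaced beads: shape factor exactly 6
  expect_equal(shape_factor(cbind(0, 0, c(0, 7, 14))), 6)
  ## straight N-bead rod: 12 (N-1)/(N+1), approaching 12
  for (n in c(10, 100, 1000))
    expect_equal(shape_factor(cbind(0, 0, seq_len(n))),
                 12 * (n - 1) / (n + 1), tolerance = 1e-12)
  expect_equal(shape_factor(cbind(0, 0, seq_len(10000))), 12,
               tolerance = 0.001)
})

test_that("end-to-end distance skips terminal charge beads", {
  ch <- build_flexible_chain("AAAA")       # NTERM + 4 + CTERM
  ## residue beads are rows 2..5 at spacing 4.1
  expect_equal(end_to_end(ch), 3 * 4.1)
  ## plain matrices use the full first-to-last distance
  expect_equal(end_to_end(cbind(0, 0, c(0, 5, 20))), 20)
})

test_that("axis vector: exact for rods, stable under reordering and
           covariant with rotations", {
  z <- seq(0, 100, by = 5)
  rod <- cbind(0.3 * z, -0.2 * z, z)           # collinear, oblique
  v <- axis_vector(rod)
  u <- c(0.3, -0.2, 1) / sqrt(0.3^2 + 0.2^2 + 1)
  expect_equal(abs(sum(v * u)), 1, tolerance = 1e-12)
  expect_gte(v[3], 0)
  ## bead reordering
  expect_equal(axis_vector(rod[sample(nrow(rod)), ]), v, tolerance = 1e-9)
  ## covariance with a rigid rotation
  th <- 0.9
  Rx <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3,
               byrow = TRUE)
  vr <- axis_vector(rod %*% t(Rx))
  expect_equal(abs(sum(vr * (Rx %*% v))), 1, tolerance = 1e-9)
  ## degenerate (sphere-like) bodies are refused
  set.seed(1)
  sph <- matrix(rnorm(3000), ncol = 3)
  sph <- sph / sqrt(rowSums(sph^2))
  expect_error(principal_axis(sph, tol = 0.5), "degenerate")
})

test_that("orientation cosines: flat, upright, oblique and radial poses", {
  upz <- cbind(0, 0, 0:20)
  expect_equal(cos_to_surface_normal(upz), 1)
  flat <- cbind(0:20, 0, 5)
  expect_equal(cos_to_surface_normal(flat), 0)
  ## rod at 60 degrees from the normal: cosine 0.5
  tilt <- cbind(sin(pi / 3) * (0:20), 0, cos(pi / 3) * (0:20))
  expect_equal(cos_to_surface_normal(tilt), 0.5, tolerance = 1e-12)
  np <- list(x = 0, y = 0, z = 0)
  radial <- cbind(0, 0, 300 + (0:20))
  expect_equal(cos_to_np(radial, np), 1, tolerance = 1e-12)
  tangential <- cbind(0:20, 0, 300)
  expect_lt(cos_to_np(tangential, np), 0.05)
})

test_that("free-energy profile: flat for uncharged, matches the exact
           1-bead Boltzmann oracle, and round-trips", {
  ## uncharged bead in a box: F(z) = 0 within noise
  bead <- bead_model(matrix(c(10, 10, 50), 1), radius = 2, charge = 0,
                     rigid = FALSE)
  sys0 <- cg_system(bead, flat_surface(0, simulation_cell(100, 100, 102)))
  s0 <- mc_run(sys0, run_schedule(100, 60000, 15, seed = 8,
                                  check_every = 10000),
               moves = list(move_spec("bead_translate", 40)))
  f0 <- free_energy_profile(s0, bin_width = 10)
  mid0 <- profile_midpoints(f0)
  interior <- !is.na(f0$values) & mid0 > 15 & mid0 < 85  # full bins only
  expect_true(all(abs(f0$values[interior]) < 0.25))

  ## charged bead above an attractive wall: F(z) tracks gc_energy(z)
  beadq <- bead_model(matrix(c(10, 10, 30), 1), radius = 2, charge = 1,
                      rigid = FALSE)
  sysq <- cg_system(beadq, flat_surface(-0.01,
                                        simulation_cell(60, 60, 100)))
  sq <- mc_run(sysq, run_schedule(500, 400000, 80, seed = 21,
                                  check_every = 50000),
               moves = list(move_spec("bead_translate", 16)))
  fq <- free_energy_profile(sq, bin_width = 6)
  mid <- profile_midpoints(fq)
  field <- surface_field(-0.01, sysq$conditions)
  ## exact oracle: bin-integrated Boltzmann weights of the wall potential
  dens <- function(zz) exp(-gc_energy(1, zz, field))
  wts <- diff(vapply(fq$edges, function(u)
    integrate(dens, 2, max(u, 2))$value, numeric(1)))
  ref <- -log(wts / sum(wts))
  ok <- !is.na(fq$values)
  z <- com_heights(sq)
  plateau <- ok & mid >= max(z) - 0.2 * (max(z) - min(z))
  ref <- ref - mean(ref[plateau])   # same anchoring as the profile
  ## accurate to 0.1 kBT where the histogram is well resolved, 0.4 in the
  ## sparsest bins
  counts <- hist(z, breaks = fq$edges, plot = FALSE)$counts
  solid <- ok & mid < 90 & counts >= 300
  expect_gte(sum(solid), 3)   # the well region is densely sampled
  expect_lt(max(abs(fq$values[solid] - ref[solid])), 0.1)
  rest <- ok & mid < 90 & !solid
  if (any(rest)) expect_lt(max(abs(fq$values[rest] - ref[rest])), 0.4)

  ## exp(-F) renormalizes back to P
  P <- exp(-fq$values[!is.na(fq$values)])
  P <- P / sum(P)
  z <- com_heights(sq)
  counts <- hist(z, breaks = fq$edges, plot = FALSE)$counts
  Pemp <- counts[counts > 0] / sum(counts)
  expect_equal(P, Pemp, tolerance = 1e-12)
})

test_that("deeper surface charge gives a deeper free-energy minimum", {
  s1 <- campaign_flat(-0.005)
  s2 <- campaign_flat(-0.01)
  f1 <- free_energy_profile(s1)
  f2 <- free_energy_profile(s2)
  expect_lt(min(f2$values, na.rm = TRUE), min(f1$values, na.rm = TRUE))
})

test_that("g(r): ideal gas is flat at 1; the hard core is empty", {
  ## neutral point particle in the confinement shell
  bead <- bead_model(matrix(c(700, 700, 950), 1), radius = 1e-9,
                     charge = 0, rigid = FALSE)
  cell <- simulation_cell(1400, 1400, 1400)
  lay <- single_nanoparticle(200, cell, 0)
  sys <- cg_system(bead, lay, use_lj = FALSE)
  s <- mc_run(sys, run_schedule(100, 60000, 10, seed = 31,
                                check_every = 20000),
              moves = list(move_spec("bead_translate", 150)))
  g <- radial_g(s, bin_width = 50)
  mid <- profile_midpoints(g)
  inner <- mid < 450   # away from the outer boundary bins
  expect_true(all(abs(g$values[inner] - 1) < 0.15))
  expect_equal(sum(vapply(s$positions, function(p)
    sqrt(sum((p[1, ] - c(700, 700, 700))^2)) < 200, logical(1))), 0)

  ## attractive system: a strong near-surface peak. The rod's center of
  ## mass sits of order half a rod length from the particle surface when
  ## bound, so the peak is at finite r, with depletion far away.
  sa <- campaign_single_np(100)
  ga <- radial_g(sa, bin_width = 10)
  mids <- profile_midpoints(ga)
  expect_gt(max(ga$values), 1)
  expect_lt(mids[which.max(ga$values)], 300)
  expect_lt(mean(ga$values[mids > 500], na.rm = TRUE), 0.2)
})

test_that("adsorbed fraction is monotone in the cutoff and saturates", {
  s <- campaign_flat(-0.005)
  cuts <- c(5, 10, 20, 40, 80, 1e4)
  fr <- vapply(cuts, function(cc) adsorbed_fraction(s, cc)$fraction,
               numeric(1))
  expect_true(all(diff(fr) >= 0))
  expect_equal(fr[length(fr)], 1)
})

test_that("cosine distributions are normalized with support in [0, 1]", {
  s <- campaign_flat(-0.01)
  cd <- cosine_distribution(s)
  expect_equal(sum(cd$values), 1, tolerance = 1e-12)
  expect_gte(min(cd$edges), 0)
  expect_lte(max(cd$edges), 1)
})

test_that("block averaging reports a sane standard error", {
  set.seed(5)
  x <- rnorm(1000)
  b <- block_average(x, 10)
  expect_equal(b$mean, mean(x))
  expect_lt(abs(b$se - sd(x) / sqrt(1000)), 0.03)
})
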