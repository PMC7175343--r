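# Structure loading, coarse-graining and charge assignment on synthetic
# PDB fixtures with known ground truth.

test_that("toy PDB fixtures parse with resolved/unresolved residues and ions", {
  txt <- make_toy_pdb(list(A = list(sequence = "DKE")))
  rec <- load_structure(txt)
  expect_equal(nrow(rec$residues), 3)
  expect_true(all(rec$residues$resolved))

  txt2 <- make_toy_pdb(list(A = list(sequence = "DKA", unresolved = 3L)),
                       ions = data.frame(resid = "CA", x = 5, y = 5, z = 5))
  rec2 <- load_structure(txt2)
  expect_equal(sum(!rec2$residues$resolved), 1)
  expect_identical(rec2$residues$resid[!rec2$residues$resolved], "ALA")
  ion <- rec2$residues[rec2$residues$is_ion, ]
  expect_equal(nrow(ion), 1)
  expect_identical(ion$element, "CA")

  ## 10 resolved + 5 unresolved -> 33% unresolved
  txt3 <- make_toy_pdb(list(A = list(sequence = "DKEAGDKEAGDKEAG",
                                     unresolved = 11:15)))
  expect_equal(unresolved_fraction(load_structure(txt3)), 1 / 3)
})

test_that("unknown assemblies and malformed files give clean errors", {
  txt <- make_toy_pdb(list(A = list(sequence = "DKE")))
  expect_error(load_structure(txt, assembly = 2), "available assemblies")
  expect_error(load_structure("not a pdb\nat all\n"), "parse")
})

test_that("rigid coarse-graining: one bead per resolved residue plus termini", {
  txt <- make_toy_pdb(list(A = list(sequence = "DKE")))
  m <- coarse_grain_rigid(load_structure(txt))
  expect_equal(n_beads(m), 5)  # 3 residues + NTERM + CTERM
  expect_true(m$rigid)
  expect_equal(nrow(m$bonds), 0)
  expect_true(all(m$radius == 2.5))
  expect_setequal(m$label, c("ASP", "LYS", "GLU", "NTERM", "CTERM"))
})

test_that("truncated chains get no terminal bead at the missing end", {
  ## unresolved C-terminal tail: no CTERM bead, so its -1 is absent
  txt <- make_toy_pdb(list(A = list(sequence = "DKEAG", unresolved = 5L)))
  m <- assign_charges(coarse_grain_rigid(load_structure(txt)))
  expect_false("CTERM" %in% m$label)
  expect_true("NTERM" %in% m$label)
  ## resolved: D K E A (-1 +1 -1 0) + NTERM (+1) = 0
  expect_equal(net_charge(m), 0)
})

test_that("charge rules: titratable residues, ions, termini, idempotence", {
  rules <- default_charge_rules()
  expect_equal(unname(rules$residue[c("ASP", "GLU", "LYS", "ARG", "HIS",
                                      "CYS", "TYR")]),
               c(-1, -1, 1, 1, 0, 0, 0))
  txt <- make_toy_pdb(list(A = list(sequence = "DKE")),
                      ions = data.frame(resid = "CA", x = 9, y = 0, z = 0))
  m <- assign_charges(coarse_grain_rigid(load_structure(txt)))
  ## D-K-E with both termini: -1 +1 -1 +1 -1 = -1; calcium +2
  expect_equal(m$charge[m$label == "CA"], 2)
  expect_equal(net_charge(m), -1 + 2)
  ## idempotent
  expect_identical(assign_charges(m)$charge, m$charge)
  ## unknown labels: warning + zero
  m2 <- bead_model(diag(3), label = c("ASP", "XXX", "LYS"))
  expect_warning(m3 <- assign_charges(m2), "XXX")
  expect_equal(m3$charge, c(-1, 0, 1))
})

test_that("flexible chains: bead counts, bonds, net charges", {
  ch <- assign_charges(build_flexible_chain("AAA"))
  expect_equal(n_beads(ch), 5)
  expect_equal(nrow(ch$bonds), 4)
  expect_false(ch$rigid)
  expect_equal(net_charge(ch), 0)        # termini +1 -1
  expect_equal(sum(ch$charge[!ch$label %in% c("NTERM", "CTERM")]), 0)

  kd <- assign_charges(build_flexible_chain("KKDD"))
  expect_equal(net_charge(kd), 0)        # +1+1-1-1 + termini

  ## a 410-residue chain (the alpha-C fragment length) -> 412 beads
  long <- build_flexible_chain(paste(rep("S", 410), collapse = ""))
  expect_equal(n_beads(long), 412)
  ## consecutive bonds at the equilibrium length in the initial state
  d <- diff(long$pos)
  expect_equal(unname(sqrt(rowSums(d^2))), rep(4.1, 411))

  expect_error(build_flexible_chain("AAZB"), "position 3")
  expect_error(build_flexible_chain(""), "non-empty|invalid")
})

test_that("longitudinal profiles: conservation, uniform rod, tripartite rod", {
  ## uniform +1 rod: every bin holds N/20 charge
  rod <- make_charged_rod(rod_spec(100, 5,
                                   data.frame(fraction = 1, charge = 1)))
  p <- longitudinal_profile(rod, 20, "charge")
  expect_equal(p$values, rep(5, 20))
  ## charge conservation for several bin counts
  mim <- fibrinogen_mimic_rod()
  for (nb in c(7, 20, 33))
    expect_equal(sum(longitudinal_profile(mim, nb, "charge")$values),
                 net_charge(mim))
  ## tripartite rod: positive end bins, negative middle bins
  tri <- make_charged_rod(rod_spec(90, 5, data.frame(
    fraction = c(0.15, 0.70, 0.15), charge = c(1, -1, 1))))
  v <- longitudinal_profile(tri, 20, "charge")$values
  expect_gt(v[1], 0); expect_gt(v[20], 0)
  expect_lt(v[10], 0)
  expect_error(longitudinal_profile(mim, 0), "n_bins")
})

test_that("hydrophobic residues are counted correctly in profiles", {
  rodseq <- paste(rep("L", 30), collapse = "")  # hydrophobic
  m <- build_flexible_chain(rodseq)
  p <- longitudinal_profile(m, 10, "hydrophobic_count")
  expect_equal(sum(p$values), 30)
  m2 <- build_flexible_chain(paste(rep("S", 30), collapse = ""))
  expect_equal(sum(longitudinal_profile(m2, 10, "hydrophobic_count")$values),
               0)
})

test_that("unresolved charge bookkeeping adds tail residue charges", {
  ## chain truncated after residue 2; unresolved D D K -> -1 -1 +1 = -1,
  ## plus the C-terminal -1 of the unresolved tail
  txt <- make_toy_pdb(list(A = list(sequence = "KADDK", unresolved = 3:5)))
  rec <- load_structure(txt)
  expect_equal(unresolved_charge(rec, include_cterm = FALSE), -1)
  expect_equal(unresolved_charge(rec), -2)
})
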