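---
title: "Coarse-grained Monte Carlo simulation of protein adsorption: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained Monte Carlo simulation of protein adsorption: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgadsorb)
```

## The problem

When a protein meets a charged interface — a silica implant surface, a
nanoparticle, a nanostructured coating — it adsorbs in particular amounts
and orientations, and those orientations control which epitopes remain
available to cells. `cgadsorb` models this process at residue resolution
for a single molecule in a box: a protein built one bead per amino acid,
interacting with charged flat walls and nanoparticle lattices through
screened electrostatics only, sampled by Metropolis Monte Carlo in the
canonical (NVT) ensemble. The motivating system is human fibrinogen, a
45-nm rod whose crystal structure resolves only 65% of its residues;
the remaining C-terminal 410 residues of each Aα-chain (the αC-chains)
are intrinsically disordered and are treated as separate flexible
bead–spring chains.

## The coarse-grained model

**Rigid main body.** Every residue resolved in the crystal structure
becomes a hard sphere of radius 2.5 Å centered on its Cα atom, carrying
an integer point charge at its center: Asp and Glu −1, Lys and Arg +1,
His and all other residues 0 (pH 7.4; the charged-histidine population is
taken as negligible, and Cys/Tyr are treated as neutral). Free chain
termini are modeled as separate beads (+1 at the backbone N of the first
resolved residue, −1 at the carboxyl C of the last); a terminus whose
flanking residues are unresolved is *not* physically present in the
fragment, so it contributes no bead and no charge. Bound calcium ions
become +2 beads at the ion sites. All positions are fixed relative to
each other: the body moves only by whole-molecule translations and
rotations.

The 2.5 Å radius is smaller than most residues' physical size; it is
chosen to give realistic *contact separations between charges*, which is
what matters for a purely electrostatic model.

**Flexible chains.** Sequence-built chains use 2.0 Å beads (allowing
realistic bonded distances), consecutive beads joined by a harmonic bond
\(w_b = k_h (R_b - R_{eq})^2\) with \(k_h = 0.76\,k_BT/\text{Å}^2\) and
\(R_{eq} = 4.1\) Å, plus the two terminal charge beads. Non-bonded bead
pairs interact through the screened Coulomb term below and a weak
Lennard-Jones well \(4\varepsilon_{nb}[(\sigma/r)^{12}-(\sigma/r)^6]\)
with \(\varepsilon_{nb} = 0.05\,k_BT\); nearest bonded neighbors are
excluded from both (they interact through the bond), 1–3 pairs are
included.

**Electrolyte and pair electrostatics.** The solvent is an implicit 1:1
electrolyte (default 0.025 M, εr = 78.5, T = 298.15 K — the temperature
is not dictated by the model and is fixed at standard laboratory
conditions, consistent with the chosen permittivity). Charges interact
through the size-corrected Debye–Hückel potential

$$ w_{ij} = \frac{l_B z_i z_j}{r_{ij}(1 + \kappa\sigma_{ij})}
   e^{-\kappa (r_{ij}-\sigma_{ij})}, \qquad r_{ij} \ge \sigma_{ij}, $$

with a hard core (+∞) inside the contact distance σij (sum of radii),
Bjerrum length \(l_B \approx 7.14\) Å and Debye length
\(\kappa^{-1} \approx 19.2\) Å at the default conditions.

**Charged wall and nanoparticles.** The substrate is a uniformly charged
plane at z = 0 described by Gouy–Chapman theory:
\(w_{GC} = 2 z_i k_BT \ln[(1+\Gamma_0 e^{-\kappa r_s})/(1-\Gamma_0
e^{-\kappa r_s})]\) with \(\Gamma_0 =
\tanh(\tfrac12\sinh^{-1}(\rho/\sqrt{8k_BTc_0\varepsilon_0\varepsilon_r}))\).
\(r_s\) is read as the distance from the surface plane to the bead
*center*, with a hard wall at one bead radius. Nanoparticles attached to
the wall (hexagonally packed, resting on the substrate) or free in
solution carry the point charge \(Z = 4\pi R^2 \rho\) at their centers —
the same surface charge density as the substrate — and interact with
beads through the pair potential above with \(\sigma = R + r_{bead}\).
The wall's field is taken as unaffected by attached particles (terms are
simply additive; the area shadowed by particles is not subtracted). No
hydrophobic or van der Waals protein–surface attraction is included: the
model isolates the electrostatics.

The box is periodic in x and y (minimum image convention), hard-walled
in z. Because every interaction decays with the Debye length, no Ewald
summation is needed; this is a documented limitation for very weakly
screened conditions. No interaction cutoff is applied by default (a
cutoff flag exists).

## Sampling

Metropolis Monte Carlo with acceptance \(\min(1, e^{-\Delta E/k_BT})\).
Rigid bodies use whole-body translations and rotations about the center
of mass (axis uniform on the sphere, angle uniform in ±max). Flexible
chains use the classic polymer move set: crankshaft (rotate the beads
strictly between two randomly picked beads about their connecting axis),
pivot (rotate one end segment about the same kind of axis) and
single-bead translation. All proposals are symmetric. A *perfectly
collinear* chain is a fixed point of crankshaft and pivot moves (every
bead lies on the axis), so chain runs must include bead translations
and/or start from a non-collinear configuration;
`initialize_configuration()` grows a random walk at the equilibrium bond
length.

Default step sizes are 5 Å / 0.3 rad (rigid) and 1 rad / 2 Å (chains);
for adsorption runs in tall boxes the move set is augmented with
occasional large translations (hundreds of Å) so the molecule crosses
the box diffusively in reasonable time — these are ordinary symmetric
proposals and leave the sampled distribution unchanged. Optional step
auto-tuning toward 30–50% acceptance operates during equilibration only,
never in production, to preserve detailed balance.

Energies are tracked incrementally (only terms involving moved beads are
recomputed; segment rotations preserve within-segment distances) and
validated against a full recompute at fixed intervals; the maximum
drift is recorded in every result and is at machine precision in the
test suite. Runs are bit-reproducible given the schedule seed, and every
run summary embeds the complete parameter set, the physical-constants
table and the seed.

The engine is validated against exactly solvable references: a two-site
toy with a known Boltzmann ratio, a single charged bead above the wall
(sampled density vs. direct quadrature of \(e^{-w_{GC}(z)}\), χ² test),
uniform sampling above an uncharged wall (KS test), and the
freely-jointed chain limit (\(\langle R_{ee}^2\rangle/\langle
R_g^2\rangle = 6N/(N+1)\), \(\langle R_{ee}^2\rangle = (N-1)b^2\)).

## Observables

* **Free-energy profile** \(F(z) = -\ln P(z) + C\) from the
  center-of-mass height histogram (2 Å bins by default), anchored so the
  mean over the outer 20% of the sampled range is zero; empty bins are
  masked rather than interpolated.
* **Orientation.** The molecule's direction is its principal gyration
  axis (largest-eigenvalue eigenvector of the mass-weighted gyration
  tensor) — a convention that is symmetric under end-swap and robust for
  rod-like bodies. Reported as \(|\cos\theta|\) to the surface normal
  (0 = lying flat, 1 = upright) or to the line joining the nanoparticle
  center and the protein center of mass.
* **g(r)** around a single nanoparticle: center-of-mass counts per
  spherical shell outside the particle surface, normalized by the
  overall concentration of the (single) molecule in the confinement
  volume — not by a local bulk estimate, which is unreliable when nearly
  everything is adsorbed.
* **Adsorbed fraction.** "Adsorbed" requires a definition; here a
  snapshot is adsorbed when the minimum bead-to-surface separation is
  within two Debye lengths (≈38 Å at 0.025 M), which covers the width of
  the screened-electrostatic well. The cutoff is a parameter and is
  reported with every number. Absolute adsorbed fractions also scale
  with the box height (they compare bound volume to total volume), so
  they are comparable only within a fixed geometry; trends across
  surface charge, particle size and spacing are the meaningful output.
* **Polymer descriptors.** Mass-weighted \(R_g\); end-to-end distance
  between the first and last residue beads (terminal charge beads
  excluded); shape factor \(R_{ee}^2/R_g^2\) (6 for a Gaussian chain, 12
  for a rigid rod; exactly \(12(N-1)/(N+1)\) for a straight N-bead
  chain). Statistical errors by block averaging (10 blocks, ±1 SE).

## Synthetic reference structures

Because the package must be testable without downloading crystal
structures, the `make_*` generators produce fixtures with known ground
truth: PDB files with resolved and unresolved (SEQRES-only) residues,
bound ions and multiple chains; freely-jointed chains; and charged rigid
rods. `fibrinogen_mimic_rod()` is a synthetic stand-in for the
fibrinogen main body: 90 beads at 5 Å spacing (a 445 Å rod), net charge
−8, with near-neutral charge-rich ends whose *positive* charges sit at
the outermost tips and a distributed negative middle. This reproduces,
at toy scale, the adsorption phenomenology that drives the real
molecule: end-on anchoring to negative surfaces through the positive
tips, stronger adsorption at higher surface-charge magnitude, more
adsorption on nanoparticle-decorated than on flat surfaces, and a mean
orientation that tilts away from the surface as the curvature grows.

Two features of the real system are *not* reproducible with a collinear
uniform-bead rod, and tests of them are expected to fail by design of
the geometry rather than by implementation error. First, the wall
potential is exactly linear in the bead charge, so a straight rod lying
flat presents its net charge (−8) to the wall and is repelled: the
flat-lying orientation mode of the real main body (which buries positive
patches against the surface while negative residues sit higher, using
its three-dimensional thickness) cannot be the energy minimum for any
collinear charge pattern. Second, the non-monotone dependence of
adsorbed amount on nanoparticle lattice spacing relies on a thick
molecule being sterically blocked from the gaps between touching 40-nm
spheres; the thin mimic rod threads those interstices, so its adsorbed
fraction is maximal at the *smallest* spacing. Both limitations are
properties of the deliberately minimal rod geometry, documented here so
that passing and failing checks are interpreted correctly.

## Problem sizes and numerical choices

The shipped test suite and the reproduction script run at "toy scale",
chosen as the smallest sizes at which every qualitative result is
resolved beyond three standard errors: the 90-bead mimic rod; cells of
600–1560 Å side with the default height 1500 Å (tall enough that a
field-free bulk region exists for the free-energy zero); hexagonal
lattices at one commensurate repeat (2 particles per cell);
4 × 10³ equilibration and 5 × 10⁴ production sweeps for rigid adsorption
runs; 10⁴ freely-jointed chains for ensemble averages. Energy
bookkeeping is validated to <10⁻⁸ kBT against full recomputes;
hard-core violations are checked over entire sample sets. Ties at bin
edges follow `findInterval` (right-closed); degenerate principal axes
(sphere-like bodies) raise an error instead of returning an arbitrary
direction.

SASA, used only for structure characterization (the hydrophobic surface
profile), is Shrake–Rupley with 960 golden-spiral points per heavy atom,
probe 1.4 Å and Bondi radii, normalized per residue by the Tien et al.
Gly-X-Gly maxima; a ≥20% relative-accessibility threshold defines
"surface" residues. Different SASA dialects shift individual residue
values by a few percent, so profile *shapes*, not absolute values, are
the supported output.

## Known limitations

Single molecule per box (no crowding or multilayer adsorption); no
explicit ions, image charges or van der Waals surface terms; the rigid
body has no internal flexibility (the real molecule has hinge bending);
main body and αC-chains are simulated separately, not as one connected
molecule; glycans and alternate conformations are ignored. Absolute
adsorbed fractions depend on the box height and the adsorption cutoff
and are reported only together with both.
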