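---
title: "Grid solvation thermodynamics and automated water placement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid solvation thermodynamics and automated water placement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gistwater)
```

## The problem

Quantum chemical *microsolvation* treats a solute together with a small
number of explicit solvent molecules inside an implicit-solvent continuum.
The recurring questions are how many waters to include, where to put them,
and how to orient them.  `gistwater` answers them the way hydration-site
analysis does in biomolecular simulation: run a molecular-dynamics
simulation of the rigid (restrained) solute in explicit water, discretise
the solvent statistics onto a three-dimensional grid, compute per-voxel
solvation thermodynamics (grid inhomogeneous solvation theory, GIST), and
then condense the density and free-energy grids into individual, oriented
water molecules ranked by their solvation free energy.  The selected
solute--water clusters are exported as PDB files for quantum chemical
follow-up.

The package does not run molecular dynamics.  Its input is a multi-model
PDB trajectory of one restrained solute plus rigid 3-site waters, with a
CSV sidecar carrying the per-atom force-field parameters (partial charge,
Lennard-Jones sigma/epsilon, solute flag) that a PDB cannot hold.

## Per-voxel thermodynamics

The analysis grid is a cube (default 30 Å edge, 0.5 Å spacing) of
half-open voxels; a water belongs to the voxel containing its oxygen.
With `N_r` the number of (water, frame) observations in voxel `r` and
`N_f` the number of frames, the total solvation free energy is the sum of
voxel contributions

    dA_solv = sum_r dA_r * N_r / N_f ,
    dA_r    = dE_sw + dE_ww - T (S_trans + S_orient),

all per water observation.  The occupancy weighting `N_r/N_f` makes the
empty-grid and single-permanent-water limits exact.

**Energies.**  `E_sw` sums the Coulomb plus 12-6 Lennard-Jones
interactions (Lorentz--Berthelot combination, minimum image when a box is
present) of a water's three sites with all solute atoms.  `E_ww` is half
the interaction with all other waters of the same frame, so every pair is
counted once globally.  Energies are referenced to the neat liquid:
`E_sw`, `S_trans`, `S_orient` reference to zero, and the bulk per-water
water--water energy (`eww_ref`, default -9.533 kcal/mol for TIP3P-like
water) is subtracted.  Because the per-observation `E_ww` carries the 1/2
factor, `eww_ref/2` is subtracted per observation by default so that
bulk-like voxels read approximately zero; full subtraction is available
via `gist_params(eww_ref_mode = "full")`.

**Entropies.**  Both terms are first-order nearest-neighbour (NN) Shannon
entropy estimates, `R (gamma + mean log(N_f * v_i))`, where `gamma` is
Euler's constant (the estimator's asymptotic bias correction) and `v_i`
the volume claimed by observation `i`'s nearest neighbour:

* translational: `v = rho0 * (4 pi / 3) * d^3` with `d` the distance to
  the nearest water oxygen of any *other* frame (the collapsed-ensemble
  convention; the `N_f` factor inside the logarithm normalises for the
  superposition of frames).  For uniform bulk at the reference density
  `rho0` the estimate converges to zero -- Euler's constant exactly
  cancels the expectation of the log NN volume of a Poisson process --
  which the test suite verifies.
* orientational: `v = domega^3 / (6 pi)` with `domega` the smallest
  quaternion angular distance `2 acos(|q_i . q_j|)` to another observation
  in the same voxel.  Water orientations are body frames built from the
  O->H bisector and the H--H axis, with the two hydrogens put in a
  canonical (lexicographic) order so the C2v symmetry cannot split one
  physical orientation into two quaternions.

Numerical guards: a voxel with fewer than two observations has undefined
orientational entropy (set to 0 with a warning); coinciding orientations
would make the logarithm diverge, so angular distances are floored at
1e-3 rad and the floored count reported.  When the trajectory has an
orthorhombic box, NN searches use minimum-image distances, which removes
the boundary bias of an open search on a grid that spans the whole box.

Defaults follow standard practice: T = 300 K, R = 1.987204e-3
kcal/(mol K), Coulomb constant 332.0636 kcal Å/(mol e²), rho0 = 0.0334
molecules/Å³ (TIP3P reference; the density is not printed alongside the
other reference settings, so the standard GIST value is adopted).

## Water placement

Oxygens are placed by greedy density allocation: repeatedly select the
voxel with the highest residual occupancy count (ties: lexicographic
voxel index), place an oxygen at that voxel's centre, and subtract one
water's worth of counts -- the *occupancy quantum*, `N_f` counts, a water
present every frame -- drawing first from the selected voxel and then
from its neighbours in order of increasing centre-to-centre distance.
The loop stops once 95% (configurable) of the total in-grid counts is
allocated.  All accounting is exact integer arithmetic, so
`allocated + residual = initial` holds exactly and the loop always halts.
Each placed water inherits a density-weighted free energy: the `dA_r` of
its contributing voxels weighted by the fraction of the quantum drawn
from each.

Protons are assigned from the trajectory itself.  For each placement, the
protons of exactly those observations whose oxygen was drawn into it are
binned on a 0.1 Å fine grid, after discarding protons outside a radial
shell of 0.8--1.1 Å around the placed oxygen (bracketing the rigid
0.9572 Å bond plus the sub-voxel offset of the oxygen placement).  The
first proton goes to the most occupied fine voxel; for the second, only
voxels keeping the H-O-H angle within 5° of the model's equilibrium angle
(104.5°) are eligible, and the most occupied of them wins.  The
representative proton position is the occupancy-weighted centroid of the
winning voxel rather than its geometric centre, so a noiseless input
reproduces the geometry exactly, and the final angle satisfies the window
*by construction*.  O-H bond lengths are not re-normalised to the model
value by default.  When the shell captures no protons, or no occupied
voxel falls inside the angular window, the water is completed with ideal
geometry (the O->H1 direction rotated by the equilibrium angle within the
plane spanned by O->H1 and the mean observed proton direction) and
flagged `fallback`.

Ranked waters are classified by their oxygen's minimum distance to any
solute atom: `near` (< 3 Å, first shell at hydrophilic sites), `mid`
(3--6 Å) and `bulk` (>= 6 Å), boundaries going outward.  Sorting is by
ascending free energy with distance, then placement order, as
tie-breaks.  The chart CSV, placement table, cluster PDB and OpenDX grids
are mutually consistent exports of the same state.

## The synthetic ground-truth generator

`synthetic_spec()` + `generate_trajectory()` emulate the statistical
structure the analysis assumes, with known truth: a fixed 3-atom polar
toy solute, hydration hotspots (per-frame occupancy probability `p`,
isotropic positional noise `sigma`, a reference orientation with
random-axis Gaussian angular noise) and a uniform bulk background at the
model's reference density in a cubic box (default 12.4 Å edge, about 60
waters per frame, 200 frames).  Design choices worth knowing:

* The water count is constant across frames (as in an NVT ensemble, and
  as a multi-model PDB requires): the bulk contingent is
  `round(rho0 * accessible volume)`, with the accessible volume estimated
  by seeded Monte Carlo around the solute's 2.4 Å exclusion region, and a
  hotspot water that is unoccupied in a frame becomes an extra bulk water
  for that frame.  Voxel occupancies remain Poisson-like.
* The 2.4 Å exclusion radius applies between *all* waters, not only
  against solute and hotspots; without it near-coincident waters produce
  astronomically large Lennard-Jones energies that poison every energy
  mean.  Cross-frame NN statistics are unaffected (frames are
  independent), so the bulk zero-entropy limit is preserved.
* Generation is fully seeded and bit-reproducible, and restores the
  session RNG state.

What the fixture does *not* emulate: hydrogen-bond networks and liquid
structure.  Bulk orientations are uniform, so the synthetic solvent is
far less cohesive than real TIP3P water and fixture `dA` values sit well
above what real simulations give (the `eww_ref/2` subtraction then acts
as a constant offset).  Passing tests therefore validate the estimators,
the bookkeeping and the placement geometry -- not force-field physics.

## Validation, problem sizes, known limitations

The test suite checks every search and accumulation step against
brute-force oracles (all-pairs NN searches, literal greedy allocation,
loop histograms, 9-term pair sums), the decomposition identity
`dA_r = dE_sw + dE_ww - T dS` to 1e-10, exact count conservation, the
Poisson zero-entropy limit of bulk water (within three standard errors),
and hotspot recovery on the seeded three-hotspot fixture.  Study-scale
runs use 200 frames with ~63 waters per frame (about 13,000 observations,
a 24³-voxel grid over the box), sizes chosen so a full analysis runs in
seconds on one core; the bulk-entropy check uses 80 frames.

Known limitations:

* Only rigid 3-site waters; flexible solutes, non-water solvents, Ewald
  electrostatics and higher-order (mutual-information) entropy terms are
  out of scope.
* Orientation assignment is resolution-limited at small frame counts.
  With positional hotspot noise of 0.3 Å, each proton lobe spreads over
  hundreds of 0.1 Å fine voxels; at 200 frames the modal voxel holds only
  2--3 protons, so the max-occupancy choice carries angular noise of the
  order of the lobe width (~20°).  Reliable orientation recovery needs
  either tightly localised orientations or trajectory lengths in the
  thousands of frames -- the regime the fine-grid algorithm was designed
  for.  The angle *window* is unaffected (it holds by construction), as
  is oxygen placement.
* The assigned positions are time-averaged: a site dominated by several
  distinct poses is represented by its strongest one only.

## A minimal run

```{r example, eval = FALSE}
spec <- synthetic_spec(n_frames = 200, seed = 1)
traj <- generate_trajectory(spec)
cfg  <- gw_config()

gist <- gist_analysis(traj, cfg)              # bin + energies + entropies
pw   <- place_waters(gist, traj, cfg)         # place, orient, rank
head(pw$ranking$waters[, c("rank", "delta_a", "distance", "class")])

export_chart(pw$ranking, "chart.csv")
select_and_write_cluster(pw$ranking, traj, "cluster.pdb", n = 6)
```

The same pipeline is scriptable through `cmd_synth()`, `cmd_gist()`,
`cmd_place()`, `cmd_rdf()` and `cmd_select()`, or from a shell via
`inst/cli/gistwater.R`.
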