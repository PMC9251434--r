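---
title: "Conformational landscapes, pores and peptide release of a barrel-shaped assembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational landscapes, pores and peptide release of a barrel-shaped assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

```{r}
library(corelandscape)
```

## The scientific problem

Large protein machines such as the 26S proteasome do not adopt a single
structure: cryo-EM datasets capture a population of particles spread over a
continuum of conformations. Two questions recur when such ensembles are
analysed. First, what are the dominant collective motions (lid rotation and
tilt of the regulatory particle, compression of the core barrel, swings of
peripheral subunits), and how large are they? Second, how is the particle
population distributed over those motions -- which states are stable, what
fraction of particles occupies each, and how high are the free-energy
barriers between them? A third, downstream question concerns function: once
the protease has cut its substrate, can the peptide products leave the
barrel through the narrow wall pores fast enough, or does the machine need
to open its axial gate?

`corelandscape` implements this analysis chain as reusable, tested R code,
exercised end to end on a synthetic coarse-grained ensemble whose ground
truth is set by construction. The package does not process images or maps;
it starts where image processing ends, at per-particle conformational
coordinates and bead-level structural models.

## The surrogate assembly

`build_assembly()` constructs a coarse-grained barrel: four stacked rings
(two outer alpha rings, two inner beta rings) forming a closed cylindrical
wall with caps, plus a regulatory particle (lid, ATPase base, an RPN1
cluster and an RPN11 marker bead) docked at the proximal face. The barrel
axis is +z and the proximal face sits at low z. Defaults -- 55 Å outer
radius, 15 Å ring spacing (60 Å barrel height), 10 Å wall thickness,
2.5 Å beads on a 2.5 Å wall lattice -- are a deliberately generic
proteasome-like scale chosen so that gates and drilled pores fall in the
4--17 Å measurement regime. Every wall and cap ring carries a bead count
divisible by seven, so each core ring is exactly sevenfold symmetric; the
suite verifies self-coincidence under a 2π/7 rotation to below 1e-6 Å.

Two kinds of openings are configurable. The distal cap can carry an
annular gate of any inner diameter (0 closes the shell). Wall pores are
drilled as elliptical prisms along the radial direction and then lined with
rim beads placed exactly on the ellipse offset by `bead radius + probe
radius`, so the *free* channel has the requested axes by construction:
the largest inscribed sphere at the constriction has diameter `d_short`
and the longest cross-section chord is `d_long`. This is what makes
parameter-recovery tests meaningful -- the constructed truth is exact,
and any deviation is attributable to the measurement pipeline.

Each bead carries a pseudo-residue drawn once (seeded) from a fixed
composition -- 10% each of D, E, K, R, 30% hydrophobic, 30% polar-neutral
-- so pore-lining chemistry exercises both the formal-charge and the
hydropathy classification.

```{r}
model <- build_assembly(assembly_config(gate_diameter = 14))
model
```

## Modes and their recovery

`define_modes()` returns the default catalogue of four rigid-body modes:
lid rotation about the barrel axis pivoted at the RPN11 marker (0--35°),
lid tilt about a perpendicular axis (4--10°), compression of the two
distal core rings along the axis (0--12 Å), and the RPN1 swing
(1--25 Å). The tilt pivot is placed at the centroid of the gap between
lid and base -- the description "free space between the ATPase and the
lid" fixes a region, not a point, and the surrogate makes no fidelity
claim about that choice. An amplitude of exactly zero is always accepted
as "mode not engaged", including for modes whose nominal range starts
above zero; this keeps the identity conformer constructible.

`decompose_rigid_motion()` recovers the motion of a group between two
conformers by Kabsch superposition followed by a screw-axis
decomposition: rotation angle from the trace, axis from the skew part,
translation along the axis, and the pivot reported as the axis point
closest to the group centroid (the unique stable representative of the
screw line). Constructed motions are recovered to numerical precision;
the property suite round-trips random pivots, axes and angles at 1e-6.
All motion is reported relative to the alignment anchor -- by default the
two proximal core rings -- and labelled as such.

`classify_mode()` applies fixed taxonomy cut-offs (2° rotation threshold,
0.5 Å displacement threshold, 15°/75° axis cones). These numbers are
artifact choices: the motions they separate are named in the literature,
but no published cut-offs exist. `principal_modes()` is a plain
mean-centred PCA (exact SVD via `stats::prcomp`; at a few thousand beads
no randomised solver is warranted). Note that a pure rotation traced over
a wide arc is intrinsically rank-2 in Cartesian coordinates (cosine and
sine components), so "one constructed mode implies one dominant
component" holds exactly only for translational modes; the tests use
translations for that check.

## The free-energy landscape

`bin_particles()` histograms particles over two mode coordinates (default
30 × 30 bins, a package default); `boltzmann_invert()` converts occupancies to
energies via `E_i = -ln(N_i / N_max)` in kT. Three numerical choices
matter and are deliberate:

* **No pseudocounts, reference at the modal bin.** The Boltzmann
  conversion only ever uses relative populations.
* **Empty bins are masked, not set to a large energy.** An unsampled bin
  carries no information; treating it as impassable gives barrier
  estimates honest "at least" semantics when basins are disconnected
  (`find_barrier()` then reports the maximum observed energy with an
  explicit `lower_bound` flag).
* **8-connectivity** for both watershed basins and barrier paths, the
  standard raster-watershed convention.

`find_basins()` is an ordered-flooding watershed with persistence
merging: catchments shallower than `min_depth` (default 1 kT) below their
first connecting saddle are absorbed into their deeper neighbour. Poisson
noise in sparsely sampled regions otherwise seeds one- or two-bin basins
of depth ~ln 2; the designed basins of the default surface are several kT
deep and unaffected. Noise-free analytic grids can be analysed with
`min_depth = 0`.

`find_barrier()` computes the minimax barrier -- over all 8-connected
paths of non-empty bins, the minimum of the path maximum, minus the
starting basin's minimum -- with a bottleneck variant of Dijkstra's
algorithm. The test suite proves it equivalent to exhaustive simple-path
enumeration on all grid shapes up to 4 × 4.

## The synthetic two-basin surface

`two_basin_surface()` is the generator the recovery tests sample from. It
places three states on the (lid rotation, compression) plane: a resting
basin (58% of particles), a rotated basin (35%) and a compressed basin
(7%) at the extreme of the compression coordinate, with both transition
saddles at 5.6 kT above the resting minimum. Design points worth knowing:

* **Fraction control is by per-basin mass rescaling**, not by tuning well
  depths, so the ground-truth fractions are exact. Rescaling shifts each
  basin's effective energy by a constant, which would silently move both
  the realised saddle heights and the watershed divides; the constructor
  therefore (a) balances the remote well depths so their natural masses
  match the targets (making the rescale a near-identity), (b) iterates
  the ground-truth basin labels to the watershed fixed point of the
  effective energies, and (c) calibrates the two saddle plateaus by a
  deterministic fixed-point loop until the realised minimax barriers on
  the final grid equal the requested value to 1e-8.
* **The saddles are short flat plateaus (about two grid columns) notched
  0.7 kT above their approach ramps**, and the valleys narrow to about
  one bin at the crossing. This concentrates the transition flux in a
  few well-populated bins, which is what makes the barrier recoverable
  from 1e5 particles: the saddle bins then hold enough counts that the
  log-ratio estimator has a standard deviation near 0.1 kT. These are
  generator design choices, frozen before the recovery tests were run.
* **Bins more than 10 kT above the floor are forbidden** (zero
  probability) rather than capped at a finite energy, so stray
  single-count fringe bins do not seed spurious basins.
* Amplitudes for the two modes not on the landscape axes (tilt, RPN1
  swing) are sampled independently and uniformly over their ranges, as
  nuisance coordinates.

What the generator emulates is the *population structure* of a particle
ensemble: multinomial sampling of Boltzmann-weighted bins with exact
per-state masses. What it does not emulate: alignment and classification
errors, projection-direction bias, defocus-dependent particle quality,
model misspecification of the mode coordinates themselves, or any
correlation between the landscape axes and the nuisance motions. Passing
recovery tests therefore demonstrate that the *analysis chain* is
unbiased at realistic counting statistics, not that real micrographs
would yield these numbers.

```{r}
surface <- two_basin_surface()
particles <- sample_particles(surface, 1e5, seed = 20220311)
grid <- particles |> bin_particles(c(30, 30)) |> boltzmann_invert() |>
  find_basins(min_depth = 1)
state_fractions(assign_states(particles, grid))
autoplot(grid)
```

## Pore and gate geometry

`rasterize_assembly()` marks voxels within `bead radius + probe` (probe
1.4 Å, a water-sized probe; default spacing 0.5 Å) of any bead centre.
`detect_pores()` finds 6-connected solvent components inside the wall
shell that touch both the interior cavity and the exterior, excluding the
axial gate corridor so the gate is reported separately, as is
conventional. Pore inventories in the literature are typically read off rendered
surfaces by eye, with no algorithm stated, so the grid/flood-fill
definition here is this package's own operational definition rather than
a reproduction of any particular procedure.

Diameters are refined against the exact bead geometry rather than read
from voxels: `d_min` is twice the percolation bottleneck of the channel
(union-find over voxels in decreasing clearance order, then a continuous
in-plane maximisation of the clearance at the bottleneck), and `d_max` is
the longest chord of that constriction cross-section perpendicular to the
channel direction (ray marching at 0.1 Å). Both converge well below one
voxel on drilled-channel fixtures; the suite checks rotation invariance
and exact pore counts for multi-channel constructions. One caveat worth
knowing: a channel constructed at exactly the 7 Å release threshold
measures a few hundredths of an Ångström above it (the rim bead
discretisation bulges between beads), so the strict `> 7 Å` filter is
exercised with constructions clearly on either side of the boundary.

`measure_gate()` reports the diameter of the largest solvent circle in
the distal cap plane centred on the barrel axis, computed analytically
from probe-inflated bead distances (the voxel grid adds nothing for an
axis-centred measurement). Lining chemistry uses beads whose surface lies
within 4 Å of a channel voxel; formal charges are D/E = -1, K/R = +1, H
neutral (neutral pH), and hydropathy is the Kyte--Doolittle mean, with
`> 0` labelled hydrophobic -- matching the binary hydrophobic/hydrophilic
colouring conventions of surface renderings.

## Release kinetics

The hindered-diffusion model treats a peptide of length `L` residues
crossing an inert pore of thickness `x` as free one-dimensional diffusion
slowed by a factor `L²`:

* `tau_free = x² / (2D)` -- about 167 ns for `x` = 1 nm and
  `D` = 3 µm²/s (a literature estimate for a typical short product);
  the commonly quoted round figure of 160 ns is the same quantity, and
  the package reports the exact value.
* `tau_pore = L² · x² / (2D)` -- about 16.7 µs for a 10-mer.
* One product of length `L` is generated every `L / v` seconds at a
  translocation speed of `v` = 40 residues/s, i.e. 0.25 s for a 10-mer
  -- four orders of magnitude slower than pore release
  (`floor(log10(ratio))` = 4). The comparison is per product, not per
  residue: only the per-product reading yields four orders of magnitude,
  which fixes the intended interpretation.

Attractive pore linings would slow release massively; the package exposes
this only as a warning flag (`release_kinetics(mean_hydropathy = ...)`)
when the lining's hydropathy exceeds a configurable threshold, and
deliberately fits no adsorption model.

```{r}
release_kinetics(L = 10, x = 1, D = 3, v = 40)
```

## The pipeline

`run_pipeline(default_config(), out_dir)` chains every stage -- assembly,
mode catalogue, surface, sampling (1e5 particles), ensemble writing
(25 conformer PDB models), PCA, rigid-motion recovery of every mode
endpoint, landscape/basins/all pairwise barriers, pore and gate geometry
(on the core barrel alone, at 0.5 Å), kinetics -- and writes per-stage
TSV tables, a YAML config echo, a timestamped log, and a flat key-value
summary. All randomness flows from the single config seed; two runs with
the same config produce byte-identical tables. Stage failures abort with
the stage name and leave a `FAILED` marker beside any partial outputs.
Where the two measured saddles differ slightly, the pipeline reports all
pairwise basin barriers rather than interpreting which pair a single
published figure refers to.

Problem sizes throughout (1e5 particles, 30 × 30 bins, 0.5 Å grids on a
55 Å barrel, 25-conformer PCA ensembles) were chosen as the smallest at
which the statistical checks above are stable; they run in seconds to a
couple of minutes on a single core.

## Known limitations

* The surrogate geometry is generic: nothing about the specific subunit
  architecture, the HbYX-mediated gate regulation, or inter-ring register
  is modelled; groups are rigid bodies.
* The landscape is two-dimensional by construction; real heterogeneity
  mixes many coordinates, and projecting onto two can merge or split
  basins.
* Barrier estimates inherit counting noise in the saddle bins
  (~0.1 kT sd at the default settings) and a small positive bias from
  taking a maximum over plateau bins; both shrink with particle count.
* Pore chemistry classification is a two-class summary of a coarse
  pseudo-residue decoration; it exercises the bookkeeping, not
  electrostatics.
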