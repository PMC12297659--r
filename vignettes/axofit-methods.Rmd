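---
title: "Identifying proteins in axoneme density maps: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying proteins in axoneme density maps: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

axofit implements the desk-scale computations behind visual-proteomics
identification of proteins in subtomogram-averaged cryo-ET maps of the
sperm axoneme central apparatus, together with the lattice statistics used
when interpreting such maps. This vignette explains the models, the
parameters that matter, and the design decisions that were genuinely open.

## The identification problem

A local density map (5–20 Å resolution) shows an unassigned blob. The
candidate pool is large — every protein detected by mass spectrometry in
the organelle. The computational core is: for each candidate predicted
structure, find the best rigid placement in the density and score how
specifically it explains the map; then rank candidates. Three stages:

1. **PAE partitioning.** Predicted models are only locally reliable. The
   predicted aligned error (PAE) matrix is block-structured: low mutual
   error within a rigid unit, high between units. We partition each chain
   into rigid units and fit units independently, which avoids fitting a
   hinge-bent prediction as one wrong body.
2. **Rigid-body fitting.** Exhaustive search over a rotation grid with an
   FFT translational scan of a locally normalized cross-correlation.
3. **Scoring.** A global z-score of the best correlation against the
   candidate's own scan distribution, and size-binned local z-scores that
   measure region-level match quality against comparable regions across
   all candidate fits.

## PAE partitioning

The PAE matrix $P$ (Å) need not be symmetric; we symmetrize optimistically,
$S_{ij} = \min(P_{ij}, P_{ji})$, on the grounds that one confident
direction is evidence of mutual rigidity. Residues become graph nodes with
weights $w_{ij} = \max(0, 1 - S_{ij}/\tau)$; $\tau$ (default 10 Å) is the
error level at which a residue pair stops counting as mutually placed.
Units are communities under greedy agglomerative modularity maximization
at resolution $\gamma$ (default 1) with a fixed merge order (ties break
lexicographically), so the partition is fully deterministic. Clusters
smaller than `m_min` (default 20 residues — smaller fragments carry too
few atoms to fit) are merged into their strongest-connected neighbour, or
declared flexible when unconnected. Units may be sequence-discontiguous:
rigidity in error space does not respect sequence contiguity (domain
inserts are common in ASH-domain proteins).

A deterministic greedy optimizer was chosen over stochastic community
detection deliberately: reproducibility is worth more here than the last
few percent of modularity, and planted-block recovery (the regime PAE
matrices actually present: gaps of tens of Å between intra- and
inter-unit error) is exact for any reasonable optimizer.

## Density simulation and the correlation scan

Each atom contributes an isotropic Gaussian whose FWHM equals the stated
resolution ($\sigma = \mathrm{res}/2\sqrt{2\ln 2}$), truncated at
$4\sigma$ (<0.01% mass loss). Conventions for "resolution" differ across
packages; this one is stated once and tested via the closed-form integral
$(\sum_a w_a)(2\pi\sigma^2)^{3/2}$.

The translational scan computes, at every integer-voxel offset with the
moving box fully inside the target, the Pearson correlation between the
moving map — within its fraction-of-max auto-mask (level 0.1) — and the
overlapping target region. Masked local normalization makes the score
invariant to affine intensity changes of the target and insensitive to
neighbouring density outside the mask; a plain overlap integral is
neither. The scan is computed with three 3-D FFTs per orientation (a
packed-complex transform of mask and masked values against precomputed
target spectra) and is defined to equal — and is tested against — the
direct sliding-window Pearson correlation.

Rotations come from a deterministic Hopf-style grid (Fibonacci axes ×
uniform in-plane angles, identity prepended) whose empirical covering
radius stays below $1.5\delta$; $\delta$ defaults to 15°. Kept fits pass
non-maximum suppression: a pose is suppressed only when a better kept pose
is within `nms_translation` *and* `nms_rotation`, so distinct orientation
basins at the same location survive.

**Refinement matters.** At $\delta = 15$–30° the best grid pose can sit
tens of degrees from the optimum, where the correlation has lost most of
its discriminating power. Coordinate-ascent refinement (six pose
parameters, shrinking steps, monotone by construction) recovers the basin
optimum; `run_identify()` refines kept fits by default. Because α-helices
at ~8 Å are nearly apolar rods, helix bundles have well-scoring flipped
placements; refining several NMS-diverse basins (rather than only the
single best grid pose) is what reliably reaches the true basin.

## Scoring and ranking

All scanned correlations of a candidate are Fisher-transformed; the global
z is the transformed best correlation standardized by that distribution's
mean and sd. The attached tail probability is the normal upper tail of the
z — a heuristic calibration, documented as such: the true null of a
correlation scan over a quasi-continuous pose space is not normal, and
ranking uses z, never p.

Local z-scores tile the fit's overlap mask into cubes (default edge 8
voxels; tiles with fewer than `v_min = 20` occupied voxels are dropped),
score each tile by local correlation, and standardize against cohort
regions of comparable size — within ±25% relative, the realization chosen
for "comparable"; any monotone alternative binning is switchable. Two
numerical decisions: a degenerate bin (sd = 0) yields z = 0 (total
ignorance should not rank a region), and each region is excluded from its
own bin (leave-one-out). The latter trades the exact zero-mean-per-bin
property of plain standardization for outlier sensitivity: a badly
mismatched region otherwise inflates its own bin's sd and partially hides
itself, defeating the score's purpose of localizing mismatch.

Candidates are ranked by global z, with ties broken by best correlation,
then mean local z, then candidate id.

## Axoneme lattice statistics

These operations work in nm (conversion from Å happens at module
boundaries, 10 Å/nm).

- `expected_unique_fraction(pick, repeat)` = pick/repeat: picks at 8 nm
  against a 32-nm structural repeat ideally contribute 25% to the
  long-repeat class.
- `dedup_particles` is the greedy first-kept interval removal applied
  before 16-nm and 32-nm reconstructions.
- `pattern_period` returns the minimal period of a spiral layout string
  times the layer spacing (AAAB at 8-nm layers → 32 nm; a single C layout
  → 8 nm).
- `overlap_count(L, s)` = ⌈L/s⌉ copies of an element of length L placed
  every s covering the positions where the stack is deepest (a >32-nm
  protein every 16 nm → 3 copies).
- `classify_occupancy` probes two spherical sites between two tubule
  stand-ins and calls each present when its mean density exceeds the
  background mean by θ (default 3) background sds. Two guards proved
  necessary: probe masks exclude the tubule cylinders (the inter-tubule
  gap is ~10 nm, so probe spheres otherwise overlap the shells' Gaussian
  shoulders), and the background sd is floored at `sd_floor_frac` (default
  1%) of the map maximum, because a noise-free synthetic background has
  sd ≈ 0 and any tail would read as "present".
- `edge_distance` fits each tubule axis as the principal line through
  intensity-weighted slice centroids near a seed and returns inter-axis
  distance minus two radii. The radius is *supplied*, not estimated: the
  field's "edge distance" has no canonical contour definition, so this
  package makes its definition explicit and parameterized.
- `compare_distance_sets` uses Welch's t by default (`pooled = TRUE` for
  the classical equal-variance test) — the safer default when one group is
  visibly more variable than the other.

## The synthetic-data generators

The generators emulate what the analysis assumes, not what a microscope
produces:

- **Toy domains** are backbone-only traces (helix bundle / β-slab /
  confined coil). They are deliberately asymmetric — markedly unequal
  helix lengths, irregular anchor polygons — because near-symmetric
  phantoms make pose recovery ill-posed at these resolutions, and real
  domains are asymmetric. They are also kept compact (longest-helix cap,
  soft coil confinement) so a rotating candidate's bounding box fits the
  scene grids used throughout.
- **Scenes** plant one candidate at a seed-drawn pose in a 48³ (default
  analysis size) grid and add white Gaussian noise scaled to the signal
  sd. White noise is the simplest model consistent with a subtomogram
  *average*; single-particle tomographic noise (missing wedge, CTF) is
  deliberately out of scope, so passing recovery tests demonstrates
  correctness of the search, not robustness to anisotropic artefacts.
- **PAE blocks** draw two-level matrices with optional jitter.
- **Filament tables** pick straight filaments every Δ nm with known phase
  in a longer repeat.
- **Bridge phantoms** hold two parallel Gaussian-ridge cylindrical shells
  (radius 12.5 nm — a 25-nm microtubule — axis spacing 35 nm) with 2/1/0
  connective rods at z = ±8 nm, the spacing of the two bridge densities in
  one 32-nm repeat; subvolumes are 72-nm cubes at 2-nm voxels (the
  geometry does not fit a smaller box). `distance_sd` jitters the
  per-particle axis spacing so group comparisons of measured distances
  have a planted truth.

Every generator is a pure function of its arguments including the seed.

## Problem sizes and numerical choices

The shipped tests exercise: pose recovery on 20 noiseless 48³ scenes at
δ = 15° (refining the top 8 NMS-diverse basins); identification with 1
true + 5 decoy candidates on 20 noisy (relative sd 0.3) 46³ scenes at
δ = 25°; PAE block recovery over 20 seeds; occupancy recovery at n = 1000
phantoms × 10 seeds; and edge-distance recovery with two groups emulating
a stable vs a destabilized bridge (planted edge means 10.34 vs 10.71 nm,
planted distance sds 0.4 vs 1.4 nm; group sizes 100 and 500 — the wider
group needs the larger n for the mean comparison to have power at
α = 0.001). These sizes were chosen so the whole suite runs on one CPU in
well under half an hour while keeping every recovery criterion
statistically meaningful.

Other numerical choices: Fisher transforms clamp |cc| at 1 − 10⁻⁷;
scan denominators below 10⁻⁹·n·mean(B²) yield cc = 0 (flat target
regions); fits tie-break deterministically on (rotation index, offset);
refinement stops when a sweep improves cc by < 10⁻⁴ after step shrinking.

## Known limitations

- No missing wedge, CTF, or B-factor model; no flexible fitting — rigid
  units only; no symmetry-aware search (and no improper rotations: the
  map hand is assumed correct, which real-map users should check).
- The tail probabilities are heuristic; use ranks.
- The MRC reader supports modes 0/1/2, little-endian, and resolves the
  origin as ORIGIN-field-else-NXSTART; deposited maps with exotic headers
  may need conversion first.
- `edge_distance` assumes near-parallel tubules aligned with the grid z
  axis within the per-slice centroid neighbourhood.
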