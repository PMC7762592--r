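---
title: "Predicting tailed-phage capsid architectures from genome length"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting tailed-phage capsid architectures from genome length}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsidkit)
```

## The problem

Tailed phages (*Duplodnaviria*) build icosahedral capsids from HK97-fold
major capsid proteins and pack dsDNA at quasi-crystalline density
(~0.5 bp/nm^3). Strikingly, no tailed phage has been observed with the
smallest icosahedral architectures T = 1 or T = 3, even though encapsulins
and several non-tailed viral families show that the folds and the lifestyle
are compatible with them. If small-tailed phages exist but are rarely
sampled, their genomes should already be hiding in isolate databases and
metagenome assemblies — and because capsid geometry constrains genome
length, genome length alone can nominate candidates. `capsidkit` implements
that chain of reasoning end to end: lattice theory, cage geometry, capsid
allometry, and a genome-length classifier.

## Generalized T-numbers

An icosahedral capsid is indexed by lattice steps `(h, k)` with the classic
triangulation number `T0(h,k) = h^2 + hk + k^2`; the shell holds `60 * T0`
major capsid proteins. Capsid protein lattices are not restricted to the
hexagonal tiling: the trihexagonal, snub hexagonal and rhombitrihexagonal
Archimedean tilings place minor capsid proteins in their secondary polygons
(triangles and squares), enlarging the shell surface by a lattice area
factor while keeping `60 * T0` major capsid proteins. The generalized
T-number is `T_i = alpha_i * T0` with

| lattice | alpha | value |
|---|---|---|
| hexagonal | 1 | 1 |
| trihexagonal | 4/3 | 1.333 |
| snub hexagonal | 7/3 | 2.333 |
| rhombitrihexagonal | 4/3 + 2*sqrt(3)/3 | 2.488 |

The rhombitrihexagonal factor is the exact area ratio of that tiling's unit
cell (one hexagon, two triangles, three squares of unit edge) to the bare
hexagon; it evaluates to about 2.488 and reproduces all downstream
quantities tied to that lattice (T values near 2.49 and 7.46, a predicted
genome mean of 8.94 kbp). Merging all four lattices, the achievable series
begins 1, 4/3, 7/3, 2.49, 3:

```{r}
architecture_table(enumerate_architectures(4))
```

Numerically equal T values from different lattices (e.g. T = 4 from
hexagonal (2,0) and trihexagonal (1,1)) are retained as distinct
architectures, since genome length cannot distinguish the lattice class;
the classifier operates on the deduplicated numeric grid `t_grid()`.

## Cage meshes

`build_cage()` lays the planar tiling over the twenty icosahedron facets
(the Caspar-Klug construction) and returns a closed polygonal mesh. The
construction works on the `(h, k)` geodesic triangulation: unit lattice
triangles are claimed against the Caspar-Klug facet triangle with exact
integer arithmetic — centroids falling exactly on a facet edge are resolved
by an antisymmetric tie-break so that each physical triangle is claimed
exactly once — and folded across facet edges into 3D. The four tilings are
then derived from the welded triangulation: the hexagonal cage is its dual,
the trihexagonal cage its rectification (vertices at edge midpoints), the
rhombitrihexagonal cage its cantellation (corner hexagons at distance
`a/(1+sqrt(3))` from each lattice point, squares on lattice edges), and the
snub cage its snub (corner hexagons at `a/sqrt(7)` twisted by
`asin(1/(2*sqrt(7)))`, the closed-form parameters of the planar snub
tiling; the sign of the twist selects the laevo or dextro enantiomorph).
Hexagons centred on the twelve 5-fold vertices collapse to pentagons
automatically, so every primal cage has exactly 12 pentagons.

```{r}
face_census(build_cage(generalized_t(1, 0, "snub_hexagonal")))
```

At `sphericity = 0` vertices sit on the flat icosahedron facets; at 1 they
are pushed to the circumscribing sphere; intermediate values interpolate
each vertex radius linearly. Two numerical notes. First, faces that
straddle a facet edge (e.g. the hexagons of the hexagonal T = 7 cage or
rhombitrihexagonal squares sitting on a fold) are necessarily bent at
sphericity 0 — exactly as in a folded paper model — so face planarity holds
only for faces contained in one facet. Second, the exact interpolation
used by interactive viewers for their "sphere factor" is not documented;
linear radial interpolation is this package's choice. Coordinates are
emitted deterministically with two opposite 5-fold vertices on the z-axis.
`dual_mesh()` gives the associated Laves-lattice cages, and `write_mesh()`
emits OBJ, OFF or Chimera BILD.

## Capsid metrics

`derive_metrics()` turns a measurement table (one row per cryo-EM capsid:
interior/exterior vertex-to-vertex diameters, sphericities, surfaces,
volumes, genome length) into shell thickness (difference of radii — input
diameters are halved), genome packing density (genome/interior volume,
with exactly 1000 bp per kbp), and per-MCP surface areas (surface divided
by `60 * T0`; by default all surface is attributed to major capsid
proteins, since the apportioning between major and minor proteins is not
standardized — a fraction argument is available). Spearman correlations
against diameter (`correlate_with_diameter()`, two-tailed) and Shapiro-Wilk
normality checks (`test_normality()`) reproduce the screening statistics
used on such tables.

## Allometric models

The central statistical objects are the two power laws
`G(T) = a_G * T^b_G` (genome, kbp) and `D(T) = a_D * T^b_D`
(diameter, nm). `fit_allometric()` follows the original protocol: values
are averaged per distinct T **in linear space first** (this de-biases
oversampled architectures such as T = 7; arithmetic averaging is the
natural reading of "average genome length"), then both axes are logged
base 10 and an ordinary least-squares line is fitted with `lm`. The fit
carries everything needed for standard regression intervals on the log
scale (`residual_sd`, `mean_log10_t`, `sxx`, `df`), which
`predict_interval()` back-transforms with `10^(.)`, giving asymmetric
intervals on the linear scale. Intervals default to the mean response —
the published intervals are described as confidence intervals — with
`new_observation` available; because the per-capsid training table is not
part of the package, interval behaviour is validated by regression
properties (agreement with `predict.lm`, leverage minimum at the centroid,
collapse for noiseless fits) rather than by printed interval bounds.

The published parameters ship as a parameter file:

```{r}
pp <- printed_params()
predict_mean(pp$genome_kbp, c(1, 4/3, 7/3, 2.488, 3, 4))
```

Two conserved quantities anchor the theory: constant packing density makes
genome length scale with volume (`G ~ D^3`) and constant exposed area per
major capsid protein makes T scale with surface (`T ~ D^2`), so
`b_G = 3/2` and `b_D = 1/2`; `theoretical_exponents()` derives both
numerically from capsids constructed under exactly those constraints. The
fitted values (1.47 ± 0.09 and 0.52 ± 0.03) bracket the theory.

## The classifier

`assign_t()` evaluates the genome model on the deduplicated T grid (all
four lattices, capped at T < 40, matching the range over which model
intervals were tabulated) and assigns each genome the architecture with
the nearest model-mean genome length. Design choices: distance is measured
in linear kbp ("nearest average genome length" read literally; a log-space
flag exists for sensitivity analysis), and a length exactly midway between
two means goes to the smaller T (parsimony — never over-predict capsid
size on a tie). The classification boundaries are therefore the arithmetic
midpoints of consecutive model means, which a brute-force scan confirms.
Genomes with assigned T <= 4 are flagged as small-capsid candidates.
`estimate_density()` reports the Gaussian-kernel density of genome lengths
with the rule-of-thumb bandwidth `0.9 * min(sd, IQR/1.34) * n^(-1/5)`
(`bw.nrd0`, the default of R's `density`) on 512 grid points spanning the
data plus three bandwidths, and `find_peaks()` lists its strict interior
maxima.

```{r}
g <- printed_params()$genome_kbp
assign_t(c(11600, 7400, 102000), g)[, c("length_bp", "assigned_t",
                                        "nearest_mean_kbp")]
```

## Synthetic data

Real inputs (RefSeq phage tables, gut-phage contig collections, the
per-capsid measurement appendix) are not redistributable at package scale,
so the `gen_*` generators emulate them:

* `gen_capsid_table()` builds capsid records under the two conserved
  quantities: exterior per-MCP area uniform in 24-35 nm^2, packing density
  uniform in 0.34-0.62 bp/nm^3, diameters from the quasi-spherical
  surface, thickness affine in exterior diameter and clamped to 3-8 nm.
  The defaults — 23 capsids over T = {4, 7, 9, 12, 13, 16, 27} with T = 7
  oversampled (replicates 3, 7, 3, 3, 3, 2, 2) and lognormal noise of
  0.05 log10 units on diameters (one shared factor, preserving interior <
  exterior ordering) and genome — mirror the size and composition of the
  characterized-capsid pool. By construction the noiseless table obeys
  `G ~ T^1.5` and `D ~ T^0.5` exactly up to the uniform draws; range
  containment holds at the construction stage, before noise.
* `gen_genome_mixture()` draws genome lengths from lognormal mixtures.
  The presets anchor their component medians at the dominant peaks of the
  two published genome-length distributions (isolates: 18.3, 42.0,
  158.9 kbp; gut contigs: 12.6, 42.9, 98.2, 160.8 kbp). Weights
  (0.15/0.60/0.25 and 0.10/0.50/0.20/0.20) and spreads (0.05 log10 units,
  0.04 for the largest components) are package choices made once so that
  the presets are actually multimodal at their anchors; only the peak
  locations are anchored to published values.

What the generators deliberately do not emulate: sequence content, genome
completeness or assembly artifacts, satellite phages (which can carry
genomes far smaller than their capsid, like P4), and the long right tail of
jumbo phages. Tests passing on these fixtures therefore establish that the
machinery recovers known structure — power-law exponents within their
standard errors, ~95% CI coverage, mixture peaks within a bandwidth — not
that any particular real database would yield the published candidate
counts.

## Problem sizes and reproducibility

The test suite and the acceptance script run at desk scale by design:
parameter-recovery and coverage simulations use the seven training
T-numbers with a few hundred replicate fits, mixture analyses use 3000
synthetic genomes, and cage checks cover every architecture with T <= 4 in
all four lattices plus the hexagonal T = 7 cage. All stochastic steps take
explicit seeds; identical specifications produce byte-identical outputs.

## Known limitations

* Evaluation-only fits built from printed parameters cannot produce
  intervals or residual diagnostics; those require a fresh fit.
* Elongated (prolate) capsids with Q-numbers are out of scope; the
  classifier will happily assign an icosahedral T to a phage that is
  actually prolate.
* KDE peak finding reports grid-local maxima; with the default bandwidth,
  minor shoulders closer than about one bandwidth to a dominant peak merge,
  so peak-recovery checks pass an explicit bandwidth matched to the
  narrowest mixture component.
* The classifier's accuracy inherits the model's large intercept
  uncertainty (CV ~27%); neighbouring small-T architectures have
  overlapping intervals, so assignments for T < 3 are candidates, not
  determinations.
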