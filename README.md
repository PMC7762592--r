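# capsidkit

Geometry and allometry of tailed-phage icosahedral capsids, and prediction
of small-capsid candidates from genome length alone.

Tailed phages build their capsids from HK97-fold major capsid proteins and
pack dsDNA at ~0.5 bp/nm³, yet the smallest icosahedral architectures
(T = 1, T = 3) have never been observed among them. Because capsid geometry
constrains how much genome a shell can hold, a phage's genome length alone
predicts its likely capsid architecture — which makes it possible to mine
sequence databases for the "missing" small-tailed phages without any
structural data. `capsidkit` implements the full chain:

* **Generalized T-numbers.** The classic triangulation number
  T₀(h,k) = h² + hk + k² is extended over the four Archimedean icosahedral
  lattices, T_i = α_i·T₀ with α = 1 (hexagonal), 4/3 (trihexagonal),
  7/3 (snub hexagonal) and 4/3 + 2√3/3 ≈ 2.488 (rhombitrihexagonal); every
  shell has 60·T₀ major capsid proteins.
* **3D cage meshes.** `build_cage()` lays any of the four lattices over an
  icosahedron via the Caspar–Klug construction (closed polygonal meshes,
  12 pentagons on the 5-fold axes, polyhedron-to-sphere sphericity
  parameter, Laves-lattice duals, OBJ/OFF/BILD writers).
* **Capsid allometry.** Log–log least-squares models G(T) = a_G·T^b_G
  (genome, kbp) and D(T) = a_D·T^b_D (diameter, nm), fitted on per-T
  averages, with standard errors, R², residual diagnostics and 95%
  intervals. The published parameters (log a_G = 0.37 ± 0.10,
  b_G = 1.47 ± 0.09; log a_D = 1.38 ± 0.34, b_D = 0.52 ± 0.03) ship as a
  parameter file; the theoretical exponents 3/2 and 1/2 follow from
  constant packing density and constant per-protein surface.
* **Classification.** `assign_t()` maps genome lengths to the architecture
  with the nearest model-mean genome length over the generalized T grid
  (T < 40) and flags T ≤ 4 small-capsid candidates; Gaussian-kernel density
  estimation locates the peaks of genome-length collections.
* **Synthetic data.** Generators emulate a capsid measurement table built
  under the conserved-quantity constraints and multimodal genome-length
  collections anchored at the published peak locations, so everything is
  testable offline.

## Worked example

```r
library(capsidkit)

# The generalized T-number series starts 1, 4/3, 7/3, ~2.49, 3:
architecture_table(enumerate_architectures(3))
#>   h k             tiling t0        t mcp_count
#> 1 1 0          hexagonal  1 1.000000        60
#> 2 1 0       trihexagonal  1 1.333333        60
#> 3 1 0     snub_hexagonal  1 2.333333        60
#> 4 1 0 rhombitrihexagonal  1 2.488034        60
#> 5 1 1          hexagonal  3 3.000000       180

# Published models predict the mean genome length (kbp) and diameter (nm)
# of the small architectures:
pp <- printed_params()
round(predict_mean(pp$genome_kbp, c(1, 4/3, 7/3, 2.488, 3, 4)), 2)
#> [1]  2.34  3.58  8.15  8.95 11.79 17.99
round(predict_mean(pp$diameter_nm, c(1, 4/3, 7/3, 2.488, 3, 4)), 2)
#> [1] 23.99 27.86 37.27 38.53 42.47 49.33

# Classify genomes by nearest model-mean genome length:
assign_t(c(11600, 7400, 102000), pp$genome_kbp)[,
  c("length_bp", "assigned_t", "nearest_mean_kbp", "is_small_candidate")]
#>   length_bp assigned_t nearest_mean_kbp is_small_candidate
#> 1     11600   3.000000        11.786049               TRUE
#> 2      7400   2.333333         8.145652               TRUE
#> 3    102000  13.000000       101.741170              FALSE
```

An 11.6 kbp genome sits almost exactly on the T = 3 model mean
(11.79 kbp): a strong small-capsid candidate. A 7.4 kbp genome lands on the
snub-hexagonal T = 7/3 ≈ 2.33 architecture, and a 102 kbp genome (a
crAssphage-sized genome) on T = 13.

```r
# A T = 3 capsid model, halfway between polyhedron and sphere:
m <- build_cage(generalized_t(1, 1, "hexagonal"), sphericity = 0.5,
                radius = 21.4)
m
#> Capsid cage mesh: (h,k) = (1,1) hexagonal, T = 3
#>   V = 60, E = 90, F = 32 (Euler 2); sphericity 0.50, radius 21.4
#>   faces: pentagon 12, hexagon 20
write_mesh(m, "obj", "t3_capsid.obj")
```

A command-line wrapper covers the same ground
(`capsidkit cage|fit|predict|simulate|metrics`), e.g.
`capsidkit predict --in genomes.fasta --params printed --tmax 40 --out report/`.

## Vignette

`vignettes/capsid-architecture-prediction.Rmd` describes the model and its
assumptions, the cage construction, the design decisions (tie-breaks,
bandwidths, interval kinds) and what the synthetic generators do and do
not emulate.
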