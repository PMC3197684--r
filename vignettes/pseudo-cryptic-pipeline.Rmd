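---
title: "Splitting a pseudo-cryptic morpho-species: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splitting a pseudo-cryptic morpho-species: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind each synthetic-data
generator in `planktotyper`, the analysis each module performs, the
default parameter choices, and the known limitations. The defaults of
`sim_config()` *are* the study conditions: every worked number in the
package documentation derives from them.

## The scientific setting

A planktonic foraminiferal morpho-species of transitional water masses
harbors two ribosomal-DNA genotypes (Type I and Type II). The split is
supported by three independent lines of evidence that this package
reproduces end to end:

1. a fixed diagnostic restriction site in the ITS region, so a single
   BstNI digest genotypes an individual;
2. a barcode gap — patristic distances between genotypes exceed all
   within-genotype variation — on a neighbor-joining tree;
3. contrasting ecologies: the genotypes occupy allopatric sea-surface
   temperature (SST) ranges meeting at a hydrographic front, and differ
   subtly in shell morphometry.

## Sequence model

`generate_sequences()` evolves uppercase A/C/G/T sequences down a fixed
four-level hierarchy: a random ancestor per marker, two genotype
ancestors, individuals within genotype, and cloned copies within
individual. Mutation is a JC-style uniform substitution process: each
site independently switches to one of the three other bases with the
branch-specific probability.

* `inter_type_divergence` (default 0.05), `intra_type_divergence`
  (0.005) and `intra_individual_divergence` (0.002) set the expected
  proportion of differing sites at each level, with the ordering
  inter > intra > intra-individual enforced.
* Because both genotype lineages also accumulate within-type and
  within-individual changes, the ancestor-level rate is corrected,
  `anc_rate = max(inter - 2 (intra + intraind), inter / 2)`, so the
  *realized* between-type p-distance tracks `inter_type_divergence`.
* The diagnostic site is engineered, not emergent: every Type I ITS
  amplicon gets `CCAGG` written at position `round(0.4 * L)` (creating
  the ~400/600 bp two-band pattern for a 1000 bp amplicon), and every
  `CCWGG` occurrence in a Type II amplicon is ablated by setting its
  third base to `G` (`CCWGG` → `CC.GG` with a `G` center matches no
  BstNI site, and the replacement cannot create a new site upstream).
  The ablation loop terminates because each step strictly reduces the
  number of A/T bases.

The digest itself cuts after the second base of each `CCWGG` match
(IUPAC `W` = A or T), keeps only cuts strictly inside the amplicon, and
reports fragment lengths sorted decreasing. A consequence worth noting:
because the cut offset is not at the motif center, digesting the
reverse complement shifts the two terminal fragments by exactly 1 bp,
so strand symmetry holds at band-count level, not as an exact fragment
multiset.

## Station and front model

`generate_stations()` (sub-seed `seed + 1`) draws `n_stations` (40)
SSTs stratified over 2–22 °C and places a single front temperature
uniformly inside `[front_sst_low, front_sst_high]` (8–12 °C). All
individuals at stations warmer than the cut are Type I; all colder
stations carry Type II. A monotone rule was a deliberate choice: an
earlier per-station coin flip inside the front band produced
SST-sympatry that contradicts the allopatric model the boundary
estimator assumes. Water-column profiles anchor SST at 10 m and decay
exponentially toward 2 °C at depth.

`boundary_temperature()` then reports the warmest Type II station, the
coldest Type I station, and whether the ranges overlap. Under the
generator the two edges bracket the drawn front and never overlap.

`station_report()` attaches to every station the detection-power
quantity `p_max = 1 - (1 - c)^(1/N)`: the highest population frequency
at which a genotype could hide given that `N` genotyped individuals
showed none of it. The identity `q = (1 - p)^N` makes this exactly
invertible, and for large `N` the bound behaves like `-ln(1 - c) / N`.

## Core-top grid model

`generate_coretop_grid()` (sub-seed `seed + 2`) builds a 1° grid of
latitudes `-grid_extent … grid_extent - 1` (default 65 → 130 rows) by
18 longitude cells, with temperatures at the 13 standard depths
0–500 m. SST follows a smooth latitudinal cosine law (≈ −2 to 28 °C)
with a small zonal wave and noise; temperature decays with depth as
`T(z) = 2 + (SST - 2) e^{-z/h}` where the thermocline scale `h` varies
with position. The varying `h` is what gives the temperature field a
genuine second mode — a surface/subsurface contrast — rather than a
single degenerate "warm vs cold" axis.

Exactly `floor(missing_cell_fraction * n_cells * 13)` locality-depth
values (default fraction 0.0327) are masked missing.
`fill_missing_temperatures()` restores them by inverse
great-circle-angular-distance weighting over the ≤ 8 surrounding cells,
in a single pass: interpolated values never feed later interpolations,
and cells with no observed neighbor stay missing. Longitudes wrap at
±180°. The estimate is a convex combination of observed neighbors, a
property the tests exercise directly.

Each cell is also a core-top locality with multinomial counts of 37
morpho-species. The focal species' expected relative abundance is 0
below 8 °C SST, flat at 0.12 up to 18 °C, and decays exponentially
beyond — rare in the tropics, absent in subpolar water. (The rule acts
on the 0 m temperature; a column-mean rule was rejected because the
column mean never exceeds ~13 °C under this thermocline, which would
make the warm decline unreachable.)

`thermal_pca()` is a correlation-matrix PCA, so eigenvalues sum to 13;
PC1 is sign-oriented to the depth-mean temperature and higher PCs to a
non-negative 500 m loading. `pc1_sst_regression()` bins localities into
1 °C SST bins and fits ordinary least squares to the bin means against
bin centers (a bin-mean-SST alternative slope is also reported).

## Morphometry model

`generate_morphometry()` (sub-seed `seed + 3`) draws 154 + 152
specimens sharing one log-normal shell-size distribution
(log-mean `log 500`, sd 0.15) while the log aperture/chamber ratio
(sd 0.18) differs between groups by `morpho_effect_size` standard
deviations (default 0.825), with the north group larger.

The default effect size is an analytic calibration, fixed before any
testing against outcomes: for two equal-variance Gaussians separated by
δ standard deviations, the optimal rule classifies at Φ(δ/2) — about
66 % at δ = 0.825 — and Wilks' λ ≈ 0.85 at n = 154/152. This places
the synthetic populations in the pseudo-cryptic regime: statistically
separable (λ far from 1, P ≪ 0.001) yet far from individually
diagnosable.

`two_group_lda()` computes λ = det(W)/det(T) from the within- and
total-group SSCP matrices, `F = ((1 - λ)/λ)((N - p - 1)/p)` on
(p, N − p − 1) degrees of freedom — (2, 303) at N = 306 — and a Fisher
discriminant with midpoint cut, reporting both resubstitution and
leave-one-out rates. `rank_tests()` reports the Mann–Whitney U
(folded to `min(U, n1 n2 − U)`; exact p only when both groups are
smaller than 20) and the asymptotic Kolmogorov–Smirnov D.

## Determinism

All randomness flows from `sim_config(seed)`. The generators use fixed
sub-seeds (`seed`, `seed + 1`, `seed + 2`, `seed + 3`; the pipeline's
bootstrap uses `seed + 4`), so each data type is reproducible
independently of whether the others are generated. Two runs of
`run_pipeline()` with equal configurations write byte-identical output
files.

```{r, eval = FALSE}
library(planktotyper)
report <- run_pipeline(sim_config(seed = 1), outdir = "results",
                       bootstrap_replicates = 100)
```

## Limitations

* The substitution model is uniform (JC-like): no transition bias, no
  rate heterogeneity, no indels, so alignment is trivial by
  construction and merge/consensus behavior must be exercised on
  hand-built gapped examples.
* The diagnostic restriction site is engineered at a fixed position
  rather than arising from the substitution process.
* The front is a single temperature cut; real hydrographic fronts
  meander, and genotype sympatry in the mixing zone is not modeled.
* The thermocline is a two-parameter exponential; inversions,
  mixed-layer structure and seasonality are absent, so PC2 captures one
  specific surface/subsurface contrast whose sign crossover sits near
  75–125 m.
* Species counts are multinomial given expected proportions;
  overdispersion and spatial autocorrelation of assemblages are not
  modeled.
* Morphometric measurements are log-normal with equal covariance by
  group — the setting in which the linear discriminant is optimal —
  so classification rates here are upper bounds on what equally sized
  real samples would give.
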