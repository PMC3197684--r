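# planktotyper

Genotyping and delimitation of pseudo-cryptic planktonic foraminifera.

`planktotyper` implements the analysis chain used to split a planktonic
foraminiferal morpho-species into two pseudo-cryptic genetic species and
to characterize their contrasting ecologies. The motivating case is a
transitional-water morpho-species whose ribosomal DNA falls into two
genotypes (Type I and Type II) separated by a sharp hydrographic front:
the genotypes are diagnosable by a single restriction site, occupy
allopatric temperature ranges, and differ subtly but significantly in
shell morphometry. Because every input the analysis needs can be
simulated with the statistical structure the methods assume, the whole
pipeline runs and is testable fully offline.

## What the package does

1. **In-silico RFLP genotyping** (`rflp_genotype`, `digest_sequence`).
   ITS rDNA amplicons are digested with BstNI (recognition site
   `CCWGG`, cut after the second base). Type I amplicons carry one
   diagnostic site and yield a two-band pattern; Type II amplicons are
   uncut. A strict mode additionally checks band sizes against the
   canonical ~400/600 bp pattern.
2. **Alignment consensus and diagnostic sites** (`merge_alignments`,
   `consensus_sequence`, `classify_sites`). Two independent alignments
   of the same sequences are merged by keeping only columns whose
   per-sequence residue homology statements agree; 60 % majority
   consensus sequences (gaps count toward the denominator) are compared
   to classify sites as synapomorphies with either group or
   autapomorphies.
3. **Distances, trees and delimitation** (`p_distance_matrix`,
   `nj_tree`, `patristic_matrix`, `bootstrap_support`, `delimit`).
   Uncorrected p-distances under pairwise deletion feed a
   neighbor-joining tree (via **ape**); patristic distances are
   summarized per group as median, 95 % nonparametric CI (2.5th/97.5th
   percentiles), and range. Two groups are delimited when the minimum
   between-group distance exceeds every group's within 97.5th
   percentile (a barcode gap).
4. **Sampling power for rare genotypes** (`undetected_fraction`,
   `station_report`). With `N` genotyped individuals, a genotype at
   population frequency `p` is missed with probability
   `q = (1 - p)^N`; the largest frequency compatible with a negative
   survey at confidence `c` is `p_max = 1 - (1 - c)^(1/N)`. At `N = 86`
   and 95 % confidence, `p_max` is about 3.4 %.
5. **Thermal niche from core-top assemblages** (`thermal_pca`,
   `interpolate_cell`, `pc1_sst_regression`, `occurrence_stats`,
   `boundary_temperature`). Gridded water-column temperatures at 13
   depths (0–500 m) with missing values filled by single-pass
   inverse-angular-distance interpolation from up to 8 neighbor cells;
   correlation-matrix PCA of the depth temperatures (eigenvalues sum to
   13; PC1 tracks the mean thermal state, PC2 the surface/subsurface
   contrast); an ordinary least-squares fit of binned PC1 against 1 °C
   SST bins; and the warm edge of the cold genotype versus the cold
   edge of the warm genotype as a front-position estimate.
6. **Morphometric discrimination** (`two_group_lda`, `rank_tests`,
   `kernel_density`). Two-group linear discriminant analysis on log
   shell size and the log aperture/chamber ratio, with Wilks' λ,
   `F = ((1 - λ)/λ)((N - p - 1)/p)`, resubstitution and leave-one-out
   classification rates; Mann–Whitney U and Kolmogorov–Smirnov D on the
   combined descriptor; Gaussian kernel densities for display.
7. **Synthetic data** (`sim_config`, `generate_sequences`,
   `generate_stations`, `generate_coretop_grid`,
   `generate_morphometry`) and the end-to-end driver `run_pipeline`,
   which writes a FASTA file, CSV tables, a JSON report and a Markdown
   summary.

## Worked example

```r
library(planktotyper)

report <- run_pipeline(sim_config(seed = 1), bootstrap_replicates = 100)

report$genotyping$concordance_pct
#> [1] 100
report$log$split_support_pct
#> [1] 100
report$delimitation$delimited
#> [1] TRUE
round(report$distances$between[["median"]], 4)
#> [1] 0.0588
round(report$thermal_niche$pca_variance_pct[1:2], 1)
#> [1] 83.2 15.7
round(report$thermal_niche$regression$slope, 3)
#> [1] 0.398
unlist(report$thermal_niche$boundary)
#> warm_edge_type2 cold_edge_type1         overlap
#>        11.66500        12.28238         0.00000
round(report$biometrics$discrimination$wilks_lambda, 3)
#> [1] 0.834
round(report$biometrics$discrimination$classification_rate, 1)
#> [1] 70.6
```

Under the default configuration the two genotypes are perfectly
recovered by the restriction digest, form a fully supported
neighbor-joining split with a clear barcode gap, occupy allopatric SST
ranges meeting near 12 °C, and are separable morphometrically at a rate
well above chance but far below certainty — the pseudo-cryptic pattern.

Genotype detection power for a negative survey:

```r
round(100 * undetected_fraction(86, confidence = 0.95), 2)
#> [1] 3.42
```

## Vignette

`vignettes/pseudo-cryptic-pipeline.Rmd` documents the statistical model
behind each generator, the default parameter choices, and the known
limitations. It is shipped as source and is not pre-built.
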