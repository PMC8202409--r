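# panmicro

Downstream analytics for genus-level microbial profiles recovered from
tumor RNA-Seq — for bioinformaticians who already have a genus × sample
read-count table (e.g. from k-mer classification of non-host reads) plus
a taxonomy map and sample metadata, and want the community-level
statistics that characterise a tissue microbiome cohort:

* **QC**: flag zero-read samples and drop samples below a read-depth
  threshold (default 100 reads).
* **Composition**: relative abundances, phylum/domain aggregation,
  per-sample domain proportions, top-N + "Other" collapses.
* **Diversity**: Shannon index *H* = −Σ *pᵢ* ln *pᵢ*; Bray–Curtis
  dissimilarity *d(x, y)* = Σ|xₜ−yₜ| / Σ(xₜ+yₜ); divergence of each
  sample to its group's per-taxon median profile (a heterogeneity
  measure); Wilcoxon–Mann–Whitney rank-sum comparisons.
* **PERMANOVA** from first principles: pseudo-*F* =
  (SS_A/(a−1)) / (SS_W/(N−a)) with SS_T = (1/N)Σ_{i<j} d²ᵢⱼ,
  within-group SS_W = Σ_g (1/n_g)Σ_{i<j∈g} d²ᵢⱼ, label-permutation
  p-values with the +1 correction, and exact enumeration whenever the
  number of distinct label arrangements fits the permutation budget.
  Pairwise group tests and an age-threshold scan are included.
* **Core microbiota**: genera detected above a positivity threshold
  (default 0.2% relative abundance) in at least a prevalence fraction of
  samples (default 20%); per-dataset, pooled and shared core sets; Venn
  overlap partitions of genus sets.
* **Pan-microbiome**: collector's curves by repeated random sample
  orderings, Heaps-law fit *P(n)* = κ·n^γ on the log-log scale, and
  explicit extrapolation with an open/closed classification (open when
  γ > 0.02).
* **Simulation**: a Dirichlet-multinomial cohort generator with
  power-law genus pools, dataset-dominated variation, planted factor
  effects and group-specific overdispersion, for calibration and power
  studies.

Everything takes tidy tibbles (first column = genus label, one column per
sample) and returns tibbles or small S3 objects with `tidy()`, `glance()`
and `autoplot()` methods.

## Worked example

Simulate a four-dataset cohort (214/191/30/147 samples, 2,500-genus
pool), QC it, and test whether sampling site (stroma vs epithelium)
shapes the community:

```r
library(panmicro)

cfg  <- synthetic_config(seed = 42)
prof <- generate_profiles(cfg)
prof
#> <taxon_profile> 2500 genera x 582 samples

qc <- qc_filter(prof$counts, min_reads = 100)
qc
#> <qc_result> min_reads=100: kept 540/582 samples (9 zero-read, 42 below threshold)

rel  <- to_relative_abundance(qc$kept)
head(alpha_diversity(rel), 3)
#> # A tibble: 3 x 2
#>   sample_id shannon
#>   <chr>       <dbl>
#> 1 s0001        4.35
#> 2 s0002        4.51
#> 3 s0003        4.39

meta <- subset(prof$metadata, sample_id %in% names(qc$kept)[-1])
site <- setNames(meta$sampling_site, meta$sample_id)
sub  <- names(site)[site %in% c("stroma", "epithelium")]
fit  <- permanova(bray_curtis(rel[, c(1, match(sub, names(rel)))]),
                  site[sub], n_permutations = 999, seed = 1)
fit
#> <permanova_test> pseudo-F = 25.608, R2 = 0.1228, p = 0.001 (999 permutations)
```

The pseudo-F of 25.6 says between-site differences are ~25× the
within-site mean square; R² = 0.123 means sampling site explains ~12% of
the total sum of squared dissimilarities; p = 0.001 is the smallest value
attainable with 999 permutations — none of the permuted statistics
reached the observed one (the generator plants a 4-fold shift on 20 taxa
in epithelium samples, so this is the correct call).

Is the pan-microbiome open? Accumulate genera over random sample
orderings and fit Heaps' law:

```r
acc <- accumulation_curve(qc$kept, n_reps = 200, seed = 1)
h   <- fit_heaps(acc)
h
#> <heaps_fit> P(n) = 812.16 * n^0.15684  (R2 = 0.817166, loglog)
pan_estimate(h, 2000)
#> # A tibble: 1 x 5
#>   n_extrapolate predicted_richness gamma open  open_margin
#> 1          2000              2675. 0.157 TRUE         0.02
```

γ ≈ 0.16 > 0: richness is still growing with sample count, so the
pan-microbiome is classified open; extrapolating the fitted curve to
2,000 samples predicts ~2,700 genera.

`run_pipeline()` chains all of the above (QC → domain proportions →
overlap → core → pan → diversity → PERMANOVA per metadata factor →
divergence → separating coefficients) and writes a plain-text report
directory with a `run.log` of every parameter and seed.

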