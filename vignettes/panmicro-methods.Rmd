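---
title: "Methods: genus-level tumor microbiome analytics in panmicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genus-level tumor microbiome analytics in panmicro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`panmicro` implements the downstream statistics used to characterise the
microbial composition of tumor tissue from genus-level read-count tables,
such as those produced by classifying non-host RNA-Seq reads. The package
deliberately starts *after* read classification: its input is a genus ×
sample integer matrix plus a taxonomy map (genus → phylum → domain) and
per-sample metadata (dataset of origin, sex, age, sampling site, tissue
source). Everything upstream — trimming, host depletion, k-mer
classification — is out of scope.

The analyses covered are: quality-control filtering of low-read samples;
relative-abundance transforms and taxonomic aggregation; Shannon alpha
diversity and Bray–Curtis beta diversity; divergence-to-median community
heterogeneity; one-factor PERMANOVA with exact enumeration for small
designs; core-microbiota detection; cross-dataset overlap partitions; and
pan-microbiome accumulation with Heaps-law fitting. A
Dirichlet-multinomial cohort simulator generates data with the structure
these analyses assume, so the whole pipeline is testable without any
sequencing downloads.

# Data model and quality control

Count tables are tibbles whose first column holds the genus label and
whose remaining columns are samples; taxonomy and metadata are plain
tibbles. Validation enforces non-negative integer counts, unique labels,
and metadata coverage of every sample. Genera lacking a phylum assignment
are retained under the explicit category `"None"` rather than dropped,
because unassigned taxa can carry substantial read mass and silently
discarding them would bias phylum-level compositions.

`qc_filter()` removes samples whose total microbial read count is
*strictly below* a threshold (default 100 reads) and separately reports
zero-read samples, mirroring the practical situation in tissue RNA-Seq
where a tail of libraries — often biopsies — yields no usable microbial
signal. Zero-total samples that survive a `min_reads = 0` setting are
never normalised: `to_relative_abundance()` leaves their columns at zero
and flags them, and all downstream relative-abundance analyses exclude
flagged samples rather than propagating `0/0`.

# Diversity and heterogeneity

Shannon diversity is computed in nats, \(H = -\sum_{p_i>0} p_i \ln p_i\),
with the base configurable; an all-zero sample has undefined diversity and
returns `NA`. Beta diversity is fixed to Bray–Curtis on relative
abundances,
\(d_{ij} = \sum_t |x_{ti}-x_{tj}| / \sum_t (x_{ti}+x_{tj})\), computed via
`vegan::vegdist`; this is the standard dissimilarity for compositional
community data and the package treats the choice of metric as a design
decision rather than an inference.

Heterogeneity is measured by *divergence to the median*: within each
group, the reference profile is the per-taxon median of the member
columns, and each member's divergence is its Bray–Curtis dissimilarity to
that reference. The median reference is deliberately **not** renormalised
to sum to one — the Bray–Curtis formula tolerates an unnormalised
reference, and renormalisation would change the values, so the convention
is fixed and documented for reproducibility. Group mean divergence
separates *dispersion* differences from *location* differences: two
groups can share a central composition (PERMANOVA null retained) while
one is far more spread out around it. This is exactly the pattern
reported for sex and age in tumor-tissue cohorts, and the simulator
reproduces it by lowering the Dirichlet concentration of designated
groups.

Two-group comparisons of diversity or divergence use the unpaired
Wilcoxon–Mann–Whitney rank-sum test (`rank_sum_test()`). The exact null
distribution is used when both groups have at most 12 observations and no
ties are present; otherwise the normal approximation with tie and
continuity correction applies. A paired signed-rank test is not
applicable to the unpaired group designs handled here.

# PERMANOVA

`permanova()` is implemented from first principles. With \(N\) samples in
\(a\) groups and squared dissimilarities \(d_{ij}^2\),

\[
SS_T = \frac{1}{N}\sum_{i<j} d_{ij}^2, \qquad
SS_W = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2, \qquad
SS_A = SS_T - SS_W,
\]

\[
F = \frac{SS_A/(a-1)}{SS_W/(N-a)}, \qquad R^2 = SS_A/SS_T .
\]

Significance comes from permuting group labels. When the number of
distinct label arrangements \(M = N!/\prod_g n_g!\) is no larger than the
requested permutation count, the full distribution is enumerated and the
p-value is exact — the fraction of arrangements (including the observed
one) with \(F \ge F_{obs}\). Otherwise the Monte-Carlo estimate
\(p = (1+\#\{F_{perm}\ge F_{obs}\})/(1+B)\) is used, so \(p\) can never be
zero and its floor is \(1/(B+1)\); the default \(B = 999\) makes the
smallest attainable p-value 0.001. A seed is mandatory on the Monte-Carlo
branch and is recorded in the result. Numerical tie handling: permuted
statistics within \(10^{-12}\) of the observed one count as "at least as
extreme", protecting the exact branch from floating-point noise in
symmetric configurations.

Only the one-factor design is implemented; multi-factor decompositions
and restricted permutation schemes are out of scope. Pairwise group
testing subsets the distance matrix per pair; pairs with a group smaller
than two are reported as not testable rather than erroring, and the same
convention applies to the age-threshold scan (default thresholds 45 to 70
in steps of 5), which dichotomises samples at each cutoff and reruns the
test.

PERMANOVA is sensitive to dispersion differences in strongly unbalanced
designs; the package keeps the heterogeneity question separate (via
divergence-to-median) rather than reading dispersion effects out of the
location test.

# Separating coefficients and fold changes

For a binary factor, the per-taxon "separating coefficient" is the
difference of group mean relative abundances (reference minus other),
which equals the slope of a per-taxon linear regression on a 0/1 group
code. Taxa are ranked by absolute coefficient; signs encode direction.
Fold changes of a single taxon are ratios of group mean relative
abundances; when the denominator mean is exactly zero, a pseudo-abundance
of half the smallest nonzero relative abundance in the table is added to
both means and the output is flagged, so the reciprocal identity
`fc(A,B) = 1/fc(B,A)` holds exactly whenever no pseudo-count triggered.

# Core microbiota, overlap, and the pan-microbiome

A genus is *detected* in a sample when its relative abundance strictly
exceeds the positivity threshold (default 0.2%); its *prevalence* is the
fraction of samples where it is detected; the *core set* is every genus
with prevalence at least the prevalence threshold (default 20%). Both
comparison conventions are configurable, but the defaults (strict
detection, inclusive prevalence) follow the common core-microbiota
definition. Core sets are computed per dataset, on the pooled collection,
and as the intersection of per-dataset cores — the "shared core".

`overlap_sets()` partitions the union of named genus sets into all
\(2^k-1\) Venn membership regions and reports each set's shared fraction;
the region cardinalities always sum to the union size, which the tests
assert as a conservation property.

The pan-microbiome is estimated by the collector's-curve procedure: draw
a uniform random ordering of samples, count cumulative distinct genera,
repeat (default 1,000 orderings), and average. Presence for accumulation
means count > 0, not the core detection threshold — the question is how
many taxa exist at all, not how many are comfortably quantifiable; the
threshold is configurable. Heaps' law \(P(n) = \kappa n^{\gamma}\) is
fitted to the mean curve by ordinary least squares on the log-log scale
(\(R^2\) reported on that scale), with an optional raw-scale
nonlinear-least-squares refinement started from the log-log estimates;
on zero-residual input the refinement cannot iterate and the log-log
estimates are kept. Extrapolation via `pan_estimate()` requires an
explicit target sample count — the package never reports a "pan size" at
a silent default — and classifies the pan-microbiome as *open* when
\(\hat\gamma\) exceeds a margin of 0.02, i.e. when richness is still
growing materially with sample count.

# The synthetic cohort generator

The generator exists so that every analysis can be exercised, calibrated
and power-tested on data whose truth is known. Its generative model:

1. A pool of \(G\) genera (default 2,500) receives occurrence
   probabilities \(p_g \propto g^{-\alpha}\) (default \(\alpha = 1\)).
   The power law makes per-sample richness land in the hundreds while the
   union across a cohort keeps growing sublinearly — the open-pool regime.
2. Each dataset \(d\) draws a base composition
   \(\theta_d \sim \mathrm{Dirichlet}(c_D\, p)\) with total concentration
   \(c_D\) (default 1,000). Dataset draws differ enough that the dominant
   axis of variation in the cohort is the dataset of origin.
3. Each sample draws
   \(\pi_s \sim \mathrm{Dirichlet}(c_s\, \theta_d\, e_s)\) with
   per-sample concentration \(c_s\) (default 200), where \(e_s\)
   multiplies the designated effect taxa for affected samples, and
   \(c_s\) is divided by `dispersion_ratio` (default 1.5) for the
   heterogeneity groups (male sex, age over 65). Overdispersion rather
   than a mean shift is how the generator plants "more heterogeneous but
   not differently located" groups.
4. Counts are \(\mathrm{Multinomial}(R_s, \pi_s)\) with
   \(R_s \sim \text{round}(\mathrm{lognormal}(\ln 3\times10^4,\,0.7))\).
   Nine samples are overridden to zero reads and a further 33 to 1–99
   reads, giving the QC stage something real to do.

Default cohort structure: four datasets of 214, 191, 30 and 147 samples.
The first carries a stroma/epithelium/bulk sampling-site split, the
second and third contain patient-derived-xenograft samples, the third and
fourth are sex-labelled, and the fourth carries ages — so every factor
analysis has a natural subset. Location effects default to a 4-fold shift
on 20 designated taxa for the epithelium site and 6-fold for PDX source;
sex and age have no location effect by default, only the dispersion
ratio. Effect taxa are drawn from abundance ranks 5–150: shifts planted
on very rare taxa are undetectable against the sampling noise of the most
abundant taxa, so restricting the eligible ranks is what makes
"planted taxa dominate the top coefficients" a meaningful, recoverable
signal rather than a lottery.

At these defaults a generated cohort shows roughly 300 genera per sample,
about 2,000 distinct genera across the cohort out of the 2,500-genus
pool, a rising accumulation curve with \(\hat\gamma \approx 0.16\), and
an extrapolated pan-microbiome above the pool-exhaustion point — the same
qualitative regime as published tumor-tissue cohorts of this size.

What the generator does **not** emulate: classification error and
contamination (every read is assigned to a true pool genus), phylogenetic
correlation between taxa, technical covariates (platform, library layout)
beyond the dataset label, and compositional zero-inflation beyond what
the Dirichlet-multinomial induces. Per-dataset core sets also come out
larger (~100–150 genera) than the few dozen reported for real cohorts,
because the simulator's within-dataset prevalence structure is cleaner
than reality. Passing tests therefore demonstrate statistical
correctness and calibration of the methods, not that real tissue data
meets the model's assumptions.

# Numerical and design choices

* **Ranking for top-N collapse** uses mean relative abundance across all
  samples, ties broken alphabetically; the "Other" row preserves column
  sums exactly.
* **Zero-total samples** are flagged, never fatal, and excluded from
  relative-abundance analyses.
* **Exactness caps**: rank-sum enumeration at 12 per group (no ties);
  PERMANOVA enumeration whenever the arrangement count fits within the
  permutation budget; both switchable.
* **Seeds** are explicit arguments everywhere randomness occurs
  (`permanova`, `accumulation_curve`, the generator, `run_pipeline`) and
  are recorded in results and in `run.log`, so every reported number is
  recomputable.
* **Problem sizes in the test-suite experiments** were chosen as the
  smallest that make the statistical assertions sharp: 1,000 null
  datasets of 2×8 samples over a 150-genus pool for type-I-error
  calibration (rejection rate within [0.03, 0.07] at α = 0.05 and a
  Kolmogorov–Smirnov uniformity check), 100 default-size cohorts for the
  heterogeneity pattern, and 20 for planted-effect power.

# Known limitations

* One-factor PERMANOVA only; no strata, no covariate adjustment.
* Bray–Curtis is the only dissimilarity wired in; phylogeny-aware
  metrics (UniFrac) are out of scope.
* The Heaps fit weights all curve points equally on the log scale; the
  early, steep part of the curve therefore influences \(\hat\gamma\)
  more than a raw-scale fit would allow. The `nls` option exists for
  sensitivity checks.
* No nonparametric richness estimators (Chao1 and relatives) — the
  accumulation-plus-Heaps route answers "is the pan-microbiome open",
  not "what is total richness".
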