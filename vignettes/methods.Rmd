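---
title: "Detecting shared environmental adaptation across replicated transects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting shared environmental adaptation across replicated transects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`clinescan` implements a comparative genotype-environment association (GEA)
workflow for organisms sampled along several independent environmental
gradients ("transects"): per-transect association scans with latent-factor
confounder control, gene-level candidate sets, cross-transect overlap and
allele-frequency parallelism tests with permutation nulls, SNP-permutation GO
enrichment, the supporting population-structure statistics, and a mixed-model
GWAS for a quantitative trait (body weight). A synthetic-data generator with
the same statistical structure makes the whole pipeline testable end to end.

This vignette explains the models, the parameters that matter, the numerical
choices, and - candidly - what the simulation-based checks do and do not
establish.

## The data model

Genotypes are biallelic SNP dosages (0/1/2 copies of the alternate allele,
`NA` when missing), held in a `genotype_table` with 1-based inclusive
coordinates (the VCF/GFF convention; BED input is converted at the boundary).
Samples carry population, transect, sex, latitude, environmental covariates
(e.g. mean annual temperature, MAT, in degrees C; precipitation of the driest
month, PDM, in mm), and optionally body weight in grams. Gene models are
spans plus exon intervals; GO annotation is a flat gene-to-term map.

## The environmental association scan

For one transect, one environmental variable $x$ (standardized), and the
mean-imputed, MAF- and call-rate-filtered dosage matrix $Y$ ($n$ samples
$\times$ p sites), the scan fits, per site $j$,

$$ y_j = \mu_j + \beta_j x + U \gamma_j + \varepsilon_j $$

where $U$ holds $K$ latent factors absorbing neutral population structure.
The factors are the leading left singular vectors of $Y$ projected off
$(1, x)$ - the deterministic least-squares analogue of a latent factor mixed
model (and the limiting case of the published ridge estimator as the ridge
penalty vanishes). Effects and factors are then re-estimated jointly by
ordinary least squares, giving $z_j = \hat\beta_j / \mathrm{se}(\hat\beta_j)$
with $n - K - 2$ residual degrees of freedom.

**Calibration.** The genomic inflation factor is
$\lambda = \mathrm{median}(z^2) / 0.4549$ (the 1-d.f. chi-square median);
calibrated p-values are the upper chi-square tail of $z^2/\lambda$, and
q-values are Benjamini-Hochberg. A site is an outlier when
$q \le$ `q_threshold` **and** $|z| \ge$ `z_threshold` (defaults 0.05 and 2;
0.01 is the conventional stricter choice for a single-transect headline
scan).

**Why $\lambda$ is far above 1 here, by design.** Environmental values are
population-level constants, so the covariate lies exactly in the span of
population structure. Per site, the population means drift; the component of
that drift aligned with $x$ is a rank-one term $x d^\top$ with small dense
loadings $d_j$, while true clines are the same term with sparse large
loadings. No per-site regression can separate them; the factors can only
absorb structure *orthogonal* to $x$ (absorbing the $x$-aligned direction
absorbs the signal too - we measured that replacing the factors with plain
genotype PCs drives the truth-ranking power from ~0.9 to chance while pushing
$\lambda$ to ~1.1). The median-based $\lambda$ rescaling *is* the robust
estimator of the dense drift scale: it calibrates the bulk, and sparse clines
survive as outliers. The cost is that the extreme tail of the calibrated null
is still somewhat heavy (the $x$-aligned drift has roughly one effective
degree of freedom per site), so single-transect outlier lists retain some
drift false positives; with six populations per transect, $\lambda$ sits
around 3-5 and the probability that a fully neutral scan calls at least one
outlier is on the order of 10%, not 5%. This is a property of the published
scan-plus-genomic-control workflow itself. The specificity of the overall
analysis comes from replication: in the null pipeline the three-transect
overlap and parallelism tests reject in 0/20 seeds, because independent drift
does not replicate.

**Choosing K.** K is the number of broad structure axes to absorb - in
practice the number of genetic clusters along the transect minus one
(conventional values: 2-3). Larger K costs degrees of freedom and, beyond
the structure dimension, starts fitting noise.

## Candidate genes, consequences, enrichment

Outlier SNPs map to genes by interval overlap: gene bodies for candidate
sets, exons only for enrichment (matching the SNP-permutation enrichment
convention). Functional consequences use a six-class priority scheme
(1 missense/stop > 2 UTR > 3 synonymous > 4 non-coding exon > 5 intron/splice
> 6 up/downstream); each SNP gets the highest-priority class among its
labels. The built-in annotator derives codon positions from cumulative exon
offsets and strand, with a deterministic pseudo-reference codon per position
and the standard genetic code - a self-contained stand-in for a full
transcript-aware effect predictor, sufficient to exercise the decision layer.

GO enrichment is permutation-based and aware of gene-length bias, because
long genes collect more SNPs: the observed statistic per term is the number
of distinct candidate genes annotated to it; *snp*-mode nulls resample SNP
sets (treating SNPs as independent - anti-conservative under LD), *gene*-mode
nulls resample SNPs until the observed distinct-gene count is reached
(treating genes as fully linked blocks - conservative), and the recommended
middle road LD-prunes both candidate and background SNPs (greedy $r^2 > 0.5$
removal within non-overlapping 50 kb windows tiled from position 1) before
running snp mode. Empirical p-values use the add-one estimator; BH is applied
across terms with at least one candidate gene.

## Cross-transect tests

**Overlap.** The observed statistic is the size of the intersection of
candidate gene sets. Null replicates redraw each set's size uniformly with
replacement (duplicates collapsed) from that transect's tested-gene universe;
the z-score and add-one empirical p are reported. Resampling gene identities
(rather than shifting genomic intervals) preserves set sizes and universe
membership and needs no genome gap masks; for sets much smaller than the
universe the null mean is the familiar $|A||B|/|U|$.

**Parallelism.** For each transect the end populations are those at minimum
and maximum distance from the equator; a shared SNP's direction is the sign
of the alternate-allele frequency change from the low to the high end,
subject to a 60% per-population call-rate rule, with allele polarization
checked (swapped ref/alt flips the dosage; incompatible alleles are
excluded). A gene is *parallel* when its evaluable shared SNPs agree in
direction across all transects - by default under a **majority** rule. We
chose majority over strict conjunction deliberately: with several effectively
independent SNPs per gene, conjunction forces every unlinked neutral SNP in a
truly selected gene to agree by chance in all transects, which caps the
parallel fraction among genuine candidates near the noise floor and drags the
genome-wide fraction far below the single-SNP expectation; the majority rule
reduces to the same logic for one-SNP genes (where the three-transect null is
exactly 25%) and lets a selected haplotype outvote unlinked variation. Both
`"all"` and `"any"` remain available.

Significance is assessed twice: a 1-d.f. chi-square against the 25% null
(appropriate for the single-SNP reading) and, more robustly, a permutation
test drawing the same number of genes with replacement from the genome-wide
set of genes with shared SNPs and their empirically computed concordance
flags - this second test needs no analytic null and is the one the pipeline
relies on.

## Mixed-model GWAS

Body weight is analysed across pooled transects with
$y = W\alpha + x_j\beta_j + u + \varepsilon$, $u \sim N(0, \sigma^2_g K)$,
where $K = ZZ^\top/m$ is the standardized-genotype kinship matrix and $W$
includes an intercept and sex. The variance ratio is estimated once under the
null by REML on the spectral decomposition (the usual single-estimate
approximation that re-uses the null variance ratio for every SNP); each SNP
is then tested by generalized least squares with a Wald test. SNPs are
filtered at MAF $\ge$ 5% and missingness $\le$ 10%; at a tested SNP, samples
with missing dosage are dropped exactly (per-SNP Cholesky GLS on the sample
subset), not imputed. Significance is BH FDR $\le$ 0.05. Heritability is
reported as $1/(1+\hat\delta)$.

## The synthetic-data generator

The generator emulates the sampling design the analysis targets, with every
dataset a deterministic function of the seed:

* **Structure**: shared ancestral allele frequencies $\sim U(0.05, 0.95)$;
  per-population frequencies from the Balding-Nichols model
  $\mathrm{Beta}(p\frac{1-F}{F}, (1-p)\frac{1-F}{F})$. Default $F = 0.1$,
  inside the 0.07-0.15 range typical of recently founded commensal
  populations, and recovered by the Weir-Cockerham estimator to within 0.02.
* **Clines**: a fraction of genic sites (default 5%) add
  `clinal_slope` $\times$ standardized distance-from-equator to the logit
  ancestral frequency before drift. A configurable fraction of the affected
  genes act with the same sign in every transect ("shared"); the rest are
  private to one transect. Default slope 1.5 is a moderate cline;
  slope 4 is the sweep-like regime (near-complete frequency reversal across
  the gradient) used as the "strong signal" condition in power checks - at
  moderate slopes single-transect BH discovery at 2,000 sites is rare, which
  is itself informative about desk-scale power.
* **Linkage**: within windows of `ld_block_span` (default 5 kb), non-leader
  sites echo the block leader's genotype column with probability
  `ld_copy_prob`; the leader is the block's first clinal site when present,
  so linked neutral variation hitchhikes on selected haplotypes - the reason
  non-causal candidate SNPs are informative at all, and the LD regime the
  three enrichment modes are designed around.
* **Environment**: latitude ranges mimic one South-American-like transect
  (3-55 degrees S) and two North-American-like transects; MAT is a noisy
  linear function of latitude spanning roughly 20 down to 5 degrees C within
  each transect; PDM is independent of latitude. All environmental values are
  population constants (locality-level climate extraction), which is also
  what makes the scan's structure-environment collinearity unavoidable (see
  above).
* **Phenotype**: weight = intercept (15 g) + sex effect (2 g) + per-allele
  causal effects + a genome-wide polygenic term + Gaussian noise. About 80%
  of causal sites are drawn from the shared clinal sites - body weight is
  itself a clinal trait, so association hits largely coincide with scan
  candidates, with a minority of non-clinal causals. Setting the polygenic
  and residual variances equal gives true $h^2 = 0.5$, recovered by the REML
  component to about $\pm 0.1$.
* **Missingness**: uniform per-call (default 5%), interacting with the 80%
  site call-rate and 60% end-population rules downstream.

**What passing tests show, and what they do not.** The generator reproduces
the *statistical* structure the methods assume - hierarchical drift, logit
clines, block LD, missingness, a sex-affected polygenic trait - so green
tests certify the estimators and the inferential plumbing. Real exome data
differ in ways the generator does not attempt: LD decays continuously rather
than in blocks, missingness tracks capture efficiency and divergence rather
than being uniform, selection acts on standing haplotypes over time,
environmental gradients are not linear in latitude, and sample sizes per
population are unbalanced. Conclusions about real-data power, especially for
the single-transect scans, should not be read off these simulations.

## Numerical and design choices

* Internal coordinates 1-based inclusive; BED converted at the boundary;
  sites keyed by (chromosome, position), duplicates rejected.
* Phased GT separators accepted, treated as unphased dosage.
* Missing dosages are mean-imputed *only* inside the scan's factor model
  (a complete matrix is required; imputing to the mean biases toward the
  null, which is conservative); the GWAS instead drops samples per SNP.
* All permutation p-values use the add-one estimator, so p = 0 never occurs
  and the smallest attainable p is 1/(n+1).
* Relatedness is the standardized-genotype moment estimator (~1 duplicates,
  ~0.5 parent-offspring, threshold 0.25 = half sibs); pruning removes the
  more-missing member of each flagged pair, ties broken lexicographically,
  scanning pairs in sample-id order - fully deterministic. The pipeline
  prunes within populations so drift-driven structure is not mistaken for
  kinship. The estimator needs a reasonably wide panel: in-sample allele
  frequencies bias pairwise estimates downward by roughly $3/n$.
* Ties at the top-n candidate boundary break by (calibrated p, chromosome,
  position), so top-candidate sets are reproducible across runs.
* Mantel tests permute rows and columns of the second matrix simultaneously;
  the statistic is the Pearson correlation of upper triangles.
* The pipeline derives per-stage seeds from one master seed by fixed
  offsets: stages are independently reproducible.
* Scan q-values threshold on *calibrated* p; the |z| gate applies to the raw
  z-score.

## Known limitations

* With per-population environments the single-transect scan cannot be both
  calibrated in its extreme tail and powered (discussed above); interpret
  single-transect outlier lists as enriched, not clean, and rely on the
  replication tests.
* The consequence annotator is deliberately minimal (no isoforms, no UTR
  intervals in the gene model, no splice-distance logic); UTR labels are
  accepted from external annotation but not emitted.
* The enrichment's gene mode conditions on the observed distinct-gene count;
  with very small candidate sets the null is coarse.
* The chi-square parallelism test inherits the single-SNP 25% null; for
  multi-SNP genes the permutation test against the empirical genome-wide
  concordance is the defensible one.

## Problem sizes used in the checks

The bundled tests and the acceptance script run the scans at 2,000 sites,
6 populations x 15 samples (null calibration; 100 replicates), parameter
recovery at up to 300 samples x 2,000 sites, and the pipeline power checks
at 3 transects x 5 populations x 10 samples with 20 seeds per condition -
sizes chosen so the full suite exercises every stage in a few minutes while
keeping Monte-Carlo error well inside the asserted tolerances.
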