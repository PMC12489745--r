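---
title: "Methods and design notes for popgea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for popgea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgea)
```

This vignette records how the statistics in `popgea` are defined, the
defaults and why they were chosen, what the simulator does and does not
emulate, and the numerical decisions a maintainer would want written down.
It states no empirical result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## Data model

Everything operates on a `geno_mat`: an individuals × sites matrix of
alternate-allele dosages (0/1/2, `NA` missing) with site metadata (chrom,
1-based pos, ref/alt, QUAL, mean depth) and individual metadata (id,
region, subregion, lat/lon). Positions are 1-based everywhere (the VCF
convention); missingness is a real `NA`, never a sentinel dosage, and all
downstream statistics use locus-wise or pairwise complete observations
unless an operation explicitly states mean imputation (PCA, the
individual-allele-frequency response of the GEA).

## Quality filtering

Individuals are filtered before sites: mean depth < 3x or missingness
> 20% removes an individual, then sites are screened on mean depth
(default window 5–12x, the upper bound being roughly twice a typical
low-coverage genome mean), QUAL ≥ 50, missingness ≤ 10%, biallelic
single-base REF/ALT, and a MAF floor that is 0 by default (structure and
GEA analyses typically re-filter at 0.05, kinship deliberately not — rare
alleles carry most of the identity information in the allele-matching
estimators). A depth threshold written as a percentage in some upstream
tool conventions is interpreted as x-coverage here; the ambiguity is noted
in `?filter_genotypes`. Per-individual depth and missingness are frozen
into the metadata on first use so that re-applying a configuration is a
no-op; rules that cannot be evaluated (no depth or QUAL recorded) pass
rather than remove.

## LD pruning

r² is the squared Pearson correlation of dosage vectors over shared calls
— appropriate for unphased genotypes; no haplotype-phase EM is attempted.
Pruning uses half-open windows `[start, start + 50 kb)` advancing by 10 kb.
The removal rule is deliberately not the common iterative greedy pair
deletion: a site is removed exactly when some higher-priority site sharing
a window exceeds the threshold with it, where priority is lower
missingness, then smaller position. This rule still guarantees that no two
surviving sites in a common window exceed the threshold (if both survived,
the lower-priority one would have been removed), is deterministic, and —
unlike iterative greedy deletion, for which counterexamples exist — is
provably monotone: lowering the threshold only enlarges the removed set,
so candidate SNP panels nest across stringency levels. The cost is a
slightly conservative prune (a site can be removed on account of a partner
that was itself removed).

## Population structure

PCA mean-imputes missing dosages, centers columns and does **not** scale
them (the convention for dosage PCA where variance carries frequency
information); the decomposition is an SVD, so reconstruction with all axes
returns the centered matrix exactly. The k-means scan scores each K by
`BIC = n·ln(WSS/n) + k·ln(n)` and picks the first local minimum (the last
K before the BIC first rises), with a manual override. Two caveats are
documented rather than hidden: the BIC curve is only meaningful on PCA
scores, whose trailing axes have small variance — on raw isotropic
high-dimensional data k-means can always find splits that beat the `ln n`
penalty (small-sample top-eigenvalue inflation), and the scan then runs
past the true K; and WSS is floored at 1e-10 so duplicated points
degenerate to K = 1 rather than `-Inf`. DAPC fits linear discriminants on
retained PCs; the number of PCs is chosen by the a-score (observed minus
permuted reassignment rate, mean over groups, default 50 permutations,
grid of 10 evenly spaced candidates), guarding against the overfitting
that retaining all PCs invites.

The admixture model maximises the binomial mixture likelihood by plain EM
block updates — slower than quasi-Newton acceleration but monotone by
construction (asserted in tests) and adequate at the scale this package
targets. F is clamped to `[1e-6, 1 − 1e-6]`; convergence is an absolute
log-likelihood change below `tol` (default 1e-3 — the Q estimates move by
far less than their statistical error well before this point), capped at
1000 iterations with a `converged` flag. Cross-validation masks a random
1/folds of *called genotype entries* (not individuals), refits, and scores
`(g − 2ĥ)²` on the masked entries; the K minimising this error is
reported. Fold assignment and initialisation derive from the seed.

## Selection scan

Genotypes are imputed, centered and scaled to unit variance; each SNP is
regressed on the leading K principal components; the K-vector of
regression z-scores is summarised by its Mahalanobis distance under a
minimum-covariance-determinant estimate of the z covariance across SNPs
(sample covariance when fewer than 10·K sites are available — the MCD
subsample is itself seeded so scans are reproducible). Distances are
divided by the genomic inflation factor `median(D²)/median(χ²_K)` before
upper-tail χ²_K p-values and Storey q-values. K is an explicit analyst
argument; `scree_report()` provides an elbow suggestion (largest
perpendicular distance to the scree chord) but does not decide. The
q-value pi0 is a cubic smoothing spline over tail proportions at
λ = 0.05…0.90 evaluated at 0.90, falling back to pi0 = 1 (Benjamini–
Hochberg) if the smoother leaves (0, 1].

## Diversity and differentiation

Nei statistics use the small-sample corrections with the harmonic mean
sample size; global values are locus averages with
F<sub>ST</sub> = 1 − H̄s/H̄t (ratio of averages, not average of ratios).
Weir–Cockerham θ aggregates variance components as ratio-of-sums. These
aggregation conventions follow the cited estimators; they matter, which is
why they are stated. A bias worth knowing: the Hs/Ht-based F<sub>ST</sub>
carries an (r−1)/r factor relative to θ under an island model with r
sampled populations, so the two only coincide in the many-population,
low-drift regime — the agreement test uses r = 8, F = 0.05 for exactly
this reason. β-F<sub>ST</sub> and β-kinship use allele matching referenced
to the mean between-population (between-individual) matching; off-diagonal
β-kinship therefore averages zero by construction and is *relative to the
sampled cohort*. Consequently relatedness pruning in a structured cohort
must use the KING-robust between-family estimator (`robust_kinship()`),
not β-kinship — the pipeline does. Bootstrap CIs resample loci with
replacement (percentile 2.5/97.5%, seeded). Nei's D defaults to the 1972
standard distance; the 1978 small-sample variant is available
(`variant = "1978"`), since the literature frequently cites "Nei's D"
without distinguishing them. Individual-level trees treat each individual
as a population of one with frequencies 0/0.5/1. Neighbour joining is
delegated to ape; negative branch lengths are clamped to zero with the
magnitude transferred to the sister edge, preserving leaf-to-leaf path
lengths through the parent.

Relative pruning at a threshold (default 0.125) greedily removes the
individual in the most flagged dyads, ties broken by lower call rate then
lexicographic id — a deterministic codification of "remove one of each
pair". On small instances the removal count is within one of an exhaustive
minimum vertex cover (asserted in tests).

## Genotype–environment association

Predictors are pruned in two stages: pairwise |r| > 0.7 drops the
later-listed variable of each pair (the kept one is the analyst's
ordering choice; both are logged), then the variable with the largest VIF
is removed repeatedly until all VIFs ≤ 3. The VIF-stage removals are not
discarded: they form part of the conditioning matrix of the partial RDA,
alongside the leading PCs (default 3) of the outlier-filtered genotype
data. Only the VIF-stage removals are conditioned on — conditioning also
on the correlation-stage removals would re-introduce near-duplicates of
kept predictors; the alternative reading is noted here. The response for
both RDA and LFMM is dosage/2 with site-mean imputation; an allele-depth
based frequency estimate is noisier at low coverage and is deliberately
not the default. The ordination itself is vegan's RDA; adjusted R² is the
Ezekiel correction `1 − (1 − R²)(n − 1)/(n − p − 1)`, the variance
partition reports full model, environment|structure and
structure|environment, and per-axis significance comes from
`anova.cca(by = "axis")` permutations. Candidate SNPs on each retained
axis (default 3) are those beyond `sd_mult` standard deviations from the
mean loading (2.5 and 3 are the supported working points); each candidate
is assigned the environmental variable with the largest absolute
correlation to its frequencies.

The latent-factor model alternates a rank-K truncated SVD of `Y − XBᵀ`
with a ridge regression of `Y − UVᵀ` on X (penalty default 1e-5 — just
enough to stabilise the solve; at `K = 0, λ = 0` the fit is exactly
per-SNP OLS, asserted to 1e-8). K defaults to 5, matching the number of
genetic clusters the structure stage typically supports in the intended
use. z-scores come from per-SNP least squares with the latent factors as
covariates, recalibrated per environmental variable by the genomic
inflation factor; multiple testing is per variable, not pooled, matching
the per-factor runs of the reference workflow. The final candidate set is
the three-way intersection (RDA ∩ LFMM ∩ scan) — maximally conservative,
trading recall for a low false discovery proportion, and nested across
threshold pairs because each ingredient is.

## The simulator

`simulate_popgen()` emulates: K discrete populations whose allele
frequencies drift from a shared ancestral pool by the Balding–Nichols Beta
model (per-population F); partial selfing producing a heterozygote deficit
at the equilibrium F = s/(2−s); Dirichlet-admixed individuals; pedigree
blocks (full-sib, half-sib, parent–offspring) built by allele-level gene
dropping from founders; environmental variables constructed as a shared
north–south gradient plus correlated noise, attached per individual so
the GEA has within-population contrast; adaptive loci whose logit
frequencies shift by `effect_size` per SD of their assigned variable;
uniform missingness and Poisson per-genotype depths. Defaults were fixed
once to mirror a realistic low-coverage resequencing study: missingness
0.8%, mean depth 6x, ancestral MAF uniform on (0.05, 0.5), four
environmental variables with pairwise noise correlation 0.3. The
`paperlike_config()` preset (5 populations, 269 population individuals
plus admixed and pedigree members, F = 0.15) is a *shape* for integration
tests, not a claim of equivalence to any real dataset.

What the simulator does **not** emulate — and therefore what passing tests
do not demonstrate about real data: linkage (loci are independent, so LD
pruning is exercised on separately constructed correlated blocks),
realistic site-frequency spectra from demographic history (no coalescent),
sequencing error in genotype calls, batch effects, spatially
autocorrelated sampling, or selection acting over time. Recovery results
on simulated data bound what the estimators can do when their model is
approximately right; they say nothing about model misspecification.

## Problem sizes and reference conditions

The test suite and acceptance script run at desk scale, chosen as the
smallest sizes at which the statistical claims are comfortably testable:
drift recovery at 5 × 40 individuals and 5,000 loci over 10 replicates;
kinship at 20,000 loci (the allele-matching estimators need >10⁴ SNPs for
tight dyad means); scan calibration and power at 5,000 loci with 200
individuals and a planted 0.4 frequency differential at 2% of loci; the
GEA at 250 individuals × 3,000 loci with 60 planted loci at logit effect
3 per SD on a 0.8-weight gradient (a strong local-adaptation scenario —
the triple intersection is conservative, and weaker effects lower recall
before they inflate the FDR); admixture at 2 × 30 and 500 loci with
F = 0.3. Bootstrap defaults are 1,000 replicates in the API and 50–200 in
tests.

## Known limitations

* The admixture EM is unaccelerated; hundreds of thousands of loci and
  K > 8 are out of its comfortable range.
* β-kinship is relative to the sampled cohort; values are not comparable
  across datasets without a common reference, and the diagonal reports
  inbreeding, not self-kinship.
* The scan's GIF recalibration assumes most loci are neutral; with
  pervasive selection the correction over-shrinks.
* The LD prune is conservative by design (see above); panels meant to
  maximise retained sites should use a dedicated optimiser.
* `prep_env()` keeps the first-listed variable of a correlated pair;
  variable order is an analytic choice the caller owns.
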