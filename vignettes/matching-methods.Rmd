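---
title: "Matching heterogeneous cohorts by projected principal components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching heterogeneous cohorts by projected principal components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcmatch)
```

## The problem

Case-control GWAS in ancestrally heterogeneous groups — for example
cohorts assembled by self-identified ethnicity — suffer from population
stratification: allele frequencies and disease risk both vary with
ancestry, so unmodeled ancestry inflates association statistics
genome-wide. A disease-focused cohort is often too small on its own,
while a large biobank offers power but a very different ancestry mix.
`pcmatch` implements a pipeline for combining the two: select the
biobank participants who are *genetically similar* to the disease
cohort, run a covariate-adjusted GWAS in each cohort, and meta-analyze.

The stages are:

1. **Quality control** (`qcPipeline`): technical-replicate removal,
   sample and variant missingness, HET/HOM-ratio outliers, KING-robust
   relatedness pruning, PC outliers, minor-allele-count/privacy and
   Hardy–Weinberg filters.
2. **Reference PC space** (`referencePCA`, `projectCohort`): PCA of the
   disease ("reference") cohort on LD-pruned common variants, then
   projection of the biobank ("target") cohort into that space using the
   reference standardization frequencies.
3. **Matching** (`propensityMatch`): logistic propensity model
   `Cohort ~ PCs + status (+ age + sex)`, subclassification on the
   reference-cohort score quantiles, density-ratio weights with the
   reference fixed at weight 1, and selection of target samples with
   weight at least 1.
4. **Association** (`logisticScan`, `firthFallbackPolicy`): per-variant
   additive logistic regression with covariates and a Firth-penalized
   refit of small-p or unstable records; genomic-control diagnostics
   (`genomicLambda`).
5. **Meta-analysis** (`ivwMeta`, `metaFilters`, `clumpVariants`):
   fixed-effect inverse-variance weighting, harmonization and
   frequency-amplitude/df/HWE filters, greedy LD clumping of significant
   loci.
6. **Power** (`powerAdditive`, `minGrrForPower`): analytic additive-model
   power and detectable genotype relative risks.

All of it is exercised on synthetic cohorts from the bundled simulator,
because the cohorts this design is aimed at are access-controlled.

## The simulator and what it does (not) emulate

`drawAncestralFrequencies` draws ancestral allele frequencies uniformly
(default 0.05–0.5) and differentiates K populations with the
Balding–Nichols model: population frequencies are
Beta(p(1−F)/F, (1−p)(1−F)/F) around the ancestral frequency p, so the
between-population variance is F·p(1−p). `drawAdmixture` gives each
sample Dirichlet admixture proportions; two cohorts differ through their
concentration vectors. `simulateGenotypes` draws each genotype
Binomial(2, q·pop_freqs) with optional uniform missingness.
`simulatePhenotypes` builds a logistic liability with a numerically
calibrated intercept (so the marginal case rate equals the requested
prevalence, default 11.1%), optional causal dosage effects,
per-ancestry log-odds offsets (the confounder), age and sex effects, and
a proxy phenotype obtained by misclassifying clinical status with given
sensitivity/specificity — an abstraction of family-history ("by-proxy")
case definitions.

Deliberate simplifications: variants are independent (no linkage
disequilibrium; `simulateLDBlock` appends crude correlated copies for
exercising pruning and clumping), there is no sequencing-error or
batch-effect model, no sex chromosomes, and proxy noise is symmetric
misclassification rather than a family-structure model. Passing tests
therefore show that the *statistical machinery* behaves as designed
under its own assumptions — calibration under the null, stratification
control, correct oracle arithmetic — not that real WGS data meet those
assumptions.

Default study conditions for the two-cohort scenario
(`stratificationScenario`): three ancestral populations at Fst 0.1, a
4,000-sample reference cohort with Dirichlet concentrations (5, 3, 2)
and a 20,000-sample target with (3, 4, 5). The concentrations were
calibrated so that PC-only matching selects about 18% of the target —
the proportion of the biobank that matched in the study this package
models (44,793 of 245,388). The confounded phenotype uses per-ancestry
log-odds offsets (1, 0, −1); ages are Uniform(55, 90) and standardized
before entering the liability.

## Projection, shrinkage and the PC space

Dosages are standardized as (g − 2p)/√(2p(1−p)) with p estimated **in
the reference cohort only**; the same p standardizes the target, so the
two cohorts share one coordinate system and frequency differences show
up as score offsets rather than being normalized away. Residual missing
calls are imputed to the mean dosage 2p (zero after standardization).
Components carry a deterministic sign (largest-magnitude loading
positive). Out-of-sample projections contract toward the origin;
`estimateShrinkage(method = "jackknife")` estimates per-component
correction factors by 10-fold leave-out (floored at 1, and they approach
1 as the reference grows). The propensity model is invariant to
per-component rescaling, so matching results do not depend on the
correction; it matters when scores are interpreted geometrically
(ancestry assignment, outlier masks).

`jaccardPCs` provides the rare-variant analogue used as GWAS covariates
for the reference cohort: pairwise Jaccard similarity of rare-minor-
allele carrier profiles (reference MAF < 1%; similarity 0 by convention
for samples carrying nothing), double-centered, eigendecomposed, and the
top eigenvectors scaled to unit variance — our reading of "standardized
variance", which the source tooling leaves unspecified.

## Matching conventions

Several choices are open in subclassification matching; ours are:

- Subclass boundaries are quantiles of the **reference** cohort's
  propensity scores (the estimand keeps every reference sample at
  weight 1), 500 subclasses by default, merged downward when a subclass
  contains no reference sample.
- A target sample in subclass s receives the density ratio
  n_ref(s)/n_target(s), and target weights are rescaled to mean 1, so
  the selection rule "weight ≥ 1" reads as *at least the average
  affinity to the reference*. Both published phrasings of the selection
  rule read as inclusive, so the threshold is ≥ 1.
- Affection status enters the propensity model as a covariate exactly
  as in the design being reproduced, even though conditioning on an
  outcome-adjacent variable is debatable; we reproduce, not repair.
- Separation in the propensity fit is an error that points to
  `penalize = TRUE` (a Firth-penalized fit) rather than silently
  returning boundary scores.

## Association-test choices

The scan is single-step covariate-adjusted ML logistic regression (IRLS,
warm-started at the covariate-only fit, tolerance 1e−8, 50 iterations),
with per-variant mean imputation of residual missing dosages. Records
that fail to converge or land beyond |beta| > 10 are never reported as
Wald results; together with records at p < 0.01 (and minor-allele count
≥ 20) they are refit by Firth-penalized likelihood, tested with the
penalized likelihood-ratio test — better calibrated than a Wald test on
penalized estimates at low minor-allele counts and finite under
separation. The whole-genome ridge prediction step of the biobank-scale
tool the study used is intentionally out of scope; principal components
and user covariates stand in for it.

Note a finite-sample caveat the simulations make visible: with a few
hundred samples and ~20 covariates, Wald chi-squares inflate by roughly
p/n even under the null. The calibration claims (genomic-control lambda
near 1) are therefore asserted at the acceptance scale (thousands of
matched samples, 50,000 null variants), where the lambda estimator's
own sampling noise (≈0.01) dominates.

## Meta-analysis conventions

Effects are combined with inverse-variance weights; alleles are
harmonized to the first study, flipping swapped alleles and resolving
strand-ambiguous (A/T, C/G) variants by frequency proximity only when
both studies are informative (|eaf − 0.5| > 0.1), dropping them
otherwise. Reported allele frequency is the sample-size-weighted mean;
the frequency amplitude (max − min eaf across studies) must be strictly
below 0.4; only variants present in both studies (df = 1) survive; and
per-population Hardy–Weinberg mid-p tables, when supplied, gate at
1e−15. Clumping is greedy on ascending p (ties by id) with r² > 0.01
within 1 Mb of the lead — the r² threshold is from the design being
reproduced, the window is our default since none is stated.

## Power: two rules, one calibration

`powerAdditive` is exact: penetrances f0, f1 = GRR·f0,
f2 = (2·GRR − 1)·f0 solve the prevalence constraint under
Hardy–Weinberg; case/control allele (or genotype) frequencies give a
1-df noncentrality, and power is the noncentral chi-square tail beyond
the alpha critical value. At GRR = 1 it returns exactly alpha, and a
Monte-Carlo rejection-rate oracle agrees with it across a test grid.

`minGrrForPower` must also reproduce the detectable-GRR thresholds that
the widely used University of Michigan web calculator prints for this
design, and a calibration exercise showed that no classical
80%-power criterion does: the printed thresholds for all six
(MAF, design) pairs correspond, to the printed precision, to a single
cut on the alternative-variance allele-test noncentrality — the point
where the expected Wald statistic reaches the one-sided genome-wide
quantile (median detectability), at which exact noncentral power is
near 0.5, not 0.8. The default `rule = "calculator"` therefore applies
that detectability criterion (reproducing the printed table to ±0.01),
while `rule = "analytic"` gives the textbook smallest GRR whose exact
noncentral power reaches the target. Reports should state which rule
they used.

## Numerical and degenerate-input conventions

- Hardy–Weinberg mid-p: exact enumeration over compatible heterozygote
  counts via a log-scale recurrence; monomorphic tables return 1; ties
  in table probability contribute half (relative tolerance 1e−12).
- KING-robust kinship uses each pair's mutually non-missing variants and
  skips pairs with fewer than 100 of them; the HET/HOM ratio floors its
  denominator at 1; the second-degree cutoff is 2^−3.5 ≈ 0.0884, the
  standard KING band boundary.
- Greedy relatedness removal breaks ties by higher missingness, then
  lexicographic id, so results are reproducible.
- LD pruning scans left to right, drops the lower-MAF member of any
  pair above the r² threshold, and prefers the earlier variant on exact
  MAF ties.
- Dirichlet draws with very small concentrations can underflow to an
  all-zero gamma vector; the limiting one-hot draw is substituted.
- The liability intercept is solved by `uniroot` on [−50, 50]; an
  unattainable prevalence is an error, not a silent clamp.

## Problem sizes used by the shipped checks

The test suite runs the full two-cohort scenario once (4,000 + 20,000
samples, 50,000 null variants, 2,000 of them forming the PC block,
chunked scans), plus module tests on cohorts of tens to a few thousand
samples; the effect-recovery checks use 30 replicates at n = 20,000 and
at the 12,038/41,222 case-control design. These sizes were chosen so
the whole suite completes on a single CPU in well under half an hour
while keeping the lambda estimator's noise near 0.01.

## Known limitations

- The projection is least-squares onto reference loadings with an
  optional jackknife shrinkage correction; the online-augmentation
  (OADP) projector used by the original tooling is not implemented.
- Calibration statements are asymptotic; small matched cohorts with
  many covariates inflate Wald statistics (see above).
- The simulator's independence assumptions make pruning and clumping
  nearly trivial except on constructed LD blocks.
- Only a two-sided additive 1-df test is covered by the power module;
  dominant/recessive/multiplicative models are out of scope.
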