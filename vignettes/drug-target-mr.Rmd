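---
title: "Drug-target mendelian randomisation with correlated instruments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-target mendelian randomisation with correlated instruments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(targetmr)
```

## The problem

Lipid-modifying drugs (statins inhibiting HMG-CoA reductase, PCSK9
inhibitors, CETP inhibitors, triglyceride-lowering agents acting through
APOC3, ANGPTL3/4 or LPL) can be proxied genetically: variants in or near the
gene encoding a drug target that robustly associate with the lipid the drug
modifies act as instruments for pharmacological modulation of that target.
Regressing instrument–outcome on instrument–exposure associations then
estimates the genetically predicted effect of target modulation on any
outcome with GWAS summary statistics — disease risk or, metabolome-wide, a
panel of NMR metabolic traits. Comparing the resulting metabolic signatures
across targets asks whether drugs with similar effects on disease risk act
through similar or different metabolic fingerprints.

`targetmr` implements this workflow end to end — association scans,
cis instrument selection, LD pruning, correlated-instrument IVW estimation,
per-target FDR control, signature scaling and concordance, and an
individual-level genetic-risk-score sensitivity analysis — together with a
synthetic cohort generator with known ground truth, so that every stage is
testable without access to individual-level biobank data.

## The estimator

For instruments $j = 1,\dots,k$ with exposure associations
$\hat\beta_{Xj}$ (per effect allele, on an exposure normalised to SD 1),
outcome associations $\hat\beta_{Yj}$ with standard errors
$\hat\sigma_{Yj}$, and pairwise LD correlations $\rho_{jk}$ from a
reference panel, the correlated-instrument IVW estimate is generalised
weighted least squares with covariance
$\Omega_{jk} = \hat\sigma_{Yj}\hat\sigma_{Yk}\rho_{jk}$:

$$
\hat\theta = (\beta_X^\top \Omega^{-1} \beta_X)^{-1}
             \beta_X^\top \Omega^{-1} \beta_Y,
\qquad
\mathrm{se}(\hat\theta) = \sqrt{(\beta_X^\top \Omega^{-1} \beta_X)^{-1}} .
$$

The LD correlations are thereby incorporated into the standard-error terms
of the weighted regression. With $\rho = I$ this is exactly the classical
fixed-effect IVW (inverse-variance-weighted average of per-instrument Wald
ratios with weights $\beta_{Xj}^2/\sigma_{Yj}^2$), and with $k = 1$ it is
the Wald ratio $\hat\beta_Y/\hat\beta_X$ with delta-method standard error
$\hat\sigma_Y/|\hat\beta_X|$; both reductions are verified to machine
precision in the test suite. Identifying assumptions are the usual
instrumental-variable ones: instruments associate with the exposure, share
no confounder with the outcome, and affect the outcome only through the
exposure. Restricting instruments to the cis region of the encoding gene is
the design's main defence of the third assumption.

Design choices worth stating explicitly:

* **Fixed-effect $\Omega$.** No residual-heterogeneity multiplier is
  applied by default; `ivw_correlated()` is the plain generalised
  least-squares solve.
* **Exposure-side uncertainty** ($\hat\sigma_{Xj}$) is ignored in the
  estimator, the standard two-sample practice; it enters only the
  instrument-strength summary.
* **F statistic.** Reported as the mean squared instrument z-score
  $\frac1k \sum_j (\hat\beta_{Xj}/\hat\sigma_{Xj})^2$, a summary-level
  approximation chosen because only summary statistics are available at
  estimation time; values below roughly 10 flag weak-instrument risk.
* **Ill-conditioned $\Omega$** (smallest eigenvalue below $10^{-10}$ times
  the largest) is a hard error naming the most collinear variant pair, not
  a silent regularisation: LD pruning at $r^2 < 0.1$ is the intended
  conditioning mechanism, and a near-singular $\Omega$ means it was not
  applied.
* **Confidence intervals** use the 1.96 normal quantile on the estimation
  scale (log-odds for binary outcomes), exponentiated for odds ratios.

## Instrument selection

Candidates for a target are variants with $P < 10^{-6}$ within 100 kb
either side of the encoding gene. Coordinates are 1-based and the window
interval is closed on both ends. The 50-kb sensitivity set is derived by
restricting the pruned 100-kb set to the narrower window
(`sensitivity_instruments()`), which makes it nested within the main set by
construction and keeps the pairwise $r^2$ bound intact. A fresh
re-selection at 50 kb would not guarantee nesting: removing an
out-of-window variant can un-block a correlated proxy that greedy pruning
had dropped, so window choice would be confounded with instrument swaps in
the sensitivity comparison. Candidates are ordered by ascending
P (ties broken by position, then variant ID) and greedily pruned: a
candidate is kept iff its squared correlation with every already-kept
variant is below 0.1, so the best-P variant always survives and the kept
set is maximal under the greedy order. Signed LD $r$ is retained for the
estimator's $\Omega$; only the pruning rule uses $r^2$. Targets left with a
single instrument are excluded from the screen by default
(`min_instruments = 2`): a gene-centric estimate from one variant in a
gene-dense region is too exposed to confounding by neighbouring genes.

Harmonisation aligns outcome records to the exposure's effect alleles:
exact matches pass, swapped alleles negate the outcome beta and complement
the frequency, anything else is dropped with a recorded reason. Palindromic
(A/T, C/G) variants are kept and aligned by exact label match by default —
appropriate when both samples come from one genotyping pipeline — with
`drop_palindromic = TRUE` available for cross-consortium use. The oriented
estimate multiplies $\hat\theta$ and its CI by the target's therapeutic
direction ($-1$ for LDL- and triglyceride-lowering targets, $+1$ for
HDL-raising CETP), so all reported effects are per 1 SD of exposure change
in the direction the drug acts.

## Screening, FDR and concordance

The metabolome screen selects instruments once per target and reuses them
across all outcome traits (selection depends only on the exposure side; the
test suite verifies reuse changes nothing). Benjamini–Hochberg FDR control
at 5% is applied within one family per drug target — that target's traits —
never pooled across targets. A trait that loses more than half of a
target's instruments during harmonisation is flagged missing and excluded
from the FDR family rather than imputed.

For cross-target comparison, each signature is divided by the absolute
value of that target's oriented disease (CAD-like) log-odds effect, putting
all targets on the scale "trait SD per unit of disease-risk reduction". The
absolute value makes every target point toward risk reduction regardless of
its therapeutic direction. Concordance between two scaled signatures is the
coefficient of determination of an intercept-included least-squares
regression of the comparator's estimates on the baseline's, computed as the
variance quotient of fitted over observed values. The regression direction
matters for the slope but barely for $r^2$; the convention (comparator on
baseline, baseline defaulting to the first/statin-like target) is fixed and
recorded in the output. Traits missing in either signature are dropped
pairwise.

## The age-stratified GRS analysis

Adjusting for or stratifying on medication use conditions on a collider
(treatment is caused by the exposure and associated with the outcome), so
robustness to treatment effects is probed indirectly: weighted genetic risk
scores (instrument–exposure betas, oriented, summed over effect-allele
dosages) are regressed on phenotypes separately in the youngest (40–54) and
oldest (61–71) age bands, where treatment prevalence differs sharply, with
age, sex and 10 principal components as covariates. Scores are standardised
to unit SD within each stratum so slopes are per SD of score, and the two
stratum estimates are compared by a two-sample z statistic — a formalised
version of the usual visual comparison. Sparse missing dosages are
mean-imputed (capped at 10% per variant); more than 10% of score variants
absent is an error.

## The synthetic cohort generator

The generator is first-class, tested code that defines the study
conditions; it emulates the features of biobank data the method actually
exploits and nothing more.

* **Genotypes.** Each individual is two independent haplotypes. A
  haplotype's alleles are indicators of a latent standard-normal AR(1)
  process falling below the variant's MAF quantile, so the latent
  correlation between variants $i$ and $j$ is $\rho^{|i-j|}$ with a single
  interpretable decay parameter, allele frequencies are exact by
  construction, and Hardy–Weinberg proportions follow from haplotype
  independence. The default $\rho = 0.6$ gives adjacent-dosage $r^2$ in the
  0.2–0.3 range, enough that pruning and the correlated-IVW covariance both
  do real work.
* **Exposures.** Each exposure is a weighted sum of causal dosages plus
  Gaussian noise, divided by its *analytic* SD computed from the effect
  sizes, allele frequencies and the AR(1) structure (the dosage covariance
  uses the bivariate normal CDF, evaluated by one-dimensional quadrature of
  the conditional normal CDF at relative tolerance $10^{-10}$). Dividing by
  the model-implied rather than empirical SD keeps the ground-truth disease
  effect $\theta$ exact in log-odds per SD, which is what parameter-recovery
  tests require. Default per-allele effects (~0.1 exposure SD, explaining
  roughly 0.5% of variance per variant) match the strongest real lipid
  loci.
* **Metabolites.** Linear loadings on the exposures plus optional direct
  variant effects (pleiotropy) and Gaussian noise. The demo panel has one
  third of traits loading on each exposure and one third on neither,
  mimicking pathway-shared subcategories of an NMR panel.
* **Disease.** Bernoulli draws from a logistic model in the exposures; the
  intercept for a target prevalence is found by integrating the logistic
  mean over the standard-normal genetic liability and root-finding.
  The demo uses 10% prevalence; parameter-recovery tests use 15%.
* **Covariates** (age 40–71, sex, fasting time, chip, 10 PCs) are drawn
  independently of genotype by default; a `confounder_sd` switch adds a
  shared latent factor across exposures for negative-control tests.
* **Partitioning.** One cohort is split into disjoint discovery / outcome /
  reference samples (default 50% / 49% / 1%), giving a genuine two-sample
  design and a ~500-individual LD reference panel at the default cohort
  size, the size of a typical public reference panel.

What the generator deliberately does **not** emulate: real haplotype block
structure and recombination maps, population stratification and
relatedness, assay-specific measurement error, non-linear or threshold
effects, and rare variants (MAF below 0.1 by default). Passing tests
therefore demonstrate correctness of the estimation machinery under the
model's own assumptions — not robustness to violations a real biobank might
present. In the same spirit, the association scan uses covariate-adjusted
least squares (via Frisch–Waugh–Lovell residualisation, numerically
identical to per-variant joint regression) and logistic regression rather
than a linear mixed model: with no simulated relatedness or structure there
is nothing for a mixed model to absorb, and the estimand coincides. This is
the package's one deliberate methodological substitution relative to
biobank-scale practice.

## Numerical and degenerate-case conventions

* Rank-based inverse normal transform: Blom offset $c = 3/8$,
  $\Phi^{-1}((r - c)/(n - 2c + 1))$, ties by mean rank, missing values
  preserved; all-identical input is an error (the transform is undefined).
* P values from the normal approximation throughout, the large-sample GWAS
  convention.
* Monomorphic variants: emitted with beta 0 and missing SE by the scan,
  rejected by LD computation, excluded from selection.
* Logistic scans flag non-converged or separated fits (missing SE) and
  harmonisation drops such records with a reason.
* Partition sizes are rounded cumulative fractions, exact whenever
  `n * fraction` is integral.
* All randomness flows through per-stage seeds derived from one master
  seed; identical configurations give bitwise-identical outputs, and the
  global RNG state of the calling session is never disturbed.
* Locus hit-counting uses greedy ±500 kb clumping seeded at the smallest P,
  with the window exposed as a parameter, since "independent loci" has no
  universal definition.

## Problem sizes used by the test suite

The package's statistical guarantees are exercised at sizes chosen to make
Monte-Carlo tolerances meaningful on a single desk machine: parameter
recovery and confidence-interval coverage over 100 replicate cohorts of
n = 50,000 (one 30-variant locus, AR(1) 0.6, true effect −0.25 log-odds per
SD); type-I error over 200 null replicates of n = 20,000; FDR calibration
over 100 replicates of a 200-trait global-null metabolome at n = 10,000;
concordance contrast at n = 50,000. Estimator–oracle equivalence is checked
against explicit matrix-inversion solves on 200 random instances to
relative error $10^{-10}$.

## Known limitations

Beyond the generator's scope above: no MR-Egger, weighted-median/mode or
multivariable MR (the estimator family is deliberately the IVW core); no
fine-mapping, colocalisation or trans instruments; no
meta-analysis across cohorts; the random-effects variance multiplier is
available behind a flag but not the default and carries no heterogeneity
diagnostics. The F-statistic approximation cannot be validated against any
external formula since none is fixed by convention at summary level.
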