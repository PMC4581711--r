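---
title: "Linking SNPs, blood transcripts and metabolites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking SNPs, blood transcripts and metabolites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Genome-wide scans routinely find loci associated with blood metabolite
concentrations (mQTLs), but an association between a SNP and, say, a
circulating acylcarnitine says nothing about mechanism. If the same locus
also regulates the abundance of a nearby transcript (an eQTL) and that
transcript's abundance is itself associated with the metabolite, the three
associations close into an *association triangle* — a candidate causal
chain *variant → transcript → metabolite*. triqtl implements the full
analysis sequence needed to find and test such triangles in a two-cohort
design: targeted-metabolomics preprocessing, a genome-wide mQTL scan with
permutation-based FDR control, LD-pruned lead-SNP selection and
direction-consistent replication through proxy SNPs, cis/trans eQTL
mapping, the expression–metabolite layer, triangle discovery against a
permutation/Poisson null, and two complementary causal analyses: an
adapted Mendelian randomization (MR) estimator and a jackknife
beta-attenuation mediation test.

Because no individual-level cohort of this kind can be redistributed, the
package ships a synthetic two-cohort generator with planted ground truth;
every stage is exercised and scored against what was planted.

# Statistical model

## The shared linear engine

Every association layer uses the same covariate-adjusted ordinary least
squares model. For a quantitative trait $y$ (a prepared metabolite
quantity or transcript), a focal predictor $x$ (a SNP gene dose in
$[0,2]$, or a transcript when testing expression–metabolite links) and
covariates $C$:

$$y = \alpha + \beta x + \gamma^{\top} C + \varepsilon$$

with two-sided p values from the $t$ distribution at
$df = n - \#\text{regressors}$, complete cases taken listwise per test
(so $n$ varies across tests and is reported). Dichotomized
below/above-detection traits run through the same engine as a linear
probability model; their trait kind is recorded in every output. The
focal predictor's explained variance is the partial $R^2$,

$$R^2_{\text{partial}} = \frac{t^2}{t^2 + df},$$

which equals the two-model RSS ratio
$(RSS_{\text{reduced}} - RSS_{\text{full}})/RSS_{\text{reduced}}$ — the
tests verify this identity against an explicit two-model fit. Matrix
scans (`assoc_scan()`) compute the same quantities via the Frisch–Waugh
projection (residualize trait and predictors on $[1, C]$, then simple
regression) and are tested for exact agreement with pair-wise fits.

## Multiplicity

SNP–metabolite tests are heavily correlated (LD among SNPs, biochemical
correlation among quantities), so the discovery scan controls FDR with an
empirical permutation null rather than an independence-based method: the
phenotype block is permuted as a whole against the genotype+covariate
block (1000 permutations by default), preserving both correlation
structures, and the full grid is rescanned each time. With observed
statistics $s_i$ (we use $-\log_{10} p$) and pooled null exceedance
counts,

$$\widehat{FDR}(t) = \frac{\frac{1}{B}\sum_b \#\{s^{(b)} \ge t\}}
 {\max(1, \#\{s \ge t\})},\qquad
q(s_i) = \min_{t \le s_i} \widehat{FDR}(t).$$

Covariates stay attached to the genotypes during permutation, so the null
reflects covariate-adjusted exchangeability; this choice (the phenotype
link, not the residual structure, is broken) is recorded in output
metadata. Replication uses the same machinery with a one-sided signed-z
statistic oriented by the discovery direction. The eQTL layer instead
follows the standard practice for expression scans: layer-specific
(cis/trans) Benjamini–Hochberg thresholds at FDR 5%, cross-checked by 100
label permutations (`verify_bh_with_permutations()`).

## From scan to validated loci

* discovery reporting cut-off $p < 10^{-7}$ (a liberal two-stage design:
  the stringency lives in replication);
* per-SNP ranking by minimal p over quantities, greedy LD pruning at
  $r^2 < 0.3$ (dose correlation); the pruned result is verified against a
  brute-force enumeration of the greedy rule in the tests;
* lead SNPs merged into loci by single linkage at 1 Mb (the merge
  distance is a configurable assumption — the field reports "unique
  genomic locations" without defining them);
* proxy search for leads absent from the replication panel: candidates
  within ±50 kb, imputation info > 0.3, LD computed in the *discovery*
  cohort (where lead and candidate coexist), qualifying at $r^2 > 0.8$,
  best $r^2$ wins;
* replication: each pair retested through its proxy with the replication
  cohort's (smaller) covariate set; the proxy's effect is oriented by the
  sign of its dose correlation with the lead; *replicated* = direction
  consistent **and** permutation $q \le 0.05$. Pairs whose orientation is
  indeterminate ($|r| < 0.05$) are excluded with a warning rather than
  guessed.

## Triangles and their null

A triangle is a SNP significantly associated with a transcript (its
layer's BH threshold) and with a metabolite (validated mQTL), whose
transcript is also significantly associated with that metabolite (BH
within the candidate grid: eQTL-significant probes × metabolites
associated at the corresponding SNP — not the full panel). Strict mode
follows the locus-wise rule (top SNP per locus, its best metabolite, its
significant eQTL probes) and feeds the causal module; exhaustive mode
enumerates all significant closures for the network export.

The chance expectation is sized by block permutations: the expression
block and the metabolite block are independently reassigned against the
genotypes and the entire chain — scan, pruning, locus assignment, eQTL,
expression–metabolite, triangle closure — is rerun per permutation (100 by
default) with the observed run's thresholds frozen. When a frozen
threshold is empty (nothing was significant in the observed run), the
permutation rerun derives that layer's own threshold exactly as the
original analysis would, so the null remains meaningful under a global
null. The observed count $k$ is then compared against
$X \sim \text{Poisson}(\hat\lambda)$ with $\hat\lambda$ the mean permuted
count, via the stable tail $P(X \ge k)$. Re-pruning inside each
permutation is the default (conservative); `freeze_leads = TRUE` reuses
the observed lead set.

## Causal analyses

Both analyses run per triangle on the common complete-data sample set,
with exact leave-one-out jackknife standard errors computed through the
case-deletion identity
$\hat\beta_{(-i)} = \hat\beta - (X^{\top}X)^{-1} x_i e_i/(1-h_i)$
(algebraically identical to refitting $n$ times; the tests compare the
two on small samples to $10^{-10}$):

**Adapted MR** (`mr_adapted()`). Plain MR with the SNP as instrument is
invalid when the SNP also affects the metabolite directly. The
adaptation removes the direct path first: fit
$y \sim g + e + C$, take the direct SNP coefficient $c$, form
$y^{*} = y - c\,g$, then estimate the causal expression effect as the
covariate-adjusted IV ratio
$\hat\beta_{MR} = \hat\beta(y^{*} \sim g + C)\,/\,\hat\beta(e \sim g + C)$.
Under a direct-plus-mediated generating model this provably restores the
expression effect — the tests plant $y = 0.4e + 0.3g + \varepsilon$ and
recover 0.4. Instruments with $|t| < 2$ in the relevance regression are
flagged weak and their p value withheld. The exact construction of the
SNP-residualization is this package's reading of the adaptation (the
choice is flagged in all outputs): it is the one under which the IV ratio
is consistent in the planted-model tests.

**Beta-attenuation mediation** (`mediation_attenuation_test()`). Fit the
SNP model without and with the transcript on the same samples and test

$$\Delta = |\hat\beta_{\text{without}}| - |\hat\beta_{\text{with}}|$$

against zero with its jackknife SE (two-sided normal reference —
justified by cohort-scale $n$). A significantly positive $\Delta$ means
the transcript accounts for part of the SNP–metabolite association. We
use the absolute-value difference (attenuation of magnitude), recording
the choice; reported causal conclusions rest on this test, which is more
conservative than MR. Note what the triangle alone cannot do: a SNP with
independent effects on transcript and metabolite produces a perfectly
significant triangle through confounding by genotype — in the synthetic
study such triangles appear and the mediation test correctly declines to
call them (see the acceptance run: 3 of 5 triangles significant, exactly
the planted mediated chains).

# Preprocessing

**Metabolites** (order is enforced; any other order raises an error):

1. *derive*: ratios $(\sum \text{num})/(\sum \text{den})$ and sums on the
   **raw** concentration scale (arsinh of a ratio is not a difference of
   arsinhs, so deriving before transforming is the only consistent
   order); any missing component or zero denominator makes the derived
   value missing (zero denominators are counted in a report);
2. *dichotomize*: columns with **strictly more than 20%** of readings
   below the detection limit become below/above indicators (exactly 20%
   stays quantitative);
3. *arsinh*: $x \mapsto \ln(x + \sqrt{x^2+1})$ — log-like for large
   values, defined at zero; negative concentrations are an error;
4. *mask outliers*: per column, a **single pass** with the interval
   mean ± 5 SD computed once on the non-missing values (no iterative
   re-estimation); zero-variance columns are skipped with a warning.

Below-detection readings are treated as missing in quantitative
analyses; what value (if any) the original panels carried for such
readings is unknowable from summary descriptions, and the missing
treatment keeps the dichotomization rule and the quantitative analyses
consistent.

**Expression**: probes kept when detected ($p \le 0.05$) in at least 5%
of samples (inclusive boundary); quantile normalization across samples
(limma) then $\log_2$; three sample-outlier rules, each at
median + 3·IQR — expressed-probe count, Euclidean distance to an
"artificial individual" (the mean profile after removing the
$\lceil 0.10\,n\rceil$ samples farthest from the plain mean; the ceiling
resolves the ambiguity for non-integral 10%), and Mahalanobis distance of
per-sample QC features (singular QC covariance is ridge-regularized with
a warning); batch adjustment; residualization on covariates first, then
on the first five principal components of the already-residualized
matrix. The Euclidean rule operates on the normalized scale (it precedes
batch adjustment in the chain). Residualization is idempotent and leaves
$|r| < 10^{-8}$ with every regressor.

Batch adjustment offers two modes. `meanscale` (default): per probe,
batch means removed and batch SDs rescaled to the pooled SD.
`eb`: the same correction with the per-(probe, batch) location and
log-scale estimates shrunk toward their across-probe means by a
moment-estimated normal-prior weight — a deliberately simple parametric
empirical-Bayes scheme whose contract (batch moments harmonized; in the
infinite-prior-precision limit every probe receives its batch's average
correction) is what the tests pin down, not a clone of any published
algorithm.

# The synthetic study

`simulate_study()` generates the conditions every test and the
acceptance run use. Defaults: discovery $n = 2000$, replication
$n = 1000$; 300 SNPs in blocks of 5 drawn from pools of 20 founder
haplotypes (LD within blocks from pool sharing, independence across
blocks; the second SNP of each block copies the first's haplotype column,
giving every block a built-in near-perfect proxy); MAF uniform on
(0.05, 0.5); dosage noise $N(0, 0.05^2)$ truncated to $[0,2]$ with
info = $1 - \sigma^2_{\text{noise}}/\text{Var(dose)}$; 120 probes (six
of them unexpressed background probes that the detection filter must
remove) in 3 batches with per-(batch, probe) shifts of SD 0.3; 20 raw
metabolites plus two ratios and one sum; per-column detection limits at
the 5% quantile (30% for two designated poorly-detected columns, which
the >20% rule must dichotomize); covariates age ~ N(60, 10²),
sex ~ Bernoulli(0.5) and three synthetic genetic PCs ~ N(0,1), with age
and sex effects planted on alternating metabolites.

Twenty effects are planted: six direct SNP→metabolite (0.3–0.5 SD/dose;
one of them on a SNP that also carries a trans eQTL, so the trans layer
is exercised among validated leads), five cis and two trans SNP→probe,
four probe→metabolite, and three mediated chains
SNP→probe→metabolite marked explicitly (0.8 SD/dose and 0.5 SD/SD — the
induced SNP–metabolite association then clears the $10^{-7}$ discovery
cut-off at $n = 2000$, and the SNP→probe effect sits at the upper end of
the explained-variance range reported for strong cis eQTLs). Metabolites
respond to the *biological* component of expression (genetic effect plus
biological noise), not to batch shifts: batch artifacts are technical
and should not propagate into chemistry. Raw concentrations are
$\exp(\text{latent})$, giving the positively skewed scale the arsinh
transform is meant for. The replication cohort shares pools and effects,
drops 10% of SNPs (never the built-in proxies) to exercise the proxy
search, and is analyzed with the reduced covariate set (age, sex).

What the generator does **not** emulate — and hence what green tests do
not establish about real data: recombination gradients and realistic LD
decay, population structure and relatedness, assay drift within plates,
metabolite–metabolite pathway coupling beyond what planted effects
induce, strand ambiguity (allele orientation is resolved by dose
correlation, which suffices only because strand flips are absent), and
any nonlinearity in dose–response.

# Numerical and design choices

* Two-sided p from the $t$ distribution, not the normal approximation.
* Probe centers are kept real-valued (possibly half-integral); the cis
  window is inclusive at exactly 1 Mb.
* Monomorphic predictors are errors in single fits and NA records in
  scans; collinear covariates error in single fits but are dropped with
  a warning during expression residualization.
* The permutation q-value uses the pooled-exceedance estimator (FDR is
  the target, not FWER) and is capped at 1; q is monotone in the
  statistic by construction.
* `poisson_tail_p()` computes $P(X \ge k)$ in log space; $k=0$ gives 1
  and $\lambda = 0$ gives 0 for $k \ge 1$. A permutation mean of exactly
  zero therefore yields a degenerate tail p of 0; the null counts
  themselves are always reported alongside.
* Jackknife SEs in the causal module come from exact case-deletion
  updates, not refits; leverage ≥ 1 is an explicit error.
* Stage seeds are derived from the master seed by fixed offsets, so any
  stage can be reproduced in isolation; identical seeds reproduce every
  output bit-identically (tested).

# Problem sizes

The default test-and-acceptance conditions were chosen so the scientific
claims are testable at desk scale: the full synthetic study at
2000 + 1000 samples; the FDR calibration at 5000 SNP–metabolite pairs
(500 SNPs × 10 traits, 5% planted effects of 0.15 trait-SD per dose at
MAF 0.3, 200 permutations, 20 seeds); genomic-inflation checks at 10,000
null tests; the triangle null at 20 full-pipeline permutations inside the
test suite and 100 in the acceptance run. In the calibration mixture the
per-trait noise variance is set so each trait has unit total variance,
making the planted effect exactly 0.15 trait-SD/dose.

# Known limitations

* The eQTL scan covers the pruned lead-SNP list only (as in a two-stage
  design), not a genome-wide transcript scan.
* The triangle Poisson test degenerates when the permutation null is
  empty ($\hat\lambda = 0$); with 100 permutations the resolution of
  $\hat\lambda$ is 0.01.
* Dichotomized traits use the linear engine (linear probability model);
  with rare "above detection" categories a logistic model would be more
  efficient.
* The MR adaptation assumes the direct SNP effect is linear and additive
  with the mediated path; pleiotropy-robust or multi-instrument
  estimators are out of scope.
* Sample QC features are synthetic Gaussians; the Mahalanobis rule's
  behaviour on strongly non-Gaussian real QC panels is untested here.
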