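---
title: "PRS-stratified EWAS and poly-methylomic profile scores: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PRS-stratified EWAS and poly-methylomic profile scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the models, their assumptions, the tunable parameters with their defaults,
what the synthetic-data generator does and does not emulate, and the design
decisions taken where more than one reasonable convention exists. Nothing
here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. Polygenic scoring by clumping and thresholding

The score is the average-per-allele weighted dosage sum
$$\mathrm{PRS}_i = \frac{1}{2m}\sum_{j:\,p_j < p_T} \beta_j\, d_{ij},$$
where $\beta_j$ is the external GWAS log-odds effect for allele A1 of
variant $j$, $d_{ij} \in [0,2]$ the A1 dosage, and $m$ the number of
included variants. Conventions, each chosen to match the widely used
scoring tool and each exposed as an argument:

* **Averaging.** Dividing by $2m$ (rather than a raw sum) makes scores
  comparable across thresholds; raw-sum users can reconstruct it as
  `raw * 2 * n_snps_included`.
* **Missing dosages** are imputed as $2\,\mathrm{MAF}_j$, not dropped.
* **Harmonisation.** When the panel codes the opposite allele, the dosage is
  flipped to $2-d$ (effect signs untouched), so scores are invariant to
  allele coding; strand-ambiguous pairs (A/T, C/G) are removed because their
  orientation is unknowable from summary data; unresolvable allele
  mismatches are dropped with a logged reason rather than raising an error,
  since a handful of messy variants should not kill a genome-wide run.
* **Clumping** is greedy by ascending p-value within a 250 kb window at
  $r^2 > 0.1$ (the scoring tool's defaults; the design only requires
  *locally* independent index SNPs). Equal p-values are broken by genomic
  position, lower first, so results are order-stable.
* **Threshold grid.** `optimize_threshold()` defaults to
  $\{5\times10^{-8}, 10^{-5}, 10^{-4}, 0.001, 0.005, 0.017, 0.05, 0.105,
  0.229, 0.5, 1\}$ — a conventional grid that includes the optima commonly
  reported for bipolar-disorder, depression and cross-disorder scores — and
  maximises Nagelkerke pseudo-$R^2$
  $$R^2 = \frac{1 - \exp\{(2/n)(\ell_0-\ell_1)\}}{1 - \exp\{(2/n)\,\ell_0\}}$$
  of a logistic case/control fit. Samples with missing phenotype (e.g. the
  high-risk group, which is neither case nor control) are excluded from the
  fit, mirroring how such cohorts code them as missing. Thresholds with
  complete separation are skipped and flagged rather than reported with an
  infinite estimate.

**Relatedness.** $\hat\pi$ is method-of-moments IBD from IBS counts with
HWE-expected sharing at empirical allele frequencies; pairs with
$\hat\pi \ge 0.1$ trigger exclusion of the member with more missing
genotypes (tie: the later sample id — the keep rule is a free choice and is
documented rather than silent). **Ancestry** components are classical MDS of
the IBS distance $1 - \mathrm{shares}/(2m)$ — the specific distance is a
design choice, stated here because conventions differ. **Outliers** use the
mean IBS distance to the four nearest neighbours, Z-standardised, excluding
$Z > 4$; mean-of-4 (rather than per-neighbour maxima) was chosen as the
simplest statistic consistent with "divergent nearest-neighbour" screening.

## 2. Quintile stratification

`quintile_strata()` sorts by score (stable in input order for ties) and
assigns the bottom and top $\mathrm{round}(0.4\,n)$ (half-up) samples to Low
and High. Half-up rounding is the unique rule reproducing both 41-of-103
and 27-of-67 strata, the two cohort sizes this design is typically quoted
for.

## 3. Probe QC, deconvolution, smoking

The analysis CpG set is the intersection of four per-probe filters
(order-invariant by construction): 10th–90th percentile β range strictly
greater than 0.05; membership of a blood-variable reference list;
blood–brain concordance $|\bar r| \ge 0.3$ (sign-agnostic — a strongly
anti-correlated probe is as informative about brain methylation as a
positively correlated one); and no annotated SNP within 50 bp. Probes
missing a concordance value while the filter is on count as failures,
reported separately. β values are clipped to $[10^{-6}, 1-10^{-6}]$ before
the M-value logit so the transform stays finite; the inverse is exact on
the clipped range.

Cell fractions solve, per sample, $\min_w \|x - Rw\|^2$ subject to
$w \ge 0,\ \Sigma w \le 1$ by quadratic programming **on the β scale**,
because purified reference profiles are β-scale measurements; the inequality
(rather than equality) on $\Sigma w$ lets profiles outside the reference
span take mass below one instead of distorting the fit. Smoking is inferred
from cg05575921 with a strict β < 0.75 rule (0.75 exactly is a non-smoker).

## 4. The per-probe model and the empirical null

The discovery scan regresses M-values on the stratum indicator (Low = 0,
High = 1; a negative coefficient means hypomethylation in the high-burden
stratum) with covariates sex, age, two MDS components, tissue source,
batch, and five of the six estimated cell fractions — the largest
(granulocytes) is dropped because estimated fractions summing to ≈1 are
collinear with the intercept. Variance moderation (empirical-Bayes shrinkage
of residual variances toward a pooled scaled-inverse-χ² prior, with
augmented degrees of freedom) is on by default and can be disabled with
`moderate_var = FALSE`; all calibration properties hold in both modes.

**Surrogate variables** are estimated by a deterministic two-step: residualise
M on the fixed design, take the SVD of the residuals, and keep the top
components whose eigenvalue share beats all of $B = 20$ row-wise permutations
(permutation $p < 0.05$), stopping at the first failure. This differs from
iteratively-reweighted SVA: the two-step is reproducible given a seed and
isolates dimension selection (the permutation step) from estimation; the
installed reference implementation of the permutation selector is used as an
independent cross-check in the tests, never as the estimator.

**Empirical-null correction.** Two-sided p-values are converted to signed
z-scores $z = \mathrm{sign}(b)\,\Phi^{-1}(1-p/2)$ and modelled as a
three-component Gaussian mixture by Gibbs sampling (default 5000 iterations,
2000 burn-in): a null component whose posterior-mean mean and SD are the
*bias* and *inflation*, plus one negative and one positive alternative.
Priors are conjugate — Dirichlet(5, 1, 1) on the weights (null-dominant),
normal-inverse-gamma on each component with IG(2, 1) variance priors.
Two constraints keep the mixture identified, and both matter in practice:

* alternative SDs may not fall below the null SD (otherwise a narrow
  alternative "shrink-wraps" the null's tails and the inflation estimate is
  biased low by several percent);
* alternative means are truncated at least 1.5 null-SDs away from the null
  mean (otherwise a wide alternative sitting on the null mean can absorb
  half the null mass, biasing both estimates).

Corrected statistics are the affine transform
$z' = (z - \mathrm{bias})/\mathrm{inflation}$ with two-sided normal
p-values, so rank order is preserved exactly. The sampler is compiled code
using R's RNG stream, so `set.seed()` reproduces chains bit-for-bit.
Multiple testing uses Bonferroni $\alpha/m$ (reported at 3 significant
figures alongside full precision) and BH-FDR q-values. The QQ display uses
the rank-0.5 convention $-\log_{10}((\mathrm{rank}-0.5)/m)$; the "inflection
point" reporting threshold defaults to $p < 0.002$ and is purely a reporting
device, not an algorithm.

## 5. Profile scores and validation models

The poly-methylomic profile score is a *sum* (not mean) of target-set
methylation weighted by discovery coefficients over CpGs passing the
discovery threshold ($p_T \in \{0.002, 0.01, 0.05\}$ by default):
$$\mathrm{PMPS}_i = \sum_{j:\,p_j < p_T} b_j\,\beta_{ij}.$$
Four conventions are genuinely underdetermined in this literature and are
all exposed as switches, with these defaults: β-scale target values
(`scale = "m"` available), sum aggregation (`aggregate = "mean"`
available), raw coefficients as weights (the empirical-null correction
rescales z-scores, not coefficients, so "corrected weights" would only
change a global scale factor), and corrected p-values for selection.
Probes absent from the target matrix are dropped silently and counted.

Validation uses type-III F-tests with sum-to-zero contrasts (the
univariate-GLM convention of the usual commercial software), partial
$\eta^2 = SS_\mathrm{term}/(SS_\mathrm{term}+SS_\mathrm{resid})$, and
Shapiro–Wilk normality per group. The interaction model adds PRS and
PRS×Group; the family-environment model reports Wald $\chi^2 = (b/se)^2$
per single-df term with 1-df χ² p-values, which is mildly anticonservative
at small n (the committed pilot table quantifies this: a 0.072 null
rejection rate at n = 66 over 400 replicates).

## 6. Gene mapping and enrichment

Regulatory domains follow basal-plus-extension: basal = TSS −5 kb/+1 kb
(strand-mirrored), extended outward up to 5 kb but never into a
neighbouring gene's basal domain. The 5 kb distal limit follows the printed
configuration of the common web tool; its usual 1 Mb default is available
via `distal = 1e6`. Coordinates are 1-based inclusive throughout the R API.
The MHC region is *not* excluded, and no correction is made for gene length
or probe density — a known bias of hypergeometric gene-level enrichment
that callers should weigh when interpreting results. Enrichment is
one-sided upper-tail hypergeometric per set, intersected with the supplied
background, BH-adjusted across sets.

## 7. What the synthetic generator emulates — and what it does not

`simulate_cohort()` provides the statistical structure the analysis
assumes, with every default chosen once as a realistic study condition:

* **Genotypes**: latent-Gaussian AR(1) copulas thresholded at MAF quantiles
  give controllable local LD in blocks (defaults: `block_rho = 0.8`, blocks
  1 Mb apart, 5 kb SNP spacing); a coalescent simulation was deliberately
  avoided because only clumping behaviour needs realistic local correlation.
  Sibling pairs inherit parental haplotypes per LD block
  ($E[\hat\pi] = 0.5$) to exercise relatedness filtering.
* **GWAS summary statistics**: Wald sampling with
  $SE = 1/\sqrt{2\,\mathrm{MAF}(1-\mathrm{MAF})\,N}$ at `gwas_n = 50000`,
  causal effects scaled to unit genetic variance, planted only on variants
  that survive standard QC so the architecture is recoverable.
* **Methylation**: bimodal baseline log2-odds (modes ±2.8), logit-scale
  cell-type offsets mixed by Dirichlet fractions (concentration
  ≈ granulocyte-dominant blood), probe×batch effects (SD 0.2), a smoking
  probe, and coupled probes shifted by `coupling_effect` (default 0.4
  M-units per SD of the score) — planted among mid-methylated probes that
  pass all CpG filters, because a coupled probe the QC would remove cannot
  carry signal into the scan. Probe-level residual SD is uniform on
  [0.25, 0.65], typical of blood array M-values; at the design's 41-vs-41
  stratum contrast this puts a 0.5 M-unit planted effect at roughly
  half-to-two-thirds Bonferroni power, which is the regime the power tests
  probe.
* **Phenotypes**: liability threshold
  $\ell = \sqrt{h^2}\,g + \sqrt{1-h^2}\,\varepsilon$ with cases above the
  90th percentile and the high-risk label given to the top of the non-case
  liability distribution, ordering group means control < high-risk < case.

Not emulated: IDAT-level signals and their normalisation artefacts,
realistic genome-wide LD maps, trans-ethnic structure, probe
cross-reactivity, and genotype imputation. Passing tests therefore
demonstrate statistical correctness of the pipeline under its assumed
data-generating model, not robustness to array-specific technical noise.

## 8. Numerical choices and degenerate inputs

β clipping at $10^{-6}$; QP ridge $10^{-9}$ on the Gram matrix;
p-values floored at $10^{-300}$ before the z conversion (which uses the
upper-tail quantile form to avoid catastrophic cancellation); empty
surrogate-variable sets are returned as zero-column matrices with a
message; monomorphic-only panels are an error for relatedness (IBD is
undefined); a threshold passing no SNPs names itself in the error; probes
with fewer than 20 complete observations abort the fit. Experiment sizes in
the test suite (cohorts of ~100–400 samples, 3000–5000 probes, 20 seeded
replicates) were chosen to match the strata sizes this design is quoted
for while keeping each experiment in the minutes range on a single CPU.

## 9. Known limitations

The empirical-null sampler assumes a three-component Gaussian family;
heavy-tailed alternatives are absorbed into inflated alternative variances
rather than modelled. Cell deconvolution is linear on the β scale while the
generator mixes on the logit scale, so estimated fractions are good but not
exact — which is also true of real reference-based deconvolution. The
pipeline consumes normalised β matrices; quantile-level normalisation of
raw intensities is out of scope. Family-clustered inference (GEE-style) is
not implemented; the discovery design assumes unrelated samples after the
$\hat\pi$ filter.
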