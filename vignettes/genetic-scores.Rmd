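---
title: "Odds-ratio-weighted genetic scores for case-control studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Odds-ratio-weighted genetic scores for case-control studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoscore)
```

## The problem

Family history is the classical proxy for inherited disease risk, but it is
uninformative when families are small or disease ascertainment has been
poor.  A genetic score built from a handful of validated risk SNPs offers a
direct, per-individual measurement of inherited risk.  genoscore implements
the whole case-control workflow around such scores for a
renal-cell-carcinoma-style study design — a few hundred cases, around a
thousand controls, and of the order of ten candidate SNPs — though nothing
in the code is specific to that disease.

## The score model

For each risk SNP we start from the per-allele (allelic) odds ratio
$\mathrm{OR}$ stated on the *risk* allele, so $\mathrm{OR} \ge 1$ by
construction, and the population risk-allele frequency $p$.  Under the
multiplicative (log-additive) model the genotypic odds ratio for $g \in
\{0,1,2\}$ copies of the risk allele is $\mathrm{OR}^g$.  The
population-average genotypic risk under Hardy–Weinberg proportions is

$$\bar{R} \;=\; p^2\,\mathrm{OR}^2 + 2p(1-p)\,\mathrm{OR} + (1-p)^2,$$

and a subject's per-SNP factor is the relative risk
$\mathrm{OR}^g / \bar{R}$.  The genetic score is the product of these
factors over the model's SNPs.  Two consequences matter:

* **Normalization.** By construction the HWE-weighted mean of each factor is
  exactly 1, so the expected score in the general population is 1 (the
  per-SNP identity is algebraic; the product form needs linkage
  equilibrium between model SNPs, which is why the model is LD-pruned).
  A score of 1 therefore reads as "population-average inherited risk",
  0.8 as below-average, 1.2 as above-average.
* **Additivity on the log scale.** $\log S = \sum_k g_k \log \mathrm{OR}_k -
  \text{const}$, so the score is a monotone function of the familiar
  weighted allele count; the multiplicative presentation only changes the
  interpretable origin.

`score_model()` constructs the fitted object directly from published
(rsID, risk allele, OR, frequency) rows; `build_score_model()` derives one
from an association screen, inverting protective ORs (an OR of 0.60 on one
allele is restated as 1/0.60 ≈ 1.67 on the other) and pruning SNP pairs in
linkage disequilibrium.  `predict()` applies the model to a genotype table,
re-orienting each SNP's dosage to the risk allele in memory so that files
never need re-coding.

### Choices made where the design was open

* **Frequency source.** Published models typically use reference-panel
  (e.g. HapMap) risk-allele frequencies; a cohort's controls are the
  fallback.  Both are supported (`freq_source`), recorded on the model, and
  default to external frequencies when supplied.  The bundled presets use
  plausible Han-Chinese frequencies (0.35, 0.51, 0.25, 0.30 for the four
  panel SNPs); the normalization identity holds whatever the frequencies,
  so downstream properties are insensitive to the exact values.
* **Missing genotypes** contribute a factor of 1 — the population-average
  risk — and are counted in `n_missing`.  This is neutral (it never moves a
  subject across the score-1 boundary by itself) but shrinks extreme
  subjects toward the mean; subjects missing every model SNP are an error
  rather than a silently meaningless score of 1.
* **LD pruning** keeps, of any pair with $r^2$ at or above the threshold
  (default 0.5), the designated SNP, else the one with the smaller
  association p-value; with neither available the pair is an error rather
  than an arbitrary choice.  ORs are taken as fixed inputs at scoring time;
  re-estimation belongs to the association module.

## The association screen

`assoc_screen()` reproduces the standard per-SNP case-control screen: the
2×2 allele-count table (missing genotypes excluded pairwise), minor-allele
frequencies in cases and controls, the cross-product odds ratio with the
Woolf log-scale 95% CI, and a p-value from the uncorrected chi-square
allelic test — switched to Fisher's exact test when the combined-sample
minor-allele frequency is below 5% (the combined sample is the symmetric
choice; the convention is configurable).  Controls are checked for
Hardy–Weinberg equilibrium with the exact conditional test (enumeration of
the heterozygote distribution given allele counts; no mid-p).  The
Bonferroni threshold `alpha/m` is attached to the result.  Zero cells take
the Haldane–Anscombe 0.5 correction with an explicit flag.  Logistic
regression (`logistic_assoc()`, `score_case_logistic()`) provides the
covariate-adjusted path; the crude allelic test and the logistic test are
deliberately separate operations since published tables rarely say which
produced them.

## Stratification and discrimination

`assign_strata_fixed()` bins scores at cutpoints (default 0.8 and 1.2) with
half-open intervals, the top bin closed below — the only consistent reading
of "low < 0.8, medium 0.8–1.2, high ≥ 1.2" labels.
`assign_strata_quantile()` splits at pooled-cohort quantiles with
right-closed boundaries, so boundary ties fall to the lower group
deterministically; with a 3-SNP model scores take only 27 distinct values,
so quartile groups are visibly unequal — that is a property of the data,
not a bug.  `stratum_likelihood()` reports each stratum's in-sample case
percentage ("likelihood" in the epidemiological reading); note this depends
on the case:control sampling ratio and is *not* an absolute risk.  Trend
across ordered strata is the 1-df Cochran–Armitage chi-square with integer
scores 0,1,2,… and no continuity correction (at k = 2 it equals the
uncorrected 2×2 chi-square).  Discrimination is summarized by the midrank
(Mann–Whitney) AUC, whose threshold-sweep ROC curve has trapezoidal area
equal to the midrank estimate to machine precision; confidence intervals
use DeLong placements by default, Hanley–McNeil as the cheap alternative —
published analyses of this design rarely say which they used, and the two
agree to well under 0.01 half-width at this study size.

## What the simulator emulates — and what it does not

`sim_config()` / `simulate_case_control()` generate cohorts with the
structure the analysis assumes: biallelic SNPs in HWE, designated pairs
drawn from two-locus haplotypes solving
$D = \pm\sqrt{r^2\,p_a(1-p_a)p_b(1-p_b)}$ (positive D by default; the
published $r^2 = 0.58$ pair is a feasibility-checked special case), disease
assigned by a logistic model whose per-allele coefficients are the log ORs,
subjects accumulated by rejection sampling until the target 346 cases and
1,130 controls are reached, and ages drawn per group (55.9 ± 12.5 in cases,
51.2 ± 9.7 in controls).  The baseline log-odds of −4 is arbitrary — under
case-control ascertainment it changes sampling effort, not odds ratios — and
a draw budget guards against hopeless intercepts.  One master seed feeds
per-SNP and per-stage derived streams, so enlarging a panel never perturbs
the draws of existing SNPs.

The simulator deliberately omits population structure and admixture,
genome-wide LD beyond configured pairs, genotyping error and missingness
mechanisms, and any age–genotype dependence.  Tests passing on simulated
cohorts therefore certify the statistical machinery (estimator
calibration, normalization, trend and ROC behaviour), not robustness to
confounding in real data.

## Numerical choices and problem sizes

The HWE exact test enumerates the conditional heterozygote distribution by
log-space recurrence (stable to thousands of alleles); ties in "no more
probable than observed" use a $1+10^{-12}$ relative slack.  The EM
haplotype-frequency estimator iterates to $10^{-10}$ (phase is ambiguous
only for double heterozygotes, so convergence takes a handful of
iterations).  Monomorphic SNPs: HWE p = 1 by convention, LD $r^2$ is an
error.  Quantile boundaries use R's default (type-7) quantiles.

The test suite checks distributional properties at sizes chosen to keep
Monte-Carlo error well inside the asserted tolerances while running in
minutes: normalization on 1,000 random (OR, p) pairs; population-mean score
on 50,000 subjects (3 Monte-Carlo SEs); CI coverage over 500 replicate
cohorts at 346/1,130 (binomial SE ≈ 1%); type-I error of the HWE and trend
tests over 10,000 null replicates (bound α + 0.01); LD round-trips at
n = 20,000 (±0.03); and the simulated-cohort AUC against the exact AUC
computed from the 27-cell genotype-class distribution (±0.005 on a mean of
three 20,000-subject cohorts).

## Known limitations

ORs enter as fixed constants — there is no shrinkage, no interaction or
dominance terms, and no uncertainty propagation from the screen into the
score.  "Likelihood" per stratum is design-dependent, as noted.  VCF
support is minimal (biallelic GT only) and read-only.  The package offers
no absolute-risk calibration: translating a score of 1.5 into a lifetime
risk needs external incidence data.
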