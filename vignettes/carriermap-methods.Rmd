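---
title: "Methods: retrospective association and fine-mapping in carrier cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retrospective association and fine-mapping in carrier cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carriermap)
```

# The problem

Cohorts of women carrying pathogenic mutations in a high-risk gene (the
package labels the two groups BRCA1 and BRCA2) are ascertained through
clinical genetics programmes, so sampling is strongly outcome-dependent:
families enter the study because someone was affected. Naive survival
analysis of such a sample biases per-allele hazard-ratio estimates for a
candidate risk-modifier SNP. `carriermap` implements the standard remedy —
a *retrospective* likelihood, the probability of the observed genotypes
given the phenotype histories — together with the surrounding machinery a
fine-mapping analysis needs: kinship-aware testing, SNP quality control,
cross-group meta-analysis, conditional scans, credible sets and
regulatory-feature overlap, plus a synthetic-cohort generator so that the
whole pipeline can be exercised against known truth.

# The retrospective genotype likelihood

Each carrier is followed from entry (age 18 by default) until the first
of disease onset, risk-reducing surgery (RRSO) or last observation; only
onsets are events. The per-allele model multiplies an age-band baseline
hazard by $e^{\beta g}$ for genotype $g \in \{0,1,2\}$ copies of the
effect allele.

The carrier incidence curve $\mu_b$ (the penetrance) is treated as known.
Because carriers of the protective allele are enriched among survivors at
later ages, the baseline hazard $\lambda_0(b)$ cannot simply equal
$\mu_b$: `constrain_baseline()` solves, band by band,

$$ w_g(b) = \frac{p_g S_g(b)}{\sum_h p_h S_h(b)}, \qquad
   \lambda_0(b) = \frac{\mu_b}{\sum_g w_g(b) e^{\beta g}}, \qquad
   S_g(b+1) = S_g(b)\,e^{-\lambda_0(b) e^{\beta g} \Delta_b}, $$

with Hardy–Weinberg birth probabilities $p_g$ at the sample minor-allele
frequency. This makes the genotype-averaged incidence equal $\mu_b$ in
every band exactly (a unit-tested invariant). The likelihood of subject
$i$'s genotype given their phenotype is then

$$ L_i(\beta) = \frac{f_i(g_i;\beta)\,p_{g_i}}
   {\sum_g f_i(g;\beta)\,p_g}, \qquad
   f_i(g;\beta) = S_g(t_i)\,\bigl(\lambda_0(b(t_i)) e^{\beta g}\bigr)^{\delta_i}. $$

Conditioning on phenotype makes the estimate invariant to any sampling
scheme that depends on phenotypes alone — which is exactly the
clinic-ascertainment situation. At $\beta = 0$ the phenotype cancels and
the likelihood degenerates to the genotype prior, a property the tests
assert directly.

`estimate_hr()` maximises this over $\beta \in [\ln 0.1, \ln 10]$ by 1-d
numerical optimization (tolerance $10^{-8}$), with the standard error
from the numerical observed information. Dosages are rounded to hard
genotypes for the likelihood; the score test below uses raw dosages, the
simplest defensible split for imputed data (rounding is innocuous for the
prior-weighted likelihood but would discard imputation information in the
test).

# The kinship-adjusted score test

Relatives share genotypes, so score contributions are not independent.
`kinship_score_test()` computes the stratified Cox partial-likelihood
score at $\beta = 0$, $U = \sum_{\text{events}} (g_i - \bar g_{R(t_i)})$,
accumulates per-individual score residuals $u_i$ (Breslow convention for
ties), and uses the sandwich variance
$\widehat{\mathrm{Var}}(U) = \sum_{ij} 2\phi_{ij} u_i u_j$ with kinship
coefficients $\phi$ ($\phi_{ii} = 0.5$, full sibs $0.25$). With everyone
unrelated this is the robust score variance $\sum_i u_i^2$, and the test
statistic $U^2/\widehat{\mathrm{Var}}(U)$ reproduces an independently
coded stratified Cox score test to $10^{-10}$ in the tests. Strata follow
the study design: country, an Ashkenazi sub-stratum for USA/Canada, and
birth-year bins (decades by default; the granularity is configurable
because published descriptions rarely state it).

Two subtleties surfaced while validating the adjustment and are worth
recording. First, when phenotypes are independent given genotypes (no
shared family frailty — the generator's situation), sib score residuals
are *uncorrelated under the null*: the kinship adjustment changes the
null variance by at most a percent or two, and can even shrink it
slightly through risk-set centering. The inflation the adjustment exists
for appears under an alternative, where the genotype-driven drift of the
score correlates sib residuals; the test suite checks exactly that.
Second, the robust score variance and the retrospective observed
information are different finite-sample estimators, so score and Wald
chi-squares agree in expectation (replicate-mean ratio within 15% of 1 in
the suite) but not replicate by replicate.

# Meta-analysis, conditional scans, credible sets

Per-SNP log hazard ratios from the two groups are combined by
fixed-effect inverse variance (`invvar_meta()`), with Cochran Q
($\chi^2_{k-1}$) for heterogeneity; SNPs present in only one group are
excluded. `se_from_ci()` reconstructs $\mathrm{SE}(\log \mathrm{HR})$
from printed 95% intervals so published per-study rows can be pooled.
Reconstructed p-values inherit the rounding of printed intervals and can
deviate several-fold; they are reported but never used as an acceptance
surface.

Independent signals are assessed by `conditional_scan()`: an ordinary
Cox model per SNP with the index-SNP dosage as covariate, adjusting for
birth year (linear by default; configurable) and stratifying by country.
Kinship is deliberately ignored here — the conditional Cox framework is
used only as a validity-preserving test for residual association, and a
SNP is a residual signal when its conditional p stays below $10^{-4}$.
Collinear test/index pairs ($r^2 = 1$) are flagged rather than fitted.

`credible_set()` implements the likelihood-ratio rule: with 1-df
statistics, $\mathrm{LR} = \exp\{(\chi^2_{\text{top}} - \chi^2)/2\}$,
and a variant stays in the set of potentially causal variants iff
$\mathrm{LR} \le 100$ *and* $r^2$ with the top SNP $> 0.1$. The
chi-square comes from the score test when full data are available and
from the $p \to \chi^2_1$ transform when only summary p-values exist;
the two routes coincide by construction. LD is computed on the same
post-imputation dosage matrix used for association (not a reference
panel), ties for the top SNP break by smaller position, and the rule is
verified against brute-force enumeration on randomized instances.

# The synthetic-cohort generator

The generator is first-class, tested code; it defines the study
conditions under which every downstream property is demonstrated.

* **Haplotypes.** A Gaussian copula: block-exchangeable latent
  correlation (`within_block_rho`), thresholded at the minor-allele
  frequency quantile. This gives direct, monotone control of within-block
  $r^2$ and exactly zero expected LD across blocks. It does not emulate
  recombination-map distance decay — LD is flat within a block — so
  credible sets on synthetic data have sharper LD boundaries than real
  ones.
* **Families.** Each family contributes $1 + \mathrm{Poisson}$ genotyped
  sisters who inherit from four parental haplotypes; sib dosage
  correlation is $2\phi = 0.5$ (tested). Kinship matrices are sparse
  block-diagonal.
* **Onset and censoring.** Onset ages invert the cumulative hazard of the
  incidence-constrained model at the causal SNP, so the population
  marginal incidence equals the penetrance curve by construction —
  `estimate_hr()` is therefore evaluated against exactly the model it
  assumes (a deliberate choice: parameter-recovery tests isolate
  estimator error from model misspecification). Censoring is the
  earliest of RRSO (exponential, default rate 0.01/yr from entry) and
  last observation (reference year 2010 minus birth year, capped at 80).
  At BRCA1-like defaults this yields roughly 16% affected, matching the
  scale of real carrier cohorts.
* **Penetrance defaults.** Piecewise-constant 5-year band hazards
  calibrated so cumulative risk to 80 is ~0.42 centred near age 50
  (BRCA1-like) and ~0.25 centred near 60 (BRCA2-like), inside the
  published 35–60% and 12–25% lifetime-risk ranges.
* **Ascertainment.** Families with at least one affected member are kept
  with probability 1, unaffected families with a configured probability —
  a deliberately simple clinic-ascertainment proxy. Because the
  retrospective likelihood conditions on phenotypes, estimates are
  insensitive to this dial, which the null/recovery tests exploit by
  leaving it at 1.
* **Imputation noise.** Imputation is modelled as observing each hard
  genotype through an additive Gaussian read-noise channel and reporting
  the posterior-mean dosage under an HWE prior. The posterior mean
  shrinks toward $2p$ as noise grows, so the realized info score
  (observed dosage variance over $2p(1-p)$) decreases monotonically from
  1 toward 0 — the defining behaviour of the info metric. Pure additive
  noise on the dosage would instead inflate the variance ratio above 1,
  which is why that simpler formulation was rejected. The per-SNP noise
  SD is solved by `uniroot` so the realized info hits its target.

What the generator does **not** emulate: shared family frailty beyond the
causal SNP (so kinship adjustment under the null is nearly neutral, see
above), recombination-distance LD decay, mutation-class-specific
penetrance, competing breast-cancer outcomes, genotyping batch effects.
Passing tests therefore demonstrate correctness of the estimators and
rules under the stated model, not robustness to these real-data features.

# Numerical and design choices

* Optimization bracket $\beta \in [\ln 0.1, \ln 10]$; estimates at the
  bracket warn. Observed information by central differences
  ($h = 10^{-3}$).
* Monomorphic SNPs error in estimation, flag `NA` in the score test, and
  are skipped (with a logged reason) by `scan_assoc()`.
* QC keeps boundary values: *lower than* 0.3 info / 0.005 MAF excludes,
  equality retains. `NA` info (monomorphic) is excluded as unmeasurable.
* Coordinates: SNPs are 1-based (VCF convention); BED intervals half-open
  0-based; a SNP at position $P$ overlaps $[s, e)$ iff $s \le P-1 < e$ —
  fixed and unit-tested at both boundaries.
* All stochastic operations take explicit integer seeds and are
  bit-reproducible; the pipeline derives all stage seeds from one root
  seed.
* Problem sizes in the shipped analysis: 2,000 families (~3,200 carriers)
  in the BRCA1-like group, 55% of that in the BRCA2-like group, 300 SNPs
  in 30 LD blocks — a deliberate desk-scale study that keeps the full
  workflow to a couple of minutes while preserving the qualitative
  behaviour of interest. Parameter-recovery properties in the test suite
  run at ~4,000 carriers per replicate with 100 replicates; simulator
  fidelity is checked at ~20,000.

# Known limitations

* The penetrance curve is treated as known; real analyses propagate no
  uncertainty from it, and neither does this package.
* The retrospective likelihood here conditions per individual; it does
  not model residual within-family phenotype correlation (the kinship
  adjustment addresses the genotype side only).
* Conditional scans use prospective Cox models (valid as tests, not as
  unbiased carrier-cohort effect estimates).
* The credible-set rule is the frequentist LR-plus-LD gate, not a
  Bayesian posterior credible set.
* Reconstructing p-values from printed CIs is rounding-limited (see
  above).
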