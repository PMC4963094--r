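# carriermap

Fine-scale mapping of risk-modifier loci in cohorts of high-risk mutation
carriers.

Carrier cohorts (e.g. women with pathogenic *BRCA1*/*BRCA2* mutations
followed for ovarian cancer) are ascertained through clinical genetics
programmes, so sampling depends on disease outcomes and ordinary survival
analysis of a candidate SNP is biased. `carriermap` implements the
retrospective-likelihood approach — modelling the probability of the
observed genotypes conditional on phenotype histories — and everything a
fine-mapping analysis of one locus needs around it:

* **Per-allele hazard ratios** by retrospective maximum likelihood with an
  incidence-constrained piecewise baseline hazard: the baseline
  `lambda0(b)` is solved band-by-band so the genotype-averaged incidence
  equals the carrier penetrance curve `mu_b` exactly, with hazard
  `lambda0(b) * exp(beta * g)` for `g` copies of the effect allele.
* **Kinship-adjusted stratified score test**: score
  `U = sum_events (g_case - riskset mean)` with sandwich variance
  `Var(U) = sum_ij 2*phi_ij u_i u_j` over score residuals `u`, so related
  carriers (kinship `phi`) do not inflate the test.
* **QC filters**: imputation info < 0.3 or MAF < 0.005 excluded
  (boundaries retained).
* **Fixed-effect inverse-variance meta-analysis** across mutation groups
  on the log-HR scale with Cochran Q heterogeneity; per-study SEs can be
  reconstructed from printed 95% CIs.
* **Conditional Cox scans** on an index SNP (birth-year adjusted, country
  stratified) with a `p < 1e-4` retention rule for independent signals.
* **Credible sets** by the likelihood-ratio rule: a variant stays
  potentially causal iff `LR vs top <= 100` and `r2 with top > 0.1`.
* **Regulatory-feature overlap** of credible-set variants with BED tracks
  (half-open 0-based intervals vs 1-based SNPs, unit-tested).
* **A synthetic carrier-cohort simulator** (LD-blocked haplotypes, carrier
  penetrance, families, RRSO/end-of-follow-up censoring, ascertainment,
  imputation noise with realistic info scores) so the entire pipeline is
  testable against known truth.

See `vignettes/carriermap-methods.Rmd` for the model, its assumptions and
the design decisions.

## Worked example

Pool two published per-study rows for one SNP (HR with 95% CI per group)
and test heterogeneity:

```r
library(carriermap)
se1 <- se_from_ci(0.74, 0.69, 0.79)   # group 1: HR 0.74 (0.69-0.79)
se2 <- se_from_ci(0.74, 0.64, 0.84)   # group 2: HR 0.74 (0.64-0.84)
invvar_meta(log(c(0.74, 0.74)), c(se1, se2))
#>    beta_meta    se_meta  hr_meta    ci_low   ci_high       p_meta q_stat df p_het
#> 1 -0.3011051 0.03090982 0.739999 0.6964936 0.7862928 1.949468e-22      0  1     1
```

The pooled per-allele HR is 0.74 (95% CI 0.70–0.79) with no
heterogeneity between groups (`q_stat = 0` for identical effects).
Credible-set membership from published p-values works through the 1-df
chi-square transform:

```r
lr_from_p(p_snp = 5.2e-13, p_top = 2.0e-16)  # 2292.4 -> excludable (> 100)
lr_from_p(p_snp = 6.7e-6,  p_top = 1.0e-6)   # 6.21   -> retained  (<= 100)
```

## The synthetic end-to-end study

The `analysis/` scripts run the whole workflow on simulated carrier
groups (run them from the repository root, in order):

```sh
Rscript analysis/01_simulate_cohorts.R   # cohorts, dosage VCFs, kinship
Rscript analysis/02_qc.R                 # info/MAF filters
Rscript analysis/03_association_scan.R   # retrospective HRs + score tests
Rscript analysis/04_meta_analysis.R      # inverse-variance meta, Cochran Q
Rscript analysis/05_conditional_scan.R   # conditioning on each top SNP
Rscript analysis/06_credible_sets.R      # LR <= 100 & r2 > 0.1 rule
Rscript analysis/07_annotate.R           # regulatory-feature overlap
```

Outputs land under `results/`. At the shipped desk scale (2,000 families
per group, 300 SNPs, causal per-allele HR 0.73) the run prints, among
other lines:

```
BRCA1: 3213 carriers in 2000 families, 529 affected (16.5%); 300 SNPs, 17 poorly imputed
BRCA1: top SNP snp0150_causal, HR 0.79 (95%CI 0.70-0.89), p = 0.00024; 0 SNPs at p < 5e-8
meta:  top SNP snp0150_causal, HR 0.77 (95%CI 0.69-0.86), p = 6.9e-06
BRCA1: conditioned on snp0150_causal; 0 residual signals at p < 1e-4
BRCA1: top snp0150_causal; 4-SNP credible set; causal variant IN the set
BRCA2: top snp0218; 9-SNP credible set; causal variant NOT in the set
```

The larger group maps the causal variant into a small credible set with
no residual conditional signal; the half-sized BRCA2-like group is
underpowered and its credible set is noise-driven — the same power
asymmetry seen in real two-group fine-mapping studies. The equivalent
single call `run_pipeline(demo_config(seed = 1), "results/run")` executes
all stages and writes a manifest.

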