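#!/usr/bin/env Rscript
# Simulate the two carrier groups (BRCA1-like and BRCA2-like) over one
# LD-blocked fine-mapping window with a single protective causal variant,
# add imputation noise, and write the genotype/phenotype/kinship files
# that every later stage reads back.
source("analysis/_common.R")

cfg <- study_config()
spec <- carriermap:::config_spec(cfg)
cens <- do.call(censoring_spec, cfg$censoring)

for (gi in seq_along(GROUPS)) {
  gname <- GROUPS[gi]
  gcfg <- cfg$groups[[gname]]
  cc <- cohort_config(n_families = gcfg$n_families, gene_label = gcfg$gene,
                      hr_per_allele = gcfg$hr_per_allele,
                      seed = cfg$seed + 1000L * gi)
  pen <- if (gname == "BRCA1") brca1_penetrance() else brca2_penetrance()
  sim <- simulate_cohort(cc, spec, pen, cens)

  # imputation-noise profile: mostly well-imputed, ~5% poorly imputed
  set.seed(cfg$seed + 1000L * gi + 1L)
  target <- runif(spec$n_snps, cfg$imputation$info_high[1],
                  cfg$imputation$info_high[2])
  poor <- runif(spec$n_snps) < cfg$imputation$frac_poor
  target[poor] <- runif(sum(poor), cfg$imputation$info_poor[1],
                        cfg$imputation$info_poor[2])
  target[spec$causal_index] <- 1          # the causal SNP stays genotyped
  noisy <- add_imputation_noise(sim$dosages, target,
                                seed = cfg$seed + 1000L * gi + 2L)

  pre <- file.path(SIM_DIR, gname)
  write_vcf_dosages(paste0(pre, "_dosages.vcf"), noisy$dosages, sim$records)
  write_phenotypes(paste0(pre, "_phenotypes.tsv"), sim$cohort)
  write_kinship(paste0(pre, "_kinship.tsv"), sim$kinship)
  write_tsv(data.frame(snp_id = sim$records$snp_id,
                       info = ifelse(is.na(noisy$info), 0, noisy$info),
                       genotyped = target == 1),
            paste0(pre, "_info.tsv"))

  message(sprintf(
    "%s: %d carriers in %d families, %d affected (%.1f%%); %d SNPs, %d poorly imputed",
    gname, nrow(sim$cohort), length(unique(sim$cohort$family_id)),
    sum(sim$cohort$event), 100 * mean(sim$cohort$event),
    spec$n_snps, sum(poor)))
}
message("Causal variant: ", sprintf("snp%04d_causal", spec$causal_index),
        " at position ", spec$positions[spec$causal_index],
        " (per-allele HR ", cfg$groups$BRCA1$hr_per_allele, ")")
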