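#!/usr/bin/env Rscript
# Fixed-effect inverse-variance meta-analysis of the two carrier groups
# on the log-HR scale, restricted to SNPs available in both, with
# Cochran Q heterogeneity per SNP.
source("analysis/_common.R")

r1 <- read.delim(file.path(OUT_DIR, "BRCA1_assoc.tsv"))
r2 <- read.delim(file.path(OUT_DIR, "BRCA2_assoc.tsv"))
m <- meta_scan(r1, r2)
write_tsv(m, file.path(OUT_DIR, "meta_assoc.tsv"))

only1 <- setdiff(r1$snp_id, r2$snp_id)
only2 <- setdiff(r2$snp_id, r1$snp_id)
top <- m[1, ]
message(sprintf("meta: %d shared SNPs (%d only in BRCA1, %d only in BRCA2 excluded)",
                nrow(m), length(only1), length(only2)))
message(sprintf("meta: top SNP %s, HR %.2f (95%%CI %.2f-%.2f), p = %.2g",
                top$snp_id, top$hr_meta, top$ci_low, top$ci_high,
                top$p_meta))
message(sprintf("meta: heterogeneity p > 0.5 for %.0f%% of SNPs (min p_het = %.3f)",
                100 * mean(m$p_het > 0.5), min(m$p_het)))
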