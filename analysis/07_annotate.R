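#!/usr/bin/env Rscript
# Overlap credible-set variants with regulatory-feature intervals
# (synthetic FAIRE/ChIP-seq-style BED track bundled with the package).
source("analysis/_common.R")

track <- read_bed(system.file("extdata",
                              "regulatory_features_synthetic.bed",
                              package = "carriermap"))
message(sprintf("track: %d intervals over %s", nrow(track),
                paste(unique(track$chrom), collapse = ",")))

for (setname in c(GROUPS, "meta")) {
  f <- file.path(OUT_DIR, paste0(setname, "_credible_set.tsv"))
  cs <- read.delim(f)
  rec <- data.frame(snp_id = cs$snp_id, chrom = "9", pos = cs$pos,
                    stringsAsFactors = FALSE)
  ann <- cbind(intersect_snps(rec, track),
               cs[, c("lr_vs_top", "r2_vs_top", "p")])
  write_tsv(ann, file.path(OUT_DIR,
                           paste0(setname, "_credset_annotated.tsv")))
  message(sprintf("%s: %d/%d credible-set SNPs overlap a regulatory feature",
                  setname, sum(ann$overlap), nrow(ann)))
}
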