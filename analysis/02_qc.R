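#!/usr/bin/env Rscript
# SNP quality control: exclude variants with imputation info < 0.3 or
# minor allele frequency < 0.005 (boundary values retained).
source("analysis/_common.R")

cfg <- study_config()
for (gname in GROUPS) {
  g <- read_group(gname)
  qc <- qc_filter(g$records, maf_min = cfg$qc$maf_min,
                  info_min = cfg$qc$info_min)
  write_tsv(qc$retained, file.path(OUT_DIR,
                                   paste0(gname, "_snps_retained.tsv")))
  write_tsv(qc$log, file.path(OUT_DIR,
                              paste0(gname, "_snps_excluded.tsv")))
  message(sprintf("%s: %d SNPs retained, %d excluded (%s)",
                  gname, nrow(qc$retained), nrow(qc$log),
                  paste(names(table(qc$log$reason)),
                        table(qc$log$reason), collapse = ", ")))
}
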