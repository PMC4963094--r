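# Shared constants for the analysis drivers. All computation lives in the
# carriermap package; these scripts are thin narrative drivers.
suppressMessages(library(carriermap))

ROOT_SEED <- 1L
SIM_DIR <- "results/sim"
OUT_DIR <- "results"
GROUPS <- c("BRCA1", "BRCA2")

dir.create(SIM_DIR, recursive = TRUE, showWarnings = FALSE)

# Study design: one 300-SNP fine-mapping window (30 LD blocks of 10), a
# single protective causal variant (per-allele HR 0.73) in the middle
# block, BRCA1-like and BRCA2-like carrier groups.
study_config <- function() demo_config(seed = ROOT_SEED,
                                       n_families = 2000L,
                                       n_snps = 300L,
                                       hr_per_allele = 0.73)

read_group <- function(gname) {
  vcf <- read_genotypes(file.path(SIM_DIR, paste0(gname, "_dosages.vcf")),
                        "vcf")
  info <- read.delim(file.path(SIM_DIR, paste0(gname, "_info.tsv")))
  vcf$records$info <- info$info[match(vcf$records$snp_id, info$snp_id)]
  vcf$records$genotyped <- info$genotyped[match(vcf$records$snp_id,
                                                info$snp_id)]
  cohort <- read_phenotypes(file.path(SIM_DIR,
                                      paste0(gname, "_phenotypes.tsv")))
  kin <- read_kinship(file.path(SIM_DIR, paste0(gname, "_kinship.tsv")),
                      cohort$id)
  list(dosages = vcf$dosages, records = vcf$records, cohort = cohort,
       kinship = kin,
       pen = if (gname == "BRCA1") brca1_penetrance() else
         brca2_penetrance())
}

write_tsv <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
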