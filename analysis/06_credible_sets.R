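#!/usr/bin/env Rscript
# Credible sets of potentially causal variants: likelihood ratio vs the
# top SNP at most 100 AND r2 with the top SNP above 0.1; per group and
# for the meta-analysis (LD from the pooled dosage matrix).
source("analysis/_common.R")

cfg <- study_config()
sets <- list()
dosages <- list()
for (gname in GROUPS) {
  g <- read_group(gname)
  dosages[[gname]] <- g$dosages
  res <- read.delim(file.path(OUT_DIR, paste0(gname, "_assoc.tsv")))
  cs <- credible_set(res, g$dosages, lr_max = cfg$thresholds$lr_max,
                     r2_min = cfg$thresholds$r2_min)
  sets[[gname]] <- cs
  write_tsv(cs$members, file.path(OUT_DIR,
                                  paste0(gname, "_credible_set.tsv")))
  causal <- grep("_causal$", cs$members$snp_id, value = TRUE)
  message(sprintf("%s: top %s; %d-SNP credible set; causal variant %s",
                  gname, cs$top_snp, nrow(cs$members),
                  if (length(causal)) "IN the set" else "NOT in the set"))
}

m <- read.delim(file.path(OUT_DIR, "meta_assoc.tsv"))
pooled <- rbind(dosages$BRCA1[, m$snp_id, drop = FALSE],
                dosages$BRCA2[, m$snp_id, drop = FALSE])
cs_meta <- credible_set(data.frame(snp_id = m$snp_id, pos = m$pos,
                                   p = m$p_meta),
                        pooled, lr_max = cfg$thresholds$lr_max,
                        r2_min = cfg$thresholds$r2_min)
sets$meta <- cs_meta
write_tsv(cs_meta$members, file.path(OUT_DIR, "meta_credible_set.tsv"))
message(sprintf("meta: top %s; %d-SNP credible set", cs_meta$top_snp,
                nrow(cs_meta$members)))

jsonlite::write_json(
  lapply(sets, function(cs) list(top_snp = cs$top_snp,
                                 members = cs$members,
                                 lr_max = cs$lr_max, r2_min = cs$r2_min)),
  file.path(OUT_DIR, "credible_sets.json"), auto_unbox = TRUE,
  digits = NA, pretty = TRUE)
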