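# Shared fixture builders for the test suite. Everything is generated in
# code under fixed seeds; no binary fixtures.

# Small LD spec: 3 blocks of 5 SNPs, causal in the middle block.
small_spec <- function(causal = 8L, rho = 0.85, n_snps = 15L) {
  set.seed(42)
  ld_block_spec(
    allele_freqs = round(runif(n_snps, 0.1, 0.5), 3),
    block_sizes = rep(n_snps %/% 3L, 3L),
    within_block_rho = rho,
    causal_index = causal
  )
}

# Simulated carrier cohort used across assoc/finemap tests.
small_cohort <- function(n_families = 800L, hr = 0.73, seed = 7L,
                         gene = "BRCA1", spec = small_spec()) {
  cfg <- cohort_config(n_families = n_families, gene_label = gene,
                       hr_per_allele = hr, seed = seed)
  pen <- if (gene == "BRCA1") brca1_penetrance() else brca2_penetrance()
  sim <- simulate_cohort(cfg, spec, pen, censoring_spec())
  sim$pen <- pen
  sim
}

# Independent stratified Cox score-test oracle (robust/residual form),
# computed through survival's score residuals at beta = 0.
cox_score_oracle <- function(dosage, time, event, stratum) {
  fit <- survival::coxph(
    survival::Surv(time, event) ~ dosage + survival::strata(stratum),
    init = 0, ties = "breslow",
    control = survival::coxph.control(iter.max = 0))
  sr <- unname(residuals(fit, type = "score"))
  sum(sr)^2 / sum(sr^2)
}

# Brute-force credible-set rule: enumerate every SNP against the stated
# conjunction, independent of the credible_set() implementation.
credible_set_bruteforce <- function(results, dosages, lr_max = 100,
                                    r2_min = 0.1) {
  ord <- order(results$p, results$pos)
  top <- results$snp_id[ord[1L]]
  chisq <- qchisq(results$p, df = 1, lower.tail = FALSE)
  chisq_top <- chisq[ord[1L]]
  keep <- character(0)
  for (i in seq_len(nrow(results))) {
    lr <- exp((chisq_top - min(chisq[i], chisq_top)) / 2)
    r2 <- suppressWarnings(cor(dosages[, results$snp_id[i]],
                               dosages[, top])^2)
    if (!is.na(r2) && lr <= lr_max && r2 > r2_min) {
      keep <- c(keep, results$snp_id[i])
    }
  }
  sort(keep)
}

# Brute-force interval overlap for the annotate module.
intersect_bruteforce <- function(records, track) {
  vapply(seq_len(nrow(records)), function(i) {
    p0 <- records$pos[i] - 1L
    any(track$chrom == records$chrom[i] & track$start <= p0 &
          track$end > p0)
  }, logical(1))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
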