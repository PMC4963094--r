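test_that("haplotype panel matches target frequencies and LD structure", {
  # independent SNPs: pairwise r2 indistinguishable from zero
  spec0 <- ld_block_spec(allele_freqs = rep(0.25, 6), block_sizes = rep(2, 3),
                         within_block_rho = 0)
  hap <- simulate_haplotypes(spec0, 20000L, seed = 1)
  r2 <- cor(hap)^2
  expect_lt(mean(r2[upper.tri(r2)]), 0.01)
  expect_lt(abs(mean(hap[, 1]) - 0.25), 0.01)

  # within-block r2 increases with rho, across-block r2 stays near zero
  r2_at <- function(rho) {
    sp <- ld_block_spec(allele_freqs = rep(0.3, 6), block_sizes = c(3, 3),
                        within_block_rho = rho)
    h <- simulate_haplotypes(sp, 8000L, seed = 2)
    c(within = cor(h[, 1], h[, 2])^2, across = cor(h[, 1], h[, 4])^2)
  }
  lo <- r2_at(0.3); hi <- r2_at(0.9)
  expect_gt(hi["within"], lo["within"])
  expect_lt(hi["across"], 0.01)

  # determinism contract
  spec <- small_spec()
  expect_identical(simulate_haplotypes(spec, 100L, seed = 9),
                   simulate_haplotypes(spec, 100L, seed = 9))
  expect_error(simulate_haplotypes(spec, 101L, seed = 9), "even")
  expect_error(ld_block_spec(allele_freqs = c(0.6, 0.2),
                             block_sizes = c(1, 1)), "0.5")
})

test_that("simulated cohort has the contracted survival and family structure", {
  sim <- small_cohort(n_families = 600L, hr = 1.0, seed = 3)
  co <- sim$cohort
  expect_true(all(co$time > 0))
  expect_true(all(co$event %in% c(0L, 1L)))
  expect_true(all(co$censor_reason[co$event == 1L] == "diagnosis"))
  expect_true(all(sim$dosages >= 0 & sim$dosages <= 2))

  # kinship: diagonal 0.5, sibs 0.25
  K <- sim$kinship
  expect_true(Matrix::isSymmetric(K))
  expect_equal(unname(Matrix::diag(K)), rep(0.5, nrow(co)))
  fam <- split(seq_len(nrow(co)), co$family_id)
  fam2 <- fam[vapply(fam, length, 1L) >= 2L][[1]]
  expect_equal(as.numeric(K[fam2[1], fam2[2]]), 0.25)

  # sib genotype correlation ~ 2 * phi = 0.5
  big <- small_cohort(n_families = 3000L, hr = 1.0, seed = 4)
  fams <- split(seq_len(nrow(big$cohort)), big$cohort$family_id)
  prs <- do.call(rbind, lapply(fams[vapply(fams, length, 1L) >= 2L],
                               function(v) c(v[1], v[2])))
  sib_cor <- cor(big$dosages[prs[, 1], 1], big$dosages[prs[, 2], 1])
  expect_lt(abs(sib_cor - 0.5), 0.05)

  # determinism
  sim2 <- small_cohort(n_families = 600L, hr = 1.0, seed = 3)
  expect_identical(sim$cohort, sim2$cohort)
  expect_identical(sim$dosages, sim2$dosages)
})

test_that("causal dosage shifts between cases and non-cases as the HR directs", {
  # null: no dosage difference beyond noise
  null <- small_cohort(n_families = 3000L, hr = 1.0, seed = 5)
  d <- null$dosages[, null$causal_index]
  diff_null <- mean(d[null$cohort$event == 1]) - mean(d[null$cohort$event == 0])
  expect_lt(abs(diff_null), 0.05)

  # protective minor allele: cases carry fewer copies
  prot <- small_cohort(n_families = 3000L, hr = 0.73, seed = 5)
  dp <- prot$dosages[, prot$causal_index]
  expect_lt(mean(dp[prot$cohort$event == 1]),
            mean(dp[prot$cohort$event == 0]))
})

test_that("ascertainment keeps affected families and drops unaffected ones", {
  spec <- small_spec()
  cfg <- cohort_config(n_families = 800L, hr_per_allele = 1.0,
                       keep_unaffected_prob = 0, seed = 11)
  sim <- simulate_cohort(cfg, spec, brca1_penetrance(), censoring_spec())
  aff <- tapply(sim$cohort$event, sim$cohort$family_id, max)
  expect_true(all(aff == 1L))
  cfg_all <- cohort_config(n_families = 800L, hr_per_allele = 1.0,
                           keep_unaffected_prob = 1, seed = 11)
  sim_all <- simulate_cohort(cfg_all, spec, brca1_penetrance(),
                             censoring_spec())
  expect_gt(nrow(sim_all$cohort), nrow(sim$cohort))
})

test_that("null-cohort cumulative incidence reproduces the penetrance curve", {
  # Kaplan-Meier on a large unascertained null cohort vs the input curve;
  # RRSO and end-of-observation censoring are independent of onset, so KM
  # is consistent for the net incidence.
  pen <- brca1_penetrance()
  spec <- ld_block_spec(allele_freqs = rep(0.3, 4), block_sizes = c(2, 2),
                        within_block_rho = 0.5)
  cfg <- cohort_config(n_families = 12500L, hr_per_allele = 1.0, seed = 21)
  sim <- simulate_cohort(cfg, spec, pen, censoring_spec())
  expect_gt(nrow(sim$cohort), 19000)
  km <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = sim$cohort)
  ages <- c(30, 40, 50, 60, 65)
  km_inc <- 1 - summary(km, times = ages)$surv
  expected <- cumulative_risk(pen, ages)
  expect_lt(max(abs(km_inc - expected)), 0.015)
})

test_that("imputation noise lowers realized info monotonically and safely", {
  set.seed(31)
  g <- matrix(rbinom(4000 * 3, 2, 0.3), ncol = 3)
  colnames(g) <- c("a", "b", "c")

  # target 1: unchanged dosages, info 1
  out1 <- add_imputation_noise(g, 1, seed = 1)
  expect_identical(out1$dosages, g)
  expect_equal(unname(out1$info), rep(1, 3))

  # realized info tracks the target and orders with noise level
  hi <- add_imputation_noise(g, 0.9, seed = 2)
  lo <- add_imputation_noise(g, 0.4, seed = 2)
  expect_true(all(abs(hi$info - 0.9) < 0.02))
  expect_true(all(abs(lo$info - 0.4) < 0.02))
  expect_true(all(hi$info > lo$info))
  expect_true(all(lo$dosages >= 0 & lo$dosages <= 2))
  # noisier channel compresses dosage variance toward the HWE mean
  expect_true(all(apply(lo$dosages, 2, var) < apply(hi$dosages, 2, var)))

  # monomorphic SNP: flagged, not a crash
  gm <- cbind(g, mono = rep(0, nrow(g)))
  outm <- add_imputation_noise(gm, 0.9, seed = 3)
  expect_true(outm$flagged[4])
  expect_true(is.na(outm$info[4]))
  expect_error(add_imputation_noise(g, 0, seed = 1), "target_info")
})

test_that("penetrance curve validation and cumulative risk behave", {
  expect_error(penetrance_curve(c(20, 20), 0.1), "increasing")
  expect_error(penetrance_curve(c(20, 80), -0.1), ">= 0")
  expect_error(penetrance_curve(c(20, 80), Inf), "finite")
  pen <- brca1_penetrance()
  risk80 <- cumulative_risk(pen, 80)
  expect_gt(risk80, 0.35); expect_lt(risk80, 0.60)
  risk80_b2 <- cumulative_risk(brca2_penetrance(), 80)
  expect_gt(risk80_b2, 0.12); expect_lt(risk80_b2, 0.25)
  expect_equal(cumulative_risk(pen, 18), 0)
})
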