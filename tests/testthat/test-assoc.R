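test_that("incidence-constrained baseline solves the hand case and limits", {
  # single band, mu = 0.01/yr, maf 0.5, beta = ln 2:
  # HWE weights (0.25, 0.5, 0.25), multipliers (1, 2, 4) -> lam0 = 0.01/2.25
  pen1 <- penetrance_curve(c(0, 1), 0.01)
  ch <- constrain_baseline(pen1, log(2), 0.5)
  expect_equal(ch$lam0, 0.01 / 2.25, tolerance = 1e-12)

  # beta = 0: constraint degenerates to lam0 = mu in every band
  pen <- brca1_penetrance()
  ch0 <- constrain_baseline(pen, 0, 0.3)
  expect_equal(ch0$lam0, pen$hazard, tolerance = 1e-12)

  # maf -> 0: almost everyone is genotype 0, lam0 -> mu
  chs <- constrain_baseline(pen, log(0.5), 1e-6)
  expect_equal(chs$lam0, pen$hazard, tolerance = 1e-4)

  # marginal genotype-averaged hazard equals mu in every band
  chb <- constrain_baseline(pen, log(0.6), 0.25)
  nb <- length(chb$lam0)
  eb <- exp(chb$beta * (0:2))
  for (b in seq_len(nb)) {
    w <- chb$p_g * chb$S[b, ]; w <- w / sum(w)
    expect_equal(chb$lam0[b] * sum(w * eb), pen$hazard[b],
                 tolerance = 1e-12)
  }
  expect_error(constrain_baseline(pen, Inf, 0.3), "finite")
  expect_error(constrain_baseline(pen, 0, 0.7), "maf")
})

test_that("retrospective likelihood matches the frozen hand oracle", {
  # 3-person toy cohort, single band mu = 0.01 from age 18, maf 0.25,
  # beta = ln 0.73: value computed independently from the formula
  pen <- penetrance_curve(c(18, 80), 0.01)
  time <- c(50, 60, 60); event <- c(1, 0, 0); g <- c(1, 0, 2)
  ll <- retrospective_loglik(log(0.73), time, event, g, pen, maf = 0.25)
  expect_equal(ll, -4.3497142682, tolerance = 1e-9)

  # at beta = 0 the phenotype cancels: ll = sum log p_g
  p_g <- c(0.75^2, 2 * 0.25 * 0.75, 0.25^2)
  expect_equal(retrospective_loglik(0, time, event, g, pen, maf = 0.25),
               sum(log(p_g[g + 1])), tolerance = 1e-12)

  # concave in beta on a grid
  grid <- seq(log(0.2), log(5), length.out = 41)
  llg <- vapply(grid, retrospective_loglik, numeric(1),
                time = time, event = event, dosage = g, pen = pen,
                maf = 0.25)
  expect_true(all(diff(llg, differences = 2) < 1e-8))

  expect_error(retrospective_loglik(0, time, event, c(1, 1, 1), pen),
               "monomorphic")
})

test_that("HR estimation is calibrated under the null and recovers the signal", {
  pen <- brca1_penetrance()
  spec <- ld_block_spec(allele_freqs = rep(0.25, 3), block_sizes = 3L,
                        within_block_rho = 0.5, causal_index = 2L)
  # null coverage: |beta| < 2 SE in about 95% of replicates
  cover <- vapply(1:60, function(i) {
    cfg <- cohort_config(n_families = 500L, hr_per_allele = 1.0,
                         seed = 4000L + i)
    sim <- simulate_cohort(cfg, spec, pen, censoring_spec())
    est <- estimate_hr(sim$cohort$time, sim$cohort$event,
                       sim$dosages[, 2], pen)
    abs(est$beta) < 2 * est$se
  }, logical(1))
  expect_gte(mean(cover), 0.85)   # binomial noise at 60 replicates

  # signal: estimates centre near the simulated HR
  hrs <- vapply(1:25, function(i) {
    cfg <- cohort_config(n_families = 1200L, hr_per_allele = 0.73,
                         seed = 5000L + i)
    sim <- simulate_cohort(cfg, spec, pen, censoring_spec())
    estimate_hr(sim$cohort$time, sim$cohort$event, sim$dosages[, 2],
                pen)$hr
  }, numeric(1))
  expect_lt(abs(mean(hrs) - 0.73), 0.04)

  expect_error(estimate_hr(c(40, 50), c(1, 0), c(1, 1), pen),
               "monomorphic")
})

test_that("kinship score test reduces to the stratified Cox score when unrelated", {
  set.seed(61)
  for (i in 1:5) {
    n <- 300L + 40L * i
    d <- runif(n, 0, 2)
    tt <- runif(n, 25, 79)
    ev <- rbinom(n, 1, 0.25)
    st <- sample(letters[1:5], n, TRUE)
    got <- kinship_score_test(d, tt, ev, st)   # NULL kinship = unrelated
    expect_equal(got$score_stat, cox_score_oracle(d, tt, ev, st),
                 tolerance = 1e-10)
    # explicit identity kinship agrees with the NULL shortcut
    K <- Matrix::Diagonal(n, 0.5)
    got2 <- kinship_score_test(d, tt, ev, st, K)
    expect_equal(got2$score_stat, got$score_stat, tolerance = 1e-10)
  }
})

test_that("score test handles tied event times against the Breslow oracle", {
  set.seed(62)
  n <- 400L
  d <- rbinom(n, 2, 0.3)
  tt <- sample(35:70, n, TRUE)             # heavy ties
  ev <- rbinom(n, 1, 0.35)
  st <- sample(c("u", "v", "w"), n, TRUE)
  got <- kinship_score_test(d, tt, ev, st)
  expect_equal(got$score_stat, cox_score_oracle(d, tt, ev, st),
               tolerance = 1e-10)
})

test_that("score statistic is invariant to allele swapping and flags degeneracy", {
  sim <- small_cohort(n_families = 400L, seed = 19)
  d <- sim$dosages[, 8]
  a <- kinship_score_test(d, sim$cohort$time, sim$cohort$event,
                          sim$cohort$stratum, sim$kinship)
  b <- kinship_score_test(2 - d, sim$cohort$time, sim$cohort$event,
                          sim$cohort$stratum, sim$kinship)
  expect_equal(a$score_stat, b$score_stat, tolerance = 1e-10)
  expect_equal(a$U, -b$U, tolerance = 1e-10)

  # constant dosage within every stratum: NA with a warning
  expect_warning(
    res <- kinship_score_test(rep(1, nrow(sim$cohort)), sim$cohort$time,
                              sim$cohort$event, sim$cohort$stratum,
                              sim$kinship),
    "no within-stratum information")
  expect_true(is.na(res$score_stat))
})

test_that("kinship adjustment widens the variance when sib residuals correlate", {
  # Without shared family frailty, sib score residuals are uncorrelated
  # under the null (phenotypes independent given genotype), so the
  # adjustment only bites where genotype drives the score: at a causal
  # SNP with a strong effect the genotype-shared drift makes sib
  # residuals positively correlated and the kinship variance exceeds the
  # naive one on average.
  spec <- ld_block_spec(allele_freqs = rep(0.3, 3), block_sizes = 3L,
                        within_block_rho = 0.5, causal_index = 2L)
  rat <- vapply(1:8, function(i) {
    cfg <- cohort_config(n_families = 1200L, hr_per_allele = 0.5,
                         sibs_extra_lambda = 1.2, seed = 400L + i)
    sim <- simulate_cohort(cfg, spec, brca1_penetrance(), censoring_spec())
    co <- sim$cohort
    d <- sim$dosages[, 2]
    adj <- kinship_score_test(d, co$time, co$event, co$stratum,
                              sim$kinship)
    naive <- kinship_score_test(d, co$time, co$event, co$stratum)
    expect_equal(adj$U, naive$U)     # the score itself is untouched
    adj$var_U / naive$var_U
  }, numeric(1))
  expect_gt(mean(rat), 1)
})

test_that("score and Wald chi-squares agree in expectation", {
  # the robust score variance and the retrospective observed information
  # are different finite-sample estimators, so per-replicate ratios are
  # noisy (and heavy-tailed when the statistics sit near zero);
  # first-order equivalence shows up in the replicate mean at a moderate
  # effect where both chi-squares are bounded away from zero
  spec <- ld_block_spec(allele_freqs = rep(0.3, 3), block_sizes = 3L,
                        within_block_rho = 0.5, causal_index = 2L)
  sim_ratio <- function(i) {
    cfg <- cohort_config(n_families = 2000L, hr_per_allele = 0.8,
                         seed = 8000L + i)
    sim <- simulate_cohort(cfg, spec, brca1_penetrance(), censoring_spec())
    d <- sim$dosages[, spec$causal_index]
    est <- estimate_hr(sim$cohort$time, sim$cohort$event, d,
                       brca1_penetrance())
    st <- kinship_score_test(d, sim$cohort$time, sim$cohort$event,
                             sim$cohort$stratum)
    st$score_stat / (est$beta / est$se)^2
  }
  ratios <- vapply(1:16, sim_ratio, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.15)
})

test_that("association scan ranks the causal SNP and survives per-SNP failures", {
  sim <- small_cohort(n_families = 2500L, hr = 0.73, seed = 37)
  res <- scan_assoc(sim$cohort, sim$dosages, sim$records, sim$pen,
                    sim$kinship)
  expect_equal(nrow(res), ncol(sim$dosages))
  expect_false(is.unsorted(res$p))
  causal_id <- sim$records$snp_id[sim$causal_index]
  # causal SNP (or a block-mate in high LD) leads the ranking
  block <- sim$records$snp_id[6:10]
  expect_true(res$snp_id[1] %in% block)
  expect_lt(which(res$snp_id == causal_id), 6)

  # a monomorphic column is logged, not fatal
  dos2 <- cbind(sim$dosages, bad = rep(0, nrow(sim$dosages)))
  rec2 <- rbind(sim$records,
                data.frame(snp_id = "bad", chrom = "9",
                           pos = max(sim$records$pos) + 1000L, ref = "A",
                           eff = "G", genotyped = TRUE, maf = 0,
                           info = 1))
  res2 <- scan_assoc(sim$cohort, dos2, rec2, sim$pen, sim$kinship)
  expect_equal(nrow(res2), ncol(sim$dosages))
  expect_match(attr(res2, "failures"), "bad")

  # empty SNP list gives an empty result
  res0 <- scan_assoc(sim$cohort,
                     sim$dosages[, integer(0), drop = FALSE],
                     sim$records[integer(0), , drop = FALSE], sim$pen)
  expect_equal(nrow(res0), 0L)
})
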