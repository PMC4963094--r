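#' LD-block specification for haplotype simulation
#'
#' Describes a set of SNPs organised into blocks of correlated variants.
#' Haplotypes are generated from a Gaussian copula: each block has an
#' exchangeable latent correlation `within_block_rho`, alleles are obtained
#' by thresholding the latent normal at the quantile of the minor-allele
#' frequency. This gives direct control over within-block r2 (increasing in
#' `within_block_rho`) and zero LD across blocks.
#'
#' @param allele_freqs Per-SNP minor-allele frequency in (0, 0.5].
#' @param block_sizes Integer sizes of consecutive LD blocks; must sum to
#'   the number of SNPs.
#' @param within_block_rho Latent correlation within a block, in \[0, 1).
#' @param positions Strictly increasing 1-based coordinates (build-37
#'   style); default lays SNPs out every 2 kb from 16,408,000 on chr 9.
#' @param chrom Chromosome label, default `"9"`.
#' @param causal_index Index of the causal SNP, or `NA` for none.
#' @return Object of class `ld_block_spec`.
#' @export
ld_block_spec <- function(allele_freqs, block_sizes,
                          within_block_rho = 0.9,
                          positions = NULL, chrom = "9",
                          causal_index = NA_integer_) {
  n <- length(allele_freqs)
  if (any(allele_freqs <= 0) || any(allele_freqs > 0.5)) {
    stop("allele frequencies must lie in (0, 0.5]")
  }
  if (sum(block_sizes) != n || any(block_sizes < 1)) {
    stop("block_sizes must be positive and partition the SNPs")
  }
  if (within_block_rho < 0 || within_block_rho >= 1) {
    stop("within_block_rho must lie in [0, 1)")
  }
  if (is.null(positions)) {
    positions <- 16408000L + 2000L * (seq_len(n) - 1L)
  }
  if (length(positions) != n || any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing, one per SNP")
  }
  if (!is.na(causal_index) && (causal_index < 1 || causal_index > n)) {
    stop("causal_index out of range")
  }
  structure(
    list(n_snps = n,
         allele_freqs = as.numeric(allele_freqs),
         block = rep.int(seq_along(block_sizes), block_sizes),
         within_block_rho = within_block_rho,
         positions = as.integer(positions),
         chrom = chrom,
         causal_index = as.integer(causal_index)),
    class = "ld_block_spec"
  )
}

#' Simulate a haplotype panel from an LD-block specification
#'
#' @param spec An [ld_block_spec()].
#' @param n_haplotypes Even number of haplotypes (>= 2).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return 0/1 matrix of `n_haplotypes` rows by `spec$n_snps` columns; 1 is
#'   the minor allele.
#' @export
simulate_haplotypes <- function(spec, n_haplotypes, seed) {
  stopifnot(inherits(spec, "ld_block_spec"))
  if (n_haplotypes < 2 || n_haplotypes %% 2 != 0) {
    stop("n_haplotypes must be even and >= 2")
  }
  set.seed(as.integer(seed))
  rho <- spec$within_block_rho
  z <- matrix(stats::rnorm(n_haplotypes * spec$n_snps),
              nrow = n_haplotypes)
  if (rho > 0) {
    for (b in unique(spec$block)) {
      cols <- which(spec$block == b)
      shared <- stats::rnorm(n_haplotypes)
      z[, cols] <- sqrt(rho) * shared + sqrt(1 - rho) * z[, cols]
    }
  }
  thr <- stats::qnorm(spec$allele_freqs)
  hap <- matrix(0L, n_haplotypes, spec$n_snps)
  hap[sweep(z, 2L, thr, "<")] <- 1L
  hap
}

#' Censoring specification for carrier follow-up
#'
#' Follow-up runs from `entry_age_min` until the first of disease onset,
#' risk-reducing surgery (constant-rate process from entry) or last
#' observation. Last observation age is `reference_year - birth_year`
#' capped at `followup_max_age`.
#'
#' @param rrso_rate Per-year rate of risk-reducing surgery (0 disables).
#' @param followup_max_age Maximum follow-up age in years.
#' @param entry_age_min Entry age in years, >= 18.
#' @param reference_year Calendar year of last observation.
#' @return Object of class `censoring_spec`.
#' @export
censoring_spec <- function(rrso_rate = 0.01, followup_max_age = 80,
                           entry_age_min = 18, reference_year = 2010) {
  if (rrso_rate < 0) stop("rrso_rate must be >= 0")
  if (entry_age_min < 18) stop("entry_age_min must be >= 18")
  if (followup_max_age <= entry_age_min) {
    stop("followup_max_age must exceed entry_age_min")
  }
  structure(list(rrso_rate = rrso_rate,
                 followup_max_age = followup_max_age,
                 entry_age_min = entry_age_min,
                 reference_year = reference_year),
            class = "censoring_spec")
}

#' Cohort configuration for the carrier-cohort simulator
#'
#' @param n_families Number of families sampled before ascertainment.
#' @param gene_label `"BRCA1"` or `"BRCA2"` (labels the mutation group).
#' @param hr_per_allele Per-allele hazard ratio at the causal SNP (> 0);
#'   ignored when the LD spec has no causal SNP.
#' @param sibs_extra_lambda Mean of the Poisson number of additional
#'   (beyond one) genotyped sisters per family.
#' @param countries Character vector of country labels.
#' @param country_weights Sampling weights, recycled to `countries`.
#' @param birth_year_range Two-element integer range of birth years.
#' @param birth_bin_years Width of birth-year strata bins (decades by
#'   default).
#' @param ashkenazi_prob Probability of the Ashkenazi sub-stratum flag for
#'   USA/Canada families.
#' @param keep_unaffected_prob Probability of retaining a family with no
#'   affected member (families with >= 1 affected are always kept); 1
#'   disables ascertainment.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_families, gene_label = "BRCA1",
                          hr_per_allele = 1.0,
                          sibs_extra_lambda = 0.6,
                          countries = c("UK", "USA", "France", "Germany",
                                        "Canada", "Netherlands"),
                          country_weights = c(3, 3, 2, 2, 1, 1),
                          birth_year_range = c(1930L, 1985L),
                          birth_bin_years = 10L,
                          ashkenazi_prob = 0.15,
                          keep_unaffected_prob = 1.0,
                          seed = 1L) {
  if (hr_per_allele <= 0) stop("hr_per_allele must be > 0")
  if (n_families < 1) stop("n_families must be >= 1")
  if (keep_unaffected_prob < 0 || keep_unaffected_prob > 1) {
    stop("keep_unaffected_prob must lie in [0, 1]")
  }
  structure(
    list(n_families = as.integer(n_families), gene_label = gene_label,
         hr_per_allele = hr_per_allele,
         sibs_extra_lambda = sibs_extra_lambda,
         countries = countries,
         country_weights = rep_len(country_weights, length(countries)),
         birth_year_range = as.integer(birth_year_range),
         birth_bin_years = as.integer(birth_bin_years),
         ashkenazi_prob = ashkenazi_prob,
         keep_unaffected_prob = keep_unaffected_prob,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Sample onset ages from a piecewise-constant hazard lam0 * mult by
# inverting the cumulative hazard; Inf when the total hazard is exhausted.
sample_onset_age <- function(lam0, edges, mult) {
  n <- length(mult)
  widths <- diff(edges)
  u <- stats::runif(n)
  target <- -log(u)
  onset <- rep(Inf, n)
  # cumulative hazard per band for each multiplier value; mult takes few
  # distinct values (genotypes), loop over them
  for (m in unique(mult)) {
    idx <- which(mult == m)
    inc <- lam0 * m * widths
    cumH <- c(0, cumsum(inc))
    tg <- target[idx]
    band <- findInterval(tg, cumH)      # last band fully exhausted
    hit <- band <= length(lam0)
    b <- band[hit]
    onset[idx[hit]] <- edges[b] + (tg[hit] - cumH[b]) / (lam0[b] * m)
  }
  onset
}

#' Simulate a carrier cohort with family structure and a causal SNP
#'
#' Families carry a high-risk mutation; genotyped members are full sisters
#' sharing parental haplotypes drawn from [simulate_haplotypes()]. Disease
#' onset follows the carrier penetrance curve, modified multiplicatively by
#' `exp(log(hr_per_allele) * g)` at the causal SNP; the baseline hazard is
#' incidence-constrained (see [constrain_baseline()]) so the
#' genotype-averaged incidence equals the input curve in every band.
#' Follow-up is censored at risk-reducing surgery or last observation.
#' Families with at least one affected member are always retained;
#' unaffected families are retained with `keep_unaffected_prob`.
#'
#' @param config A [cohort_config()].
#' @param spec An [ld_block_spec()].
#' @param pen A [penetrance_curve()].
#' @param cens A [censoring_spec()].
#' @return List with elements `cohort` (data frame: id, family_id, gene,
#'   time, event, censor_reason, country, birth_year, ashkenazi, stratum),
#'   `dosages` (individuals x SNPs matrix of minor-allele counts),
#'   `records` (per-SNP data frame: snp_id, chrom, pos, ref, eff,
#'   genotyped, maf, info) and `kinship` (sparse symmetric matrix, 0.5
#'   diagonal, 0.25 for full sibs).
#' @export
simulate_cohort <- function(config, spec, pen, cens) {
  stopifnot(inherits(config, "cohort_config"), inherits(spec, "ld_block_spec"),
            inherits(pen, "penetrance_curve"), inherits(cens, "censoring_spec"))
  set.seed(config$seed)
  nf <- config$n_families
  nsib <- 1L + stats::rpois(nf, config$sibs_extra_lambda)
  n <- sum(nsib)
  fam <- rep.int(seq_len(nf), nsib)

  # 4 parental haplotypes per family; sibs inherit one from each parent
  hap <- simulate_haplotypes(spec, 4L * nf,
                             seed = sample.int(.Machine$integer.max, 1L))
  mat1 <- 4L * (fam - 1L) + 1L  # maternal haplotype rows
  pick_m <- stats::rbinom(n, 1L, 0.5)
  pick_p <- stats::rbinom(n, 1L, 0.5)
  dos <- hap[mat1 + pick_m, , drop = FALSE] +
         hap[mat1 + 2L + pick_p, , drop = FALSE]
  storage.mode(dos) <- "double"

  country <- sample(config$countries, nf, replace = TRUE,
                    prob = config$country_weights)[fam]
  aj_fam <- stats::rbinom(nf, 1L, config$ashkenazi_prob)[fam]
  ashkenazi <- as.integer(country %in% c("USA", "Canada") & aj_fam == 1L)
  birth_year <- sample(seq(config$birth_year_range[1L],
                           config$birth_year_range[2L]), n, replace = TRUE)
  bin <- config$birth_bin_years
  birth_bin <- (birth_year %/% bin) * bin
  stratum <- paste0(country, ifelse(ashkenazi == 1L, "_AJ", ""),
                    "_b", birth_bin)

  # onset under the incidence-constrained baseline at the causal SNP
  if (!is.na(spec$causal_index)) {
    beta <- log(config$hr_per_allele)
    g <- round(dos[, spec$causal_index])
    maf <- spec$allele_freqs[spec$causal_index]
    ch <- constrain_baseline(pen, beta, maf)
    onset <- sample_onset_age(ch$lam0, pen$edges, exp(beta * g))
  } else {
    onset <- sample_onset_age(pen$hazard, pen$edges, rep(1, n))
  }

  rrso <- if (cens$rrso_rate > 0) {
    cens$entry_age_min + stats::rexp(n, cens$rrso_rate)
  } else rep(Inf, n)
  last_age <- pmin(cens$followup_max_age, cens$reference_year - birth_year)
  keep_fu <- last_age > cens$entry_age_min

  time <- pmin(onset, rrso, last_age)
  event <- as.integer(onset <= rrso & onset <= last_age & is.finite(onset))
  censor_reason <- ifelse(event == 1L, "diagnosis",
                          ifelse(rrso <= last_age, "rrso", "followup"))

  # clinic-style ascertainment on family affection status
  fam_affected <- tapply(event, fam, max) == 1L
  keep_fam <- fam_affected |
    stats::runif(nf) < config$keep_unaffected_prob
  keep <- keep_fam[fam] & keep_fu
  if (!any(keep)) stop("empty cohort after ascertainment")

  cohort <- data.frame(
    id = sprintf("I%05d", seq_len(n)),
    family_id = sprintf("F%05d", fam),
    gene = config$gene_label,
    time = time, event = event, censor_reason = censor_reason,
    country = country, birth_year = birth_year, ashkenazi = ashkenazi,
    stratum = stratum, stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(cohort) <- NULL
  dos <- dos[keep, , drop = FALSE]
  rownames(dos) <- cohort$id

  snp_id <- sprintf("snp%04d", seq_len(spec$n_snps))
  if (!is.na(spec$causal_index)) {
    snp_id[spec$causal_index] <- paste0(snp_id[spec$causal_index], "_causal")
  }
  colnames(dos) <- snp_id
  records <- data.frame(
    snp_id = snp_id, chrom = spec$chrom, pos = spec$positions,
    ref = "A", eff = "G", genotyped = TRUE,
    maf = apply(dos, 2L, compute_maf),
    info = 1.0, stringsAsFactors = FALSE
  )
  rownames(records) <- NULL

  list(cohort = cohort, dosages = dos, records = records,
       kinship = sib_kinship(cohort$family_id, cohort$id),
       causal_index = spec$causal_index)
}

#' Sparse kinship matrix for sibships
#'
#' Kinship coefficient 0.5 on the diagonal and 0.25 between members of the
#' same family (full sibs); zero otherwise.
#'
#' @param family_id Family label per individual.
#' @param ids Individual identifiers (dimnames of the result).
#' @return A sparse symmetric `Matrix`.
#' @export
sib_kinship <- function(family_id, ids) {
  n <- length(family_id)
  idx <- split(seq_len(n), family_id)
  pairs <- lapply(idx, function(v) {
    if (length(v) < 2L) return(NULL)
    cb <- utils::combn(v, 2L)
    cbind(cb[1L, ], cb[2L, ])
  })
  pairs <- do.call(rbind, pairs)
  i <- c(seq_len(n), if (!is.null(pairs)) pairs[, 1L])
  j <- c(seq_len(n), if (!is.null(pairs)) pairs[, 2L])
  x <- c(rep(0.5, n), if (!is.null(pairs)) rep(0.25, nrow(pairs)))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n),
                       symmetric = TRUE, dimnames = list(ids, ids))
}

#' Add imputation-style noise to a dosage matrix
#'
#' Models imputation as observing each hard genotype through an additive
#' Gaussian read-noise channel and reporting the posterior-mean dosage
#' under a Hardy-Weinberg prior at the sample allele frequency. As the
#' channel noise grows the posterior mean shrinks toward `2p`, so the
#' realized info score (observed dosage variance over the `2p(1-p)`
#' expected under HWE) decreases from 1 toward 0. Per SNP, the noise SD is
#' solved so the realized info hits `target_info`.
#'
#' @param dosages Individuals x SNPs matrix with values in \[0, 2\].
#' @param target_info Target info score in (0, 1]; scalar or per-SNP.
#' @param seed Integer seed.
#' @return List with `dosages` (noisy matrix, values in \[0, 2\]), `info`
#'   (realized per-SNP info; `NA` for monomorphic SNPs) and `flagged`
#'   (logical per SNP, `TRUE` where info is undefined).
#' @export
add_imputation_noise <- function(dosages, target_info, seed) {
  if (any(dosages < 0 | dosages > 2)) stop("dosages must lie in [0, 2]")
  if (any(target_info <= 0) || any(target_info > 1)) {
    stop("target_info must lie in (0, 1]")
  }
  set.seed(as.integer(seed))
  m <- ncol(dosages)
  target <- rep_len(target_info, m)
  out <- dosages
  info <- numeric(m)
  flagged <- logical(m)
  for (j in seq_len(m)) {
    d <- dosages[, j]
    p <- mean(d) / 2
    denom <- 2 * p * (1 - p)
    if (denom == 0 || stats::var(d) == 0) {
      info[j] <- NA_real_
      flagged[j] <- TRUE
      next
    }
    if (target[j] == 1) {
      info[j] <- 1
      next
    }
    z <- stats::rnorm(length(d))
    g <- round(d)
    pg <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    post_mean <- function(sigma) {
      y <- g + sigma * z
      num <- 0; den <- 0
      for (gg in 0:2) {
        lik <- pg[gg + 1L] * stats::dnorm(y, gg, sigma)
        num <- num + gg * lik
        den <- den + lik
      }
      num / den
    }
    realized <- function(sigma) {
      dd <- post_mean(sigma)
      pp <- mean(dd) / 2
      v <- mean(dd^2) - mean(dd)^2
      v / (2 * pp * (1 - pp))
    }
    lo <- 1e-3; hi <- 25
    if (realized(lo) <= target[j]) {
      # sample already at/below target before any appreciable noise
      out[, j] <- post_mean(lo)
      info[j] <- realized(lo)
      next
    }
    sig <- stats::uniroot(function(s) realized(s) - target[j],
                          c(lo, hi), tol = 1e-6)$root
    out[, j] <- pmin(2, pmax(0, post_mean(sig)))
    info[j] <- realized(sig)
  }
  names(info) <- colnames(dosages)
  list(dosages = out, info = info, flagged = flagged)
}
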