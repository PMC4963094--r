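#' Incidence-constrained baseline hazard for a per-allele effect
#'
#' Given a carrier penetrance curve (band hazards `mu_b`), a log per-allele
#' hazard ratio `beta` and a minor-allele frequency, constructs the
#' genotype-specific survival model in which the hazard for genotype `g`
#' is `lambda0(b) * exp(beta * g)` and the baseline `lambda0` is constrained
#' band by band so that the genotype-averaged (marginal) incidence equals
#' `mu_b` exactly. Birth genotype probabilities follow Hardy-Weinberg at
#' the minor-allele frequency. The recursion is
#' `w_g(b) = p_g S_g(b) / sum_g p_g S_g(b)`,
#' `lambda0(b) = mu_b / sum_g w_g(b) exp(beta g)`,
#' `S_g(b+1) = S_g(b) exp(-lambda0(b) exp(beta g) width_b)`.
#'
#' @param pen A [penetrance_curve()].
#' @param beta Log per-allele hazard ratio (finite).
#' @param maf Minor-allele frequency in (0, 0.5].
#' @return Object of class `constrained_hazard`: band edges, `lam0`
#'   (baseline hazard per band), `S` (survival at band edges, bands+1 rows
#'   by 3 genotype columns), `p_g` (HWE genotype probabilities), `beta`.
#' @export
constrain_baseline <- function(pen, beta, maf) {
  stopifnot(inherits(pen, "penetrance_curve"))
  if (!is.finite(beta)) stop("beta must be finite")
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  q <- maf
  p_g <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  nb <- length(pen$hazard)
  widths <- diff(pen$edges)
  eb <- exp(beta * (0:2))
  S <- matrix(1, nb + 1L, 3L)
  lam0 <- numeric(nb)
  for (b in seq_len(nb)) {
    wsum <- sum(p_g * S[b, ])
    if (wsum <= 0) stop("divergent hazard: cumulative risk reached 1")
    w <- p_g * S[b, ] / wsum
    lam0[b] <- pen$hazard[b] / sum(w * eb)
    S[b + 1L, ] <- S[b, ] * exp(-lam0[b] * eb * widths[b])
  }
  structure(list(edges = pen$edges, lam0 = lam0, S = S, p_g = p_g,
                 beta = beta, maf = maf),
            class = "constrained_hazard")
}

# Survival to exact age t and hazard at t for each genotype column;
# returns list of n x 3 matrices.
ch_surv_haz <- function(ch, t) {
  edges <- ch$edges
  nb <- length(ch$lam0)
  b <- pmin(pmax(findInterval(t, edges), 1L), nb)
  eb <- exp(ch$beta * (0:2))
  lam <- outer(ch$lam0[b], eb)                      # hazard at t, n x 3
  dt <- pmax(t - edges[b], 0)
  S <- ch$S[b, , drop = FALSE] * exp(-lam * dt)
  list(S = S, haz = lam)
}

#' Retrospective log-likelihood of observed genotypes given phenotypes
#'
#' The likelihood of each subject's genotype conditional on their observed
#' phenotype history (age at event or censoring, event indicator), which
#' corrects for outcome-dependent ascertainment of carrier cohorts:
#' `l(beta) = sum_i log( f_i(g_i) p_{g_i} / sum_g f_i(g) p_g )` with
#' `f_i(g) = S_g(t_i) * (lambda0(band(t_i)) exp(beta g))^{event_i}`.
#' Dosages are rounded to the nearest hard genotype for the likelihood
#' (the score test uses raw dosages).
#'
#' @param beta Log per-allele hazard ratio.
#' @param time Age at event or censoring (years).
#' @param event 0/1 event indicator.
#' @param dosage Effect-allele dosage in \[0, 2\].
#' @param pen A [penetrance_curve()].
#' @param maf Minor-allele frequency used for the HWE genotype prior;
#'   defaults to the sample MAF of `dosage`.
#' @return Log-likelihood value.
#' @export
retrospective_loglik <- function(beta, time, event, dosage, pen,
                                 maf = compute_maf(dosage)) {
  if (!is.finite(beta)) stop("beta must be finite")
  g <- round(dosage)
  if (stats::var(g) == 0) stop("monomorphic SNP: likelihood is flat")
  ch <- constrain_baseline(pen, beta, maf)
  sh <- ch_surv_haz(ch, time)
  f <- sh$S * sh$haz^event                # n x 3, f_i(g) per genotype
  fp <- sweep(f, 2L, ch$p_g, "*")
  own <- fp[cbind(seq_along(g), g + 1L)]
  sum(log(own / rowSums(fp)))
}

#' Per-allele hazard ratio by retrospective maximum likelihood
#'
#' Maximizes [retrospective_loglik()] over `beta` in `[log(0.1), log(10)]`
#' by 1-d numerical optimization (tolerance 1e-8); the standard error
#' comes from the numerical observed information at the maximum.
#'
#' @inheritParams retrospective_loglik
#' @param snp_id Optional SNP label carried into the result.
#' @return One-row data frame: snp_id, n, n_events, maf, beta, se, hr,
#'   ci_low, ci_high (95%).
#' @export
estimate_hr <- function(time, event, dosage, pen,
                        maf = compute_maf(dosage), snp_id = NA_character_) {
  if (stats::var(round(dosage)) == 0) {
    stop("monomorphic SNP: cannot estimate a per-allele HR")
  }
  nll <- function(b) -retrospective_loglik(b, time, event, dosage, pen, maf)
  opt <- stats::optimize(nll, interval = c(log(0.1), log(10)), tol = 1e-8)
  beta <- opt$minimum
  if (min(beta - log(0.1), log(10) - beta) < 1e-4) {
    warning("beta estimate at optimization bracket boundary")
  }
  h <- 1e-3
  obs_info <- (nll(beta + h) - 2 * nll(beta) + nll(beta - h)) / h^2
  if (!is.finite(obs_info) || obs_info <= 0) {
    stop("flat likelihood: observed information not positive")
  }
  se <- 1 / sqrt(obs_info)
  data.frame(snp_id = snp_id, n = length(time), n_events = sum(event),
             maf = maf, beta = beta, se = se, hr = exp(beta),
             ci_low = exp(beta - 1.959964 * se),
             ci_high = exp(beta + 1.959964 * se),
             stringsAsFactors = FALSE)
}

# Stratified Cox score residuals at beta = 0 (Breslow ties).
# Returns list(U = score, resid = per-individual score residuals).
cox_score_residuals <- function(dosage, time, event, stratum) {
  n <- length(dosage)
  resid <- numeric(n)
  U <- 0
  for (s in unique(stratum)) {
    idx <- which(stratum == s)
    if (sum(event[idx]) == 0L) next      # no events: contributes nothing
    ti <- time[idx]; di <- event[idx]; gi <- dosage[idx]
    ord <- order(ti, decreasing = TRUE)
    ti <- ti[ord]; di <- di[ord]; gi <- gi[ord]
    csum <- cumsum(gi)                    # risk set {time >= t}: prefix in
    nrisk <- seq_along(ti)                # descending-time order
    ev_pos <- which(di == 1L)
    ev_t <- ti[ev_pos]
    # Breslow: tied event times share the risk set at that time
    last_of_t <- !duplicated(ev_t)        # descending: first occurrence has
    # largest index into csum among ties? times equal -> same risk set:
    # use the largest position with that time
    rs_end <- vapply(ev_t, function(tt) max(which(ti == tt)), integer(1))
    m_k <- csum[rs_end] / rs_end          # risk-set mean dosage per event
    U <- U + sum(gi[ev_pos] - m_k)
    # residual term 2: sum over event times t_k <= t_i of
    # (d_k/n_k) * (g_i - m_k), with d_k/n_k folded per event (Breslow)
    w_k <- 1 / rs_end                     # one event each; ties repeat
    o <- order(ev_t)                      # ascending event times
    et <- ev_t[o]; wk <- w_k[o]; mk <- m_k[o]
    cw <- cumsum(wk)
    cwm <- cumsum(wk * mk)
    pos <- findInterval(ti, et)           # events with time <= t_i
    term2 <- ifelse(pos > 0, gi * cw[pmax(pos, 1L)] - cwm[pmax(pos, 1L)], 0)
    r <- -term2
    r[ev_pos] <- r[ev_pos] + (gi[ev_pos] - m_k)
    resid[idx[ord]] <- r
  }
  list(U = U, resid = resid)
}

#' Kinship-adjusted stratified score test for association
#'
#' Score test of a per-allele effect on the disease hazard, stratified by
#' cohort stratum, with the variance adjusted for the correlation between
#' genotypes of relatives. The score is the stratified Cox partial-
#' likelihood score at beta = 0 evaluated on raw dosages,
#' `U = sum over events (g_case - risk-set mean dosage)`; per-individual
#' score residuals `u_i` are accumulated and the variance is the kinship
#' sandwich `Var(U) = sum_ij 2 phi_ij u_i u_j`, so unrelated individuals
#' (`phi` diagonal 0.5) recover the robust score variance `sum u_i^2`.
#' `U^2 / Var(U)` is referred to a 1-df chi-square.
#'
#' @param dosage Effect-allele dosage in \[0, 2\].
#' @param time Age at event or censoring.
#' @param event 0/1 event indicator.
#' @param stratum Stratum label per individual.
#' @param kinship Sparse symmetric kinship matrix in cohort order, or
#'   `NULL` for unrelated individuals.
#' @return List: `score_stat` (1-df chi-square), `p` (two-sided), `U`,
#'   `var_U`, `n_strata_used`. For a dosage constant within every stratum
#'   the statistic is `NA` with a warning.
#' @export
kinship_score_test <- function(dosage, time, event, stratum,
                               kinship = NULL) {
  n <- length(dosage)
  stopifnot(length(time) == n, length(event) == n, length(stratum) == n)
  sr <- cox_score_residuals(dosage, time, event, stratum)
  u <- sr$resid
  var_u <- if (is.null(kinship)) {
    sum(u^2)
  } else {
    as.numeric(Matrix::crossprod(u, (2 * kinship) %*% u))
  }
  if (!is.finite(var_u) || var_u <= 0) {
    warning("dosage carries no within-stratum information; statistic NA")
    return(list(score_stat = NA_real_, p = NA_real_, U = sr$U,
                var_U = var_u,
                n_strata_used = length(unique(stratum[event == 1L]))))
  }
  stat <- sr$U^2 / var_u
  list(score_stat = stat,
       p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       U = sr$U, var_U = var_u,
       n_strata_used = length(unique(stratum[event == 1L])))
}

#' Per-SNP association scan
#'
#' Runs [estimate_hr()] (rounded genotypes, retrospective likelihood) and
#' [kinship_score_test()] (raw dosages) for every SNP, flags genome-wide
#' significance at `p < 5e-8`, and sorts by p-value (ties broken by
#' position). Per-SNP failures are logged and the scan continues.
#'
#' @param cohort Phenotype data frame with `time`, `event`, `stratum`.
#' @param dosages Individuals x SNPs matrix, columns matching `records`.
#' @param records SNP table (post-QC).
#' @param pen A [penetrance_curve()].
#' @param kinship Sparse kinship matrix or `NULL`.
#' @param sig_threshold Genome-wide significance threshold (default 5e-8).
#' @return Data frame of association results sorted by p; attribute
#'   `"failures"` logs skipped SNPs.
#' @export
scan_assoc <- function(cohort, dosages, records, pen, kinship = NULL,
                       sig_threshold = 5e-8) {
  stopifnot(nrow(records) == ncol(dosages))
  out <- vector("list", nrow(records))
  failures <- character(0)
  for (j in seq_len(nrow(records))) {
    res <- tryCatch({
      d <- dosages[, j]
      est <- estimate_hr(cohort$time, cohort$event, d, pen,
                         snp_id = records$snp_id[j])
      st <- kinship_score_test(d, cohort$time, cohort$event,
                               cohort$stratum, kinship)
      cbind(records[j, c("snp_id", "chrom", "pos", "ref", "eff",
                         "genotyped", "info")],
            est[, c("n", "n_events", "maf", "beta", "se", "hr",
                    "ci_low", "ci_high")],
            data.frame(score_stat = st$score_stat, p = st$p))
    }, error = function(e) {
      failures <<- c(failures,
                     paste0(records$snp_id[j], ": ", conditionMessage(e)))
      NULL
    })
    out[[j]] <- res
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame()
  if (nrow(res) > 0) {
    res$significant <- !is.na(res$p) & res$p < sig_threshold
    res <- res[order(res$p, res$pos), , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "failures") <- failures
  res
}
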