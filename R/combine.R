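#' Standard error of a log hazard ratio from a printed confidence interval
#'
#' `se = (log(ci_high) - log(ci_low)) / (2 * z)` with `z = 1.959964` at the
#' default 95% level. Lets published per-study HR/CI values be reused in a
#' meta-analysis.
#'
#' @param hr Hazard ratio (must lie inside the interval).
#' @param ci_low,ci_high Confidence bounds, `0 < ci_low < ci_high`.
#' @param level Confidence level, default 0.95.
#' @return Standard error of `log(hr)`.
#' @export
se_from_ci <- function(hr, ci_low, ci_high, level = 0.95) {
  if (ci_low <= 0 || ci_high <= ci_low) {
    stop("confidence interval must satisfy 0 < ci_low < ci_high")
  }
  if (hr < ci_low || hr > ci_high) {
    warning("hr lies outside the stated confidence interval")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  (log(ci_high) - log(ci_low)) / (2 * z)
}

#' Fixed-effect inverse-variance meta-analysis with Cochran Q
#'
#' Combines per-study log hazard ratios with weights `w_i = 1 / se_i^2`:
#' `beta = sum(w b) / sum(w)`, `se = sum(w)^{-1/2}`. Heterogeneity is
#' assessed by Cochran Q, `Q = sum w_i (b_i - beta)^2`, referred to a
#' chi-square with `k - 1` degrees of freedom.
#'
#' @param beta Per-study log hazard ratios (length >= 2).
#' @param se Per-study standard errors (> 0).
#' @return One-row data frame: beta_meta, se_meta, hr_meta, ci_low,
#'   ci_high, p_meta (two-sided normal), q_stat, df, p_het.
#' @export
invvar_meta <- function(beta, se) {
  k <- length(beta)
  if (k < 2L) stop("meta-analysis needs >= 2 studies")
  if (length(se) != k || any(!is.finite(se)) || any(se <= 0)) {
    stop("all standard errors must be finite and > 0")
  }
  w <- 1 / se^2
  bm <- sum(w * beta) / sum(w)
  sm <- 1 / sqrt(sum(w))
  q <- sum(w * (beta - bm)^2)
  data.frame(beta_meta = bm, se_meta = sm, hr_meta = exp(bm),
             ci_low = exp(bm - 1.959964 * sm),
             ci_high = exp(bm + 1.959964 * sm),
             p_meta = 2 * stats::pnorm(-abs(bm / sm)),
             q_stat = q, df = k - 1L,
             p_het = stats::pchisq(q, df = k - 1L, lower.tail = FALSE))
}

#' Meta-analysis across mutation groups for a pair of scan results
#'
#' Restricts to SNPs present in both groups (variants available in only
#' one dataset are excluded) and combines each by [invvar_meta()].
#'
#' @param res1,res2 Association result tables from [scan_assoc()].
#' @return Data frame keyed by snp_id with per-group estimates, the
#'   combined HR/CI/p, Cochran Q and heterogeneity p, sorted by p_meta.
#' @export
meta_scan <- function(res1, res2) {
  shared <- intersect(res1$snp_id, res2$snp_id)
  if (length(shared) == 0L) stop("no SNPs shared between the two groups")
  a <- res1[match(shared, res1$snp_id), , drop = FALSE]
  b <- res2[match(shared, res2$snp_id), , drop = FALSE]
  meta <- do.call(rbind, lapply(seq_along(shared), function(i) {
    invvar_meta(c(a$beta[i], b$beta[i]), c(a$se[i], b$se[i]))
  }))
  out <- cbind(
    data.frame(snp_id = shared, chrom = a$chrom, pos = a$pos,
               beta1 = a$beta, se1 = a$se, p1 = a$p,
               beta2 = b$beta, se2 = b$se, p2 = b$p,
               stringsAsFactors = FALSE),
    meta
  )
  out <- out[order(out$p_meta, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Conditional association scan given an index SNP
#'
#' Refits every SNP in a Cox proportional-hazards model that includes the
#' index-SNP dosage as a covariate, adjusts for year of birth (linear by
#' default) and stratifies by country: a residual independent signal is a
#' SNP whose conditional Wald p-value stays below `retain_threshold`
#' (default 1e-4). Kinship is not modelled here; the conditional Cox
#' framework yields valid tests for this purpose.
#'
#' @param cohort Phenotype data frame with `time`, `event`, `country`,
#'   `birth_year`.
#' @param dosages Individuals x SNPs matrix.
#' @param records SNP table matching `dosages` columns.
#' @param index_snp snp_id of the conditioning variant.
#' @param adjust_birth_year Include birth year as a linear covariate.
#' @param retain_threshold Retention p-value threshold for flagging
#'   residual signals.
#' @return Data frame: snp_id, pos, beta_cond, se_cond, hr_cond, ci, p_cond,
#'   r2_with_index, retained flag; collinear SNPs (r2 = 1 with the index,
#'   including the index itself) carry `NA` estimates and
#'   `note = "collinear_with_index"`.
#' @export
conditional_scan <- function(cohort, dosages, records, index_snp,
                             adjust_birth_year = TRUE,
                             retain_threshold = 1e-4) {
  ji <- match(index_snp, records$snp_id)
  if (is.na(ji)) stop("index SNP not found: ", index_snp)
  g_index <- dosages[, ji]
  base <- data.frame(time = cohort$time, event = cohort$event,
                     g_index = g_index, birth_year = cohort$birth_year,
                     country = cohort$country)
  form <- if (adjust_birth_year) {
    survival::Surv(time, event) ~ g_test + g_index + birth_year +
      survival::strata(country)
  } else {
    survival::Surv(time, event) ~ g_test + g_index +
      survival::strata(country)
  }
  out <- lapply(seq_len(nrow(records)), function(j) {
    row <- data.frame(snp_id = records$snp_id[j], pos = records$pos[j],
                      beta_cond = NA_real_, se_cond = NA_real_,
                      hr_cond = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, p_cond = NA_real_,
                      r2_with_index = NA_real_, retained = FALSE,
                      note = "", stringsAsFactors = FALSE)
    g <- dosages[, j]
    if (stats::var(g) == 0) { row$note <- "monomorphic"; return(row) }
    r2 <- stats::cor(g, g_index)^2
    row$r2_with_index <- r2
    if (j == ji || r2 > 1 - 1e-10) {
      row$note <- "collinear_with_index"
      return(row)
    }
    dat <- base
    dat$g_test <- g
    fit <- tryCatch(survival::coxph(form, data = dat),
                    error = function(e) NULL,
                    warning = function(w) {
                      suppressWarnings(survival::coxph(form, data = dat))
                    })
    if (is.null(fit) || is.na(stats::coef(fit)["g_test"])) {
      row$note <- "non_convergence"
      return(row)
    }
    b <- stats::coef(fit)["g_test"]
    s <- sqrt(stats::vcov(fit)["g_test", "g_test"])
    row$beta_cond <- b; row$se_cond <- s; row$hr_cond <- exp(b)
    row$ci_low <- exp(b - 1.959964 * s)
    row$ci_high <- exp(b + 1.959964 * s)
    row$p_cond <- 2 * stats::pnorm(-abs(b / s))
    row$retained <- row$p_cond < retain_threshold
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
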