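#' Pairwise LD (r-squared) between two dosage columns
#'
#' Squared Pearson correlation of effect-allele dosages; invariant to
#' swapping the coded allele of either SNP.
#'
#' @param a,b Numeric dosage vectors of equal length.
#' @return r2 in \[0, 1\].
#' @export
ld_r2 <- function(a, b) {
  if (length(a) != length(b)) stop("dosage vectors must have equal length")
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("zero variance: r2 undefined for a monomorphic SNP")
  }
  stats::cor(a, b)^2
}

#' Likelihood ratio of a SNP relative to the top SNP
#'
#' For 1-df score statistics the likelihood ratio of the top variant
#' relative to another is `exp((chisq_top - chisq_snp) / 2)`; a SNP is
#' excludable as causal when this exceeds the retention threshold
#' (conventionally 100). [lr_from_p()] converts two-sided p-values through
#' the 1-df chi-square inverse survival function first; the two routes
#' coincide exactly for 1-df statistics.
#'
#' @param chisq_snp,chisq_top Non-negative 1-df chi-square statistics with
#'   `chisq_top >= chisq_snp` (the top SNP is the most significant).
#' @return Likelihood ratio >= 1.
#' @export
lr_vs_top <- function(chisq_snp, chisq_top) {
  if (any(chisq_snp < 0) || any(chisq_top < 0)) {
    stop("chi-square statistics must be >= 0")
  }
  if (any(chisq_top < chisq_snp)) {
    stop("chisq_top must be >= chisq_snp (top SNP is most significant)")
  }
  exp((chisq_top - chisq_snp) / 2)
}

#' @rdname lr_vs_top
#' @param p_snp,p_top Two-sided p-values in (0, 1\] with `p_top <= p_snp`.
#' @export
lr_from_p <- function(p_snp, p_top) {
  if (any(p_snp <= 0) || any(p_snp > 1) || any(p_top <= 0) ||
      any(p_top > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  lr_vs_top(stats::qchisq(p_snp, df = 1L, lower.tail = FALSE),
            stats::qchisq(p_top, df = 1L, lower.tail = FALSE))
}

#' Credible set by the likelihood-ratio rule with an LD gate
#'
#' The top SNP is the most significant variant (smallest p, ties broken by
#' smaller position). A SNP is a member of the set of potentially causal
#' variants iff its likelihood ratio relative to the top SNP is at most
#' `lr_max` AND its r2 with the top SNP exceeds `r2_min`; all other SNPs
#' are excluded from being potentially causative. Likelihood ratios come
#' from the score-test chi-square when available, otherwise from the
#' p-value transform.
#'
#' @param results Association table with columns `snp_id`, `pos`, `p` and
#'   optionally `score_stat`.
#' @param dosages Individuals x SNPs dosage matrix used to compute r2 with
#'   the top SNP; column names must cover `results$snp_id`.
#' @param lr_max Likelihood-ratio retention threshold (default 100).
#' @param r2_min LD gate: members need r2 strictly greater (default 0.1).
#' @return Object of class `credible_set`: `top_snp`, `members` (data
#'   frame snp_id, pos, lr_vs_top, r2_vs_top, p, ordered by lr then
#'   position), `excluded` (with reasons), `lr_max`, `r2_min`.
#' @export
credible_set <- function(results, dosages, lr_max = 100, r2_min = 0.1) {
  if (nrow(results) == 0L) stop("need at least one association result")
  ord <- order(results$p, results$pos)
  results <- results[ord, , drop = FALSE]
  top <- results$snp_id[1L]
  chisq <- if ("score_stat" %in% names(results) &&
               !anyNA(results$score_stat)) {
    results$score_stat
  } else {
    stats::qchisq(results$p, df = 1L, lower.tail = FALSE)
  }
  chisq_top <- chisq[1L]
  lr <- exp((chisq_top - pmin(chisq, chisq_top)) / 2)
  g_top <- dosages[, top]
  r2 <- vapply(results$snp_id, function(s) {
    if (identical(s, top)) return(1)
    tryCatch(ld_r2(dosages[, s], g_top), error = function(e) NA_real_)
  }, numeric(1))
  member <- !is.na(r2) & lr <= lr_max & r2 > r2_min
  reason <- rep("", nrow(results))
  reason[!member & is.na(r2)] <- "ld_uncomputable"
  reason[!member & !is.na(r2) & lr > lr_max] <- "lr_above_threshold"
  reason[!member & !is.na(r2) & lr <= lr_max] <- "low_ld_with_top"
  reason[!member & !is.na(r2) & lr > lr_max & r2 <= r2_min] <-
    "lr_above_threshold+low_ld_with_top"
  members <- data.frame(snp_id = results$snp_id, pos = results$pos,
                        lr_vs_top = lr, r2_vs_top = r2, p = results$p,
                        stringsAsFactors = FALSE)[member, , drop = FALSE]
  members <- members[order(members$lr_vs_top, members$pos), , drop = FALSE]
  rownames(members) <- NULL
  excluded <- data.frame(snp_id = results$snp_id, lr_vs_top = lr,
                         r2_vs_top = r2, reason = reason,
                         stringsAsFactors = FALSE)[!member, , drop = FALSE]
  rownames(excluded) <- NULL
  structure(list(top_snp = top, members = members, excluded = excluded,
                 lr_max = lr_max, r2_min = r2_min),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat("Credible set (lr_max =", x$lr_max, ", r2_min =", x$r2_min, ")\n")
  cat("Top SNP:", x$top_snp, "\n")
  cat("Members:", nrow(x$members), "; excluded:", nrow(x$excluded), "\n")
  invisible(x)
}
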