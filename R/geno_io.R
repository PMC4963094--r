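#' Read genotype dosages from VCF or Oxford GEN
#'
#' For VCF, per-sample dosage is taken from the `DS` FORMAT field when
#' present, otherwise from `GT` hard calls (count of ALT alleles). Records
#' must be biallelic. For Oxford GEN, each SNP row carries genotype
#' probability triplets `(pAA, pAB, pBB)` per sample and the dosage is
#' `pAB + 2 * pBB`.
#'
#' @param path File path.
#' @param format `"vcf"` or `"gen"`.
#' @return List with `dosages` (individuals x SNPs matrix) and `records`
#'   (data frame: snp_id, chrom, pos, ref, eff, genotyped, maf, info).
#'   `info` is `NA` on load; populate it from a sidecar table or
#'   [add_imputation_noise()] output before QC.
#' @export
read_genotypes <- function(path, format = c("vcf", "gen")) {
  format <- match.arg(format)
  if (format == "vcf") read_vcf_dosages(path) else read_gen_dosages(path)
}

read_vcf_dosages <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  nsnp <- nrow(v@gt)
  if (is.null(nsnp) || nsnp == 0L) {
    return(list(dosages = matrix(numeric(0), 0L, 0L),
                records = empty_snp_records()))
  }
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE))) {
    stop("multiallelic VCF records are not supported")
  }
  fmt <- v@gt[, 1L]
  has_ds <- grepl("(^|:)DS(:|$)", fmt)
  has_gt <- grepl("(^|:)GT(:|$)", fmt)
  if (any(!has_ds & !has_gt)) {
    stop("VCF record with neither DS nor GT")
  }
  dos <- matrix(NA_real_, nrow = ncol(v@gt) - 1L, ncol = nsnp)
  if (any(has_ds)) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    dos[, has_ds] <- t(ds[has_ds, , drop = FALSE])
  }
  if (any(!has_ds)) {
    gt <- vcfR::extract.gt(v, element = "GT")
    alt_count <- function(x) {
      ifelse(is.na(x), NA_real_,
             vapply(strsplit(gsub("\\|", "/", x), "/"),
                    function(a) sum(a != "." & a != "0"), numeric(1)))
    }
    hard <- apply(gt[!has_ds, , drop = FALSE], c(1, 2), alt_count)
    dos[, !has_ds] <- t(hard)
  }
  rownames(dos) <- colnames(v@gt)[-1L]
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":",
                                         fix[, "POS"])[is.na(ids) | ids == "."]
  colnames(dos) <- ids
  records <- data.frame(
    snp_id = ids, chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], eff = fix[, "ALT"], genotyped = !has_ds,
    maf = apply(dos, 2L, compute_maf), info = NA_real_,
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  list(dosages = dos, records = records)
}

read_gen_dosages <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    return(list(dosages = matrix(numeric(0), 0L, 0L),
                records = empty_snp_records()))
  }
  if ((ncol(tab) - 5L) %% 3L != 0L || ncol(tab) < 8L) {
    stop("GEN file must have 5 leading columns plus probability triplets")
  }
  nind <- (ncol(tab) - 5L) %/% 3L
  probs <- as.matrix(tab[, -(1:5), drop = FALSE])
  p_het <- probs[, 3L * seq_len(nind) - 1L, drop = FALSE]
  p_hom <- probs[, 3L * seq_len(nind), drop = FALSE]
  dos <- t(p_het + 2 * p_hom)
  rownames(dos) <- sprintf("S%04d", seq_len(nind))
  colnames(dos) <- tab[[2L]]
  records <- data.frame(
    snp_id = tab[[2L]], chrom = as.character(tab[[1L]]),
    pos = as.integer(tab[[3L]]), ref = tab[[4L]], eff = tab[[5L]],
    genotyped = FALSE, maf = apply(dos, 2L, compute_maf),
    info = NA_real_, stringsAsFactors = FALSE
  )
  list(dosages = dos, records = records)
}

empty_snp_records <- function() {
  data.frame(snp_id = character(0), chrom = character(0),
             pos = integer(0), ref = character(0), eff = character(0),
             genotyped = logical(0), maf = numeric(0), info = numeric(0),
             stringsAsFactors = FALSE)
}

#' Write a dosage matrix to VCF with a DS FORMAT field
#'
#' One biallelic record per SNP, 1-based positions, dosages written to
#' three decimals.
#'
#' @param path Output path.
#' @param dosages Individuals x SNPs matrix (rownames are sample ids).
#' @param records SNP table as in [read_genotypes()].
#' @export
write_vcf_dosages <- function(path, dosages, records) {
  stopifnot(ncol(dosages) == nrow(records))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated effect allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(dosages)), collapse = "\t")
  ), con)
  for (j in seq_len(nrow(records))) {
    writeLines(paste(c(records$chrom[j], records$pos[j], records$snp_id[j],
                       records$ref[j], records$eff[j], ".", "PASS", ".",
                       "DS", sprintf("%.3f", dosages[, j])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Phenotype and kinship table I/O
#'
#' Plain TSV formats: the phenotype table has columns id, family_id, gene,
#' time, event, censor_reason, country, birth_year, ashkenazi, stratum;
#' the kinship table is long format (id1, id2, phi) listing off-diagonal
#' pairs, the diagonal being 0.5 by definition.
#'
#' @param path File path.
#' @param cohort Phenotype data frame.
#' @name pheno_io
#' @export
write_phenotypes <- function(path, cohort) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pheno_io
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (any(tab$time <= 0)) stop("phenotype times must be positive")
  if (any(tab$event == 1L & tab$censor_reason != "diagnosis")) {
    stop("event=1 requires censor_reason 'diagnosis'")
  }
  tab
}

#' @rdname pheno_io
#' @param kinship Sparse symmetric kinship matrix with dimnames.
#' @export
write_kinship <- function(path, kinship) {
  tri <- Matrix::triu(methods::as(kinship, "TsparseMatrix"), k = 1L)
  tab <- data.frame(id1 = rownames(kinship)[tri@i + 1L],
                    id2 = colnames(kinship)[tri@j + 1L],
                    phi = tri@x)
  tab <- tab[order(tab$id1, tab$id2), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pheno_io
#' @param ids Individual ids defining matrix order; pairs absent from the
#'   file are unrelated.
#' @export
read_kinship <- function(path, ids) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  n <- length(ids)
  i <- match(tab$id1, ids)
  j <- match(tab$id2, ids)
  keep <- !is.na(i) & !is.na(j)
  Matrix::sparseMatrix(i = c(seq_len(n), i[keep]),
                       j = c(seq_len(n), j[keep]),
                       x = c(rep(0.5, n), tab$phi[keep]),
                       dims = c(n, n), symmetric = TRUE,
                       dimnames = list(ids, ids))
}

#' Minor allele frequency of a dosage column
#'
#' `maf = min(m, 1 - m)` with `m = mean(dosage) / 2`; missing values are
#' ignored.
#'
#' @param dosage Numeric vector in \[0, 2\].
#' @return MAF in \[0, 0.5\].
#' @export
compute_maf <- function(dosage) {
  if (all(is.na(dosage))) stop("all-missing dosage column")
  m <- mean(dosage, na.rm = TRUE) / 2
  min(m, 1 - m)
}

#' Imputation info score of a dosage column
#'
#' Ratio of the observed dosage variance (population form) to the
#' `2p(1-p)` expected under Hardy-Weinberg equilibrium at the sample
#' frequency. `NA` for monomorphic columns.
#'
#' @param dosage Numeric vector in \[0, 2\].
#' @return Info score (typically in \[0, 1\]; sampling noise can push hard
#'   genotypes slightly above 1) or `NA`.
#' @export
compute_info <- function(dosage) {
  d <- dosage[!is.na(dosage)]
  if (length(d) == 0L) stop("all-missing dosage column")
  p <- mean(d) / 2
  denom <- 2 * p * (1 - p)
  if (denom == 0) return(NA_real_)
  (mean(d^2) - mean(d)^2) / denom
}

#' Quality-control filter on MAF and imputation info
#'
#' Retains SNPs with `maf >= maf_min` and `info >= info_min` (boundary
#' values are kept: exclusion applies to values strictly lower than the
#' thresholds). SNPs with `NA` info are excluded as unmeasurable.
#'
#' @param records SNP table with `maf` and `info` columns.
#' @param maf_min Minimum minor allele frequency (default 0.005).
#' @param info_min Minimum info score (default 0.3).
#' @return List with `retained` (subset of `records`) and `log` (data
#'   frame of exclusions with reasons).
#' @export
qc_filter <- function(records, maf_min = 0.005, info_min = 0.3) {
  low_maf <- records$maf < maf_min
  low_info <- is.na(records$info) | records$info < info_min
  reason <- character(nrow(records))
  reason[low_info] <- ifelse(is.na(records$info[low_info]),
                             "info_undefined", "low_info")
  reason[low_maf] <- ifelse(low_info[low_maf],
                            paste0(reason[low_maf], "+low_maf"), "low_maf")
  keep <- !(low_maf | low_info)
  list(retained = records[keep, , drop = FALSE],
       log = data.frame(snp_id = records$snp_id[!keep],
                        maf = records$maf[!keep],
                        info = records$info[!keep],
                        reason = reason[!keep],
                        stringsAsFactors = FALSE))
}

#' Mean-impute missing dosages per SNP
#'
#' @param dosages Individuals x SNPs matrix.
#' @return List with `dosages` (no missing values) and `n_imputed` per SNP.
#' @export
mean_impute <- function(dosages) {
  n_imp <- integer(ncol(dosages))
  for (j in seq_len(ncol(dosages))) {
    miss <- is.na(dosages[, j])
    if (any(miss)) {
      dosages[miss, j] <- mean(dosages[, j], na.rm = TRUE)
      n_imp[j] <- sum(miss)
    }
  }
  list(dosages = dosages, n_imputed = n_imp)
}
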