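#' Demo pipeline configuration
#'
#' A two-group (BRCA1-like and BRCA2-like) synthetic study over one
#' fine-mapping window: LD-blocked SNPs around a single protective causal
#' variant (per-allele HR 0.73 by default, matching the effect size the
#' pipeline is designed to map), carrier penetrance defaults per group,
#' clinic-style ascertainment and imputation noise. All stage behaviour
#' (QC thresholds, significance and retention thresholds, credible-set
#' thresholds) is configured here.
#'
#' @param seed Root seed; all stage randomness derives from it.
#' @param n_families Families per group before ascertainment.
#' @param n_snps Number of SNPs in the window.
#' @param hr_per_allele Causal per-allele hazard ratio.
#' @return A nested list understood by [run_pipeline()].
#' @export
demo_config <- function(seed = 1L, n_families = 2000L, n_snps = 300L,
                        hr_per_allele = 0.73) {
  block_sizes <- rep(10L, n_snps %/% 10L)
  if (sum(block_sizes) < n_snps) {
    block_sizes <- c(block_sizes, n_snps - sum(block_sizes))
  }
  list(
    seed = as.integer(seed),
    spec = list(n_snps = as.integer(n_snps), block_sizes = block_sizes,
                within_block_rho = 0.85, maf_range = c(0.05, 0.5),
                causal_index = as.integer(n_snps %/% 2L)),
    groups = list(
      BRCA1 = list(gene = "BRCA1", n_families = as.integer(n_families),
                   penetrance = "brca1", hr_per_allele = hr_per_allele),
      BRCA2 = list(gene = "BRCA2",
                   n_families = as.integer(round(n_families * 0.55)),
                   penetrance = "brca2", hr_per_allele = hr_per_allele)
    ),
    censoring = list(rrso_rate = 0.01, followup_max_age = 80,
                     entry_age_min = 18, reference_year = 2010),
    imputation = list(info_high = c(0.85, 1.0), frac_poor = 0.05,
                      info_poor = c(0.1, 0.3)),
    qc = list(maf_min = 0.005, info_min = 0.3),
    thresholds = list(significance = 5e-8, conditional_retain = 1e-4,
                      lr_max = 100, r2_min = 0.1),
    bed = system.file("extdata", "regulatory_features_synthetic.bed",
                      package = "carriermap")
  )
}

config_spec <- function(config) {
  set.seed(config$seed)
  n <- config$spec$n_snps
  mafs <- round(stats::runif(n, config$spec$maf_range[1L],
                             config$spec$maf_range[2L]), 4L)
  ld_block_spec(allele_freqs = mafs,
                block_sizes = config$spec$block_sizes,
                within_block_rho = config$spec$within_block_rho,
                causal_index = config$spec$causal_index)
}

config_penetrance <- function(name) {
  switch(name, brca1 = brca1_penetrance(), brca2 = brca2_penetrance(),
         stop("unknown penetrance label: ", name))
}

write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  nrow(tab)
}

#' Run the full pipeline on a configuration
#'
#' Stages: simulate each group (with imputation noise) and write
#' genotype/phenotype/kinship files; QC; per-group association scan;
#' cross-group meta-analysis (skipped with a warning when only one group
#' is configured); conditional scan on each group's top SNP; credible
#' sets (per group and for the meta-analysis); regulatory-feature
#' annotation of credible-set members. Deterministic given the config
#' seed. A manifest records versions, the config hash and per-stage row
#' counts; any stage failure aborts with a stage-tagged message.
#'
#' @param config Configuration list, see [demo_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "carriermap",
                   version = as.character(utils::packageVersion("carriermap")),
                   r_version = as.character(getRversion()),
                   seed = config$seed, outputs = list())
  add_output <- function(stage, file, rows) {
    manifest$outputs[[length(manifest$outputs) + 1L]] <<-
      list(stage = stage, file = file, rows = rows)
  }
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  spec <- config_spec(config)
  groups <- list()

  stage("simulate", {
    gi <- 0L
    for (gname in names(config$groups)) {
      gi <- gi + 1L
      gcfg <- config$groups[[gname]]
      cc <- cohort_config(n_families = gcfg$n_families,
                          gene_label = gcfg$gene,
                          hr_per_allele = gcfg$hr_per_allele,
                          keep_unaffected_prob = 1.0,
                          seed = config$seed + 1000L * gi)
      pen <- config_penetrance(gcfg$penetrance)
      cens <- do.call(censoring_spec, config$censoring)
      sim <- simulate_cohort(cc, spec, pen, cens)
      # imputation noise profile: mostly well-imputed, a few poor SNPs
      set.seed(config$seed + 1000L * gi + 1L)
      n <- spec$n_snps
      target <- stats::runif(n, config$imputation$info_high[1L],
                             config$imputation$info_high[2L])
      poor <- stats::runif(n) < config$imputation$frac_poor
      target[poor] <- stats::runif(sum(poor),
                                   config$imputation$info_poor[1L],
                                   config$imputation$info_poor[2L])
      target[spec$causal_index] <- 1   # causal SNP kept genotyped
      noisy <- add_imputation_noise(sim$dosages, target,
                                    seed = config$seed + 1000L * gi + 2L)
      sim$dosages <- noisy$dosages
      sim$records$info <- ifelse(is.na(noisy$info), 0, noisy$info)
      sim$records$genotyped <- target == 1
      sim$records$maf <- apply(sim$dosages, 2L, compute_maf)
      sim$pen <- pen
      groups[[gname]] <- sim
      pre <- file.path(out_dir, gname)
      write_vcf_dosages(paste0(pre, "_dosages.vcf"), sim$dosages,
                        sim$records)
      add_output("simulate", paste0(gname, "_dosages.vcf"),
                 nrow(sim$records))
      add_output("simulate", paste0(gname, "_phenotypes.tsv"),
                 write_tsv(sim$cohort, paste0(pre, "_phenotypes.tsv")))
      write_kinship(paste0(pre, "_kinship.tsv"), sim$kinship)
      add_output("simulate", paste0(gname, "_kinship.tsv"),
                 sum(sim$kinship@x != 0.5))
    }
  })

  stage("qc", {
    for (gname in names(groups)) {
      qc <- qc_filter(groups[[gname]]$records,
                      maf_min = config$qc$maf_min,
                      info_min = config$qc$info_min)
      groups[[gname]]$qc <- qc
      add_output("qc", paste0(gname, "_snps_retained.tsv"),
                 write_tsv(qc$retained,
                           file.path(out_dir,
                                     paste0(gname, "_snps_retained.tsv"))))
      write_tsv(qc$log, file.path(out_dir,
                                  paste0(gname, "_snps_excluded.tsv")))
    }
  })

  stage("scan", {
    for (gname in names(groups)) {
      g <- groups[[gname]]
      keep <- match(g$qc$retained$snp_id, g$records$snp_id)
      res <- scan_assoc(g$cohort, g$dosages[, keep, drop = FALSE],
                        g$qc$retained, g$pen, g$kinship,
                        sig_threshold = config$thresholds$significance)
      groups[[gname]]$assoc <- res
      add_output("scan", paste0(gname, "_assoc.tsv"),
                 write_tsv(res, file.path(out_dir,
                                          paste0(gname, "_assoc.tsv"))))
    }
  })

  stage("meta", {
    if (length(groups) >= 2L) {
      gn <- names(groups)
      meta <- meta_scan(groups[[gn[1L]]]$assoc, groups[[gn[2L]]]$assoc)
      groups$meta_result <- meta
      add_output("meta", "meta_assoc.tsv",
                 write_tsv(meta, file.path(out_dir, "meta_assoc.tsv")))
    } else {
      warning("meta stage skipped: fewer than two gene groups configured")
    }
  })

  stage("condition", {
    for (gname in setdiff(names(groups), "meta_result")) {
      g <- groups[[gname]]
      keep <- match(g$assoc$snp_id, colnames(g$dosages))
      cond <- conditional_scan(
        g$cohort, g$dosages[, keep, drop = FALSE], g$assoc,
        index_snp = g$assoc$snp_id[1L],
        retain_threshold = config$thresholds$conditional_retain)
      add_output("condition", paste0(gname, "_conditional.tsv"),
                 write_tsv(cond,
                           file.path(out_dir,
                                     paste0(gname, "_conditional.tsv"))))
    }
  })

  credsets <- list()
  stage("credset", {
    for (gname in setdiff(names(groups), "meta_result")) {
      g <- groups[[gname]]
      cs <- credible_set(g$assoc, g$dosages,
                         lr_max = config$thresholds$lr_max,
                         r2_min = config$thresholds$r2_min)
      credsets[[gname]] <- cs
      add_output("credset", paste0(gname, "_credible_set.tsv"),
                 write_tsv(cs$members,
                           file.path(out_dir,
                                     paste0(gname, "_credible_set.tsv"))))
    }
    if (!is.null(groups$meta_result)) {
      gn <- setdiff(names(groups), "meta_result")
      pooled <- do.call(rbind, lapply(gn, function(x) {
        groups[[x]]$dosages[, groups$meta_result$snp_id, drop = FALSE]
      }))
      meta_in <- data.frame(snp_id = groups$meta_result$snp_id,
                            pos = groups$meta_result$pos,
                            p = groups$meta_result$p_meta)
      cs <- credible_set(meta_in, pooled,
                         lr_max = config$thresholds$lr_max,
                         r2_min = config$thresholds$r2_min)
      credsets$meta <- cs
      add_output("credset", "meta_credible_set.tsv",
                 write_tsv(cs$members,
                           file.path(out_dir, "meta_credible_set.tsv")))
    }
    jsonlite::write_json(
      lapply(credsets, function(cs) {
        list(top_snp = cs$top_snp, lr_max = cs$lr_max, r2_min = cs$r2_min,
             members = cs$members)
      }),
      file.path(out_dir, "credible_sets.json"), auto_unbox = TRUE,
      digits = NA, pretty = TRUE)
  })

  stage("annotate", {
    if (!is.null(config$bed) && nzchar(config$bed) &&
        file.exists(config$bed)) {
      track <- read_bed(config$bed)
      for (gname in names(credsets)) {
        cs <- credsets[[gname]]
        recs <- data.frame(snp_id = cs$members$snp_id,
                           chrom = "9", pos = cs$members$pos,
                           stringsAsFactors = FALSE)
        ann <- intersect_snps(recs, track)
        ann <- cbind(ann, cs$members[, c("lr_vs_top", "r2_vs_top", "p")])
        add_output("annotate", paste0(gname, "_credset_annotated.tsv"),
                   write_tsv(ann,
                             file.path(out_dir,
                                       paste0(gname,
                                              "_credset_annotated.tsv"))))
      }
    } else {
      warning("annotate stage skipped: no BED track configured")
    }
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
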