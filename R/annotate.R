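#' Read a BED3+ regulatory-feature track
#'
#' Tab-separated, half-open 0-based intervals `[start, end)`; column 4 (if
#' present) is kept as the feature label and column 5 as the cell type.
#' Intervals are sorted by chromosome and start after load.
#'
#' @param path Path to a BED file (>= 3 columns; no header).
#' @return Object of class `feature_track`: data frame with chrom, start,
#'   end, label, cell_type.
#' @export
read_bed <- function(path) {
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character(0))
  if (length(first) == 0L) {
    return(structure(
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 label = character(0), cell_type = character(0),
                 stringsAsFactors = FALSE),
      class = c("feature_track", "data.frame")))
  }
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#",
                           fill = TRUE)
  if (ncol(tab) < 3L) stop("BED input needs at least 3 tab-separated columns")
  if (!is.numeric(tab[[2L]]) || !is.numeric(tab[[3L]])) {
    stop("BED start/end must be numeric")
  }
  if (any(tab[[2L]] >= tab[[3L]])) stop("BED intervals must have start < end")
  track <- data.frame(
    chrom = as.character(tab[[1L]]),
    start = as.integer(tab[[2L]]),
    end = as.integer(tab[[3L]]),
    label = if (ncol(tab) >= 4L) as.character(tab[[4L]]) else
      NA_character_,
    cell_type = if (ncol(tab) >= 5L) as.character(tab[[5L]]) else
      NA_character_,
    stringsAsFactors = FALSE
  )
  no_label <- is.na(track$label) | track$label == ""
  track$label[no_label] <- sprintf("feature%d", which(no_label))
  track$cell_type[!is.na(track$cell_type) & track$cell_type == ""] <-
    NA_character_
  track <- track[order(track$chrom, track$start, track$end), , drop = FALSE]
  rownames(track) <- NULL
  structure(track, class = c("feature_track", "data.frame"))
}

#' Intersect SNP positions with a feature track
#'
#' A SNP at 1-based position `P` overlaps a half-open 0-based interval
#' `[s, e)` iff `s <= P - 1 < e`. The overlap flag uses a binary search
#' over intervals sorted by start with a running maximum of interval ends;
#' feature labels are then collected for flagged SNPs only.
#'
#' @param records SNP table with `snp_id`, `chrom`, `pos` (1-based).
#' @param track A [read_bed()] feature track.
#' @return Data frame: snp_id, chrom, pos, overlap (logical), n_features,
#'   features (comma-separated labels).
#' @export
intersect_snps <- function(records, track) {
  out <- data.frame(snp_id = records$snp_id, chrom = records$chrom,
                    pos = records$pos, overlap = FALSE, n_features = 0L,
                    features = "", stringsAsFactors = FALSE)
  if (nrow(track) == 0L || nrow(records) == 0L) return(out)
  if (!any(records$chrom %in% track$chrom)) {
    warning("no shared chromosome names between SNPs and track; ",
            "zero overlaps")
    return(out)
  }
  for (chr in unique(records$chrom)) {
    tr <- track[track$chrom == chr, , drop = FALSE]
    if (nrow(tr) == 0L) next
    idx <- which(records$chrom == chr)
    p0 <- records$pos[idx] - 1L             # 0-based SNP coordinate
    cmax <- cummax(tr$end)
    k <- findInterval(p0, tr$start)          # last interval with start <= p0
    hit <- k > 0L & cmax[pmax(k, 1L)] > p0
    out$overlap[idx] <- hit
    for (ii in idx[hit]) {
      p <- records$pos[ii] - 1L
      j <- which(tr$start <= p & tr$end > p)
      out$n_features[ii] <- length(j)
      out$features[ii] <- paste(tr$label[j], collapse = ",")
    }
  }
  out
}
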