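#' Evaluate candidate loci in a second population
#'
#' For each candidate called in population A, looks up the same statistic
#' in population B at the nearest scored focal position (within `tol_bp`;
#' A and B need not segregate the same SNPs), converts it to an empirical
#' percentile of B's genome-wide track, and flags the locus as "elevated"
#' in B when the percentile reaches the `1 - alpha` quantile. A low
#' elevated fraction indicates sweeps that postdate the population split;
#' a shared (pre-split) sweep is elevated in both.
#'
#' @param candidates candidates from [call_top_loci()] on population A.
#' @param track_b the same statistic's [score_track()] scanned on
#'   population B with identical parameters.
#' @param alpha tail probability defining "elevated" (default 0.05).
#' @param tol_bp matching tolerance in bp (default 5000).
#' @return list: `comparison` data.frame (`rank`, `chrom`, `pos`,
#'   `matched_pos`, `stat_in_b`, `percentile_in_b`, `elevated`),
#'   `fraction_elevated` over matched candidates, `n_unmatched`.
#' @export
compare_candidates <- function(candidates, track_b, alpha = 0.05,
                               tol_bp = 5000L) {
  stopifnot(alpha > 0, alpha < 1)
  all_b <- track_b$score
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    ch <- candidates$chrom[i]; p <- candidates$pos[i]
    sub <- track_b[track_b$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    j <- which.min(abs(sub$pos - p))
    if (abs(sub$pos[j] - p) > tol_bp) return(NULL)
    v <- sub$score[j]
    pct <- 100 * mean(all_b <= v)
    data.frame(rank = candidates$rank[i], chrom = ch, pos = p,
               matched_pos = sub$pos[j], stat_in_b = v,
               percentile_in_b = pct,
               elevated = pct >= 100 * (1 - alpha),
               stringsAsFactors = FALSE)
  })
  unmatched <- sum(vapply(rows, is.null, logical(1)))
  comparison <- do.call(rbind, rows)
  if (is.null(comparison)) {
    stop("no candidate matched a scored focal position in population B")
  }
  rownames(comparison) <- NULL
  list(comparison = comparison,
       fraction_elevated = mean(comparison$elevated),
       n_unmatched = unmatched)
}

#' Export the multisite-genotype panel around a focal position
#'
#' The window's multisite genotypes as a sample-by-SNP table, optionally
#' row-ordered by identical-genotype class (largest class first) so sweep
#' haplotype structure is visible in a heatmap.
#'
#' @param gm a [genotype_matrix()].
#' @param chrom,focal_position locus of interest; the nearest SNP at or
#'   matching this position is the focal SNP.
#' @param window_snps odd window size in SNPs.
#' @param cluster order rows by genotype class size (default `TRUE`).
#' @param path optional TSV output file.
#' @return integer matrix (rownames = samples, colnames = positions),
#'   invisibly when `path` is given.
#' @export
genotype_panel_export <- function(gm, chrom, focal_position,
                                  window_snps = 201L, cluster = TRUE,
                                  path = NULL) {
  idx <- which(gm$sites$chrom == chrom)
  if (length(idx) == 0L) stop("no SNPs on chromosome ", chrom)
  focal <- idx[which.min(abs(gm$sites$pos[idx] - focal_position))]
  w <- window_genotypes(gm, focal, window_snps)
  if (is.null(w)) stop("focal position too close to a chromosome end")
  rownames(w) <- gm$samples
  half <- (window_snps - 1L) / 2L
  colnames(w) <- gm$sites$pos[(focal - half):(focal + half)]
  if (cluster) {
    has_na <- apply(w, 1L, anyNA)
    key <- ifelse(has_na, paste0("NA_", seq_len(nrow(w))),
                  apply(w, 1L, paste, collapse = ","))
    sizes <- table(key)
    ord <- order(-as.integer(sizes[key]), key, gm$samples)
    w <- w[ord, , drop = FALSE]
  }
  if (!is.null(path)) {
    df <- data.frame(sample = rownames(w), w, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(w))
  }
  w
}
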