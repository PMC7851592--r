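#' Call top-scoring candidate loci with iterative masking
#'
#' Greedy outlier calling: repeatedly take the global maximum among unmasked
#' scored positions, emit it as a candidate, and mask all positions within
#' `mask_radius_bp` of it on its chromosome, until `k` loci are called or
#' the genome is exhausted. Masking suppresses the correlated signal that
#' linkage disequilibrium spreads around a single sweep. Ties in score are
#' broken by chromosome name then position, so the result does not depend
#' on input order.
#'
#' @param track a [score_track()] (genome-wide).
#' @param k number of candidates (default 100).
#' @param mask_radius_bp masking radius around each called locus
#'   (default 100000).
#' @return data.frame of candidates: `rank`, `chrom`, `pos`, `score`,
#'   `mask_start`, `mask_end`, `statistic`.
#' @export
call_top_loci <- function(track, k = 100L, mask_radius_bp = 100000L) {
  stopifnot(nrow(track) >= 1, mask_radius_bp > 0, k >= 1)
  statistic <- attr(track, "statistic")
  if (is.null(statistic)) statistic <- "score"
  ord <- order(-track$score, track$chrom, track$pos)
  chrom <- track$chrom[ord]; pos <- track$pos[ord]; score <- track$score[ord]

  sel_chrom <- character(0); sel_pos <- integer(0); sel_score <- numeric(0)
  for (i in seq_along(ord)) {
    same <- sel_chrom == chrom[i]
    if (any(same) && min(abs(sel_pos[same] - pos[i])) <= mask_radius_bp) next
    sel_chrom <- c(sel_chrom, chrom[i])
    sel_pos <- c(sel_pos, pos[i])
    sel_score <- c(sel_score, score[i])
    if (length(sel_pos) == k) break
  }
  if (length(sel_pos) < k) {
    warning(sprintf("genome exhausted after %d of %d candidates",
                    length(sel_pos), k))
  }
  data.frame(
    rank = seq_along(sel_pos), chrom = sel_chrom, pos = sel_pos,
    score = sel_score,
    mask_start = pmax(1L, sel_pos - as.integer(mask_radius_bp)),
    mask_end = sel_pos + as.integer(mask_radius_bp),
    statistic = statistic, stringsAsFactors = FALSE
  )
}

#' Percentile of one statistic at another statistic's candidates
#'
#' For each candidate, looks up the other track's value at the nearest
#' scored position (within `tol_bp`), expresses it as an empirical
#' genome-wide percentile of the other track, and returns the median
#' percentile across candidates. Candidates with no scored position within
#' tolerance are skipped and counted.
#'
#' @param candidates output of [call_top_loci()].
#' @param other_track a [score_track()] of the other statistic.
#' @param tol_bp matching tolerance in bp (default 5000).
#' @return list with `median_percentile`, per-candidate data.frame `detail`
#'   (`chrom`, `pos`, `matched_pos`, `value`, `percentile`), and `n_skipped`.
#' @export
cross_percentile <- function(candidates, other_track, tol_bp = 5000L) {
  all_scores <- other_track$score
  res <- lapply(seq_len(nrow(candidates)), function(i) {
    ch <- candidates$chrom[i]; p <- candidates$pos[i]
    sub <- other_track[other_track$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    j <- which.min(abs(sub$pos - p))
    if (abs(sub$pos[j] - p) > tol_bp) return(NULL)
    v <- sub$score[j]
    data.frame(chrom = ch, pos = p, matched_pos = sub$pos[j], value = v,
               percentile = 100 * mean(all_scores <= v),
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(res, is.null, logical(1)))
  detail <- do.call(rbind, res)
  if (is.null(detail)) stop("no candidate matched a scored position in the other track")
  list(median_percentile = stats::median(detail$percentile),
       detail = detail, n_skipped = skipped)
}

#' Spearman rank correlation between two score tracks
#'
#' Computed over positions scored in both tracks (exact chromosome/position
#' match).
#'
#' @param track_a,track_b [score_track()] objects.
#' @return Spearman's rho.
#' @export
track_correlation <- function(track_a, track_b) {
  key_a <- paste(track_a$chrom, track_a$pos)
  key_b <- paste(track_b$chrom, track_b$pos)
  common <- intersect(key_a, key_b)
  if (length(common) < 10L) stop("fewer than 10 positions scored in both tracks")
  stats::cor(track_a$score[match(common, key_a)],
             track_b$score[match(common, key_b)], method = "spearman")
}

#' Write candidates as TSV plus a BED of masked intervals
#'
#' @param candidates output of [call_top_loci()].
#' @param tsv_path,bed_path output files (`NULL` to skip one).
#' @export
write_candidates <- function(candidates, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(candidates, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = candidates$chrom,
                      start = candidates$mask_start - 1L,
                      end = candidates$mask_end,
                      name = paste0(candidates$statistic, "_rank",
                                    candidates$rank))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(candidates)
}
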