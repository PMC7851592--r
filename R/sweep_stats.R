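#' @useDynLib sweepscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Score track
#'
#' A per-focal-SNP (or per-window) statistic along the genome: a data.frame
#' with columns `chrom`, `pos`, `score` and attributes `statistic` and
#' `parameters`. Positions are strictly increasing within each chromosome.
#'
#' @param chrom,pos,score track columns.
#' @param statistic label, e.g. `"G12"`, `"H"`, `"Fst"`.
#' @param parameters list of the scan configuration that produced the track.
#' @return a `score_track` data.frame.
#' @export
score_track <- function(chrom, pos, score, statistic, parameters = list()) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   score = as.numeric(score), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  if (any(!is.finite(df$score))) stop("track scores must be finite")
  structure(df, statistic = statistic, parameters = parameters,
            class = c("score_track", "data.frame"))
}

#' Write a score track as TSV
#'
#' @param track a [score_track()].
#' @param path output file.
#' @export
write_track_tsv <- function(track, path) {
  utils::write.table(as.data.frame(track)[, c("chrom", "pos", "score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genotype-class spectrum of a window
#'
#' Partitions the samples of a multisite-genotype window into classes of
#' identical genotypes and returns the class sizes ranked from most common
#' to most rare. Two samples share a class iff their genotype codes agree at
#' every SNP in the window; a missing call matches nothing, so any sample
#' with a missing call inside the window is a singleton class.
#'
#' @param window integer matrix `n_samples x window_snps` of genotype codes
#'   (e.g. from [window_genotypes()]), or a list of equal-length code
#'   vectors.
#' @return integer vector of class counts, decreasing; attribute `n` holds
#'   the sample count.
#' @export
genotype_spectrum <- function(window) {
  if (is.list(window)) {
    len <- lengths(window)
    if (length(unique(len)) > 1L) stop("ragged window lengths")
    window <- do.call(rbind, window)
  }
  window <- as.matrix(window)
  n <- nrow(window)
  stopifnot(n >= 1)
  has_na <- apply(window, 1L, anyNA)
  counts <- integer(0)
  if (any(!has_na)) {
    keys <- apply(window[!has_na, , drop = FALSE], 1L, paste, collapse = ",")
    counts <- as.integer(table(keys))
  }
  counts <- c(counts, rep(1L, sum(has_na)))
  counts <- sort(counts, decreasing = TRUE)
  structure(counts, n = n, class = "genotype_spectrum")
}

#' G12: pooled-top-two multisite-genotype homozygosity
#'
#' With class frequencies \eqn{p_1 \ge p_2 \ge \dots \ge p_k},
#' \deqn{G12 = (p_1 + p_2)^2 + p_3^2 + \dots + p_k^2.}
#' Pooling the two most frequent classes keeps the statistic sensitive to
#' soft as well as hard sweeps. A window with a single class scores 1.
#'
#' @param spectrum class counts from [genotype_spectrum()] (any integer
#'   vector of counts is accepted).
#' @return G12 score in `(0, 1]`.
#' @export
g12 <- function(spectrum) {
  counts <- sort(as.integer(spectrum), decreasing = TRUE)
  stopifnot(length(counts) >= 1, all(counts >= 1))
  n <- sum(counts)
  if (length(counts) <= 2L) return(1)
  p <- counts / n
  (p[1] + p[2])^2 + sum(p[-(1:2)]^2)
}

#' Genome scan of G12
#'
#' One G12 value per focal SNP whose full `window_snps` window fits on its
#' chromosome. Chromosomes with fewer SNPs than the window are skipped with
#' a warning. The scan core is incremental but exactly reproduces a naive
#' per-window recomputation.
#'
#' @param gm a [genotype_matrix()].
#' @param window_snps odd window size in SNPs (default 201).
#' @return a [score_track()] with `statistic = "G12"`.
#' @export
g12_scan <- function(gm, window_snps = 201L) {
  stopifnot(inherits(gm, "genotype_matrix"),
            window_snps >= 1, window_snps %% 2 == 1)
  chroms <- unique(gm$sites$chrom)
  res <- lapply(chroms, function(ch) {
    idx <- which(gm$sites$chrom == ch)
    if (length(idx) < window_snps) {
      warning(sprintf("chromosome %s has %d SNPs < window of %d; skipped",
                      ch, length(idx), window_snps))
      return(NULL)
    }
    vals <- .g12_scan_core(gm$calls[, idx, drop = FALSE], as.integer(window_snps))
    keep <- !is.na(vals)
    data.frame(chrom = ch, pos = gm$sites$pos[idx][keep], score = vals[keep],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res) || nrow(res) == 0L) stop("no chromosome long enough to scan")
  score_track(res$chrom, res$pos, res$score, "G12",
              list(window_snps = as.integer(window_snps)))
}

#' Maximal pairwise identity-tract length at a focal SNP
#'
#' The number of consecutive SNPs, extending maximally left and right from
#' the focal SNP (inclusive), at which two samples' genotype codes are
#' identical and non-missing; 0 when they differ (or either is missing) at
#' the focal SNP itself. Distances are SNP counts, not base pairs.
#'
#' @param a,b integer code vectors over the same site list (one chromosome).
#' @param focal_index focal SNP index.
#' @return integer tract length in SNPs.
#' @export
pairwise_tract_length <- function(a, b, focal_index) {
  L <- length(a)
  stopifnot(length(b) == L)
  if (focal_index < 1L || focal_index > L) stop("focal index out of range")
  m <- !is.na(a) & !is.na(b) & a == b
  if (!m[focal_index]) return(0L)
  lo <- focal_index
  while (lo > 1L && m[lo - 1L]) lo <- lo - 1L
  hi <- focal_index
  while (hi < L && m[hi + 1L]) hi <- hi + 1L
  hi - lo + 1L
}

#' Genome scan of the H statistic
#'
#' H at a focal SNP is the mean of [pairwise_tract_length()] over all
#' \eqn{n(n-1)/2} sample pairs. H is defined at every SNP: tracts simply
#' truncate at chromosome ends, so no edge exclusion applies.
#'
#' @param gm a [genotype_matrix()] with at least 2 samples.
#' @return a [score_track()] with `statistic = "H"`.
#' @export
h_scan <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (n_samples(gm) < 2L) stop("H scan needs at least 2 samples")
  chroms <- unique(gm$sites$chrom)
  res <- lapply(chroms, function(ch) {
    idx <- which(gm$sites$chrom == ch)
    vals <- .h_scan_core(gm$calls[, idx, drop = FALSE])
    data.frame(chrom = ch, pos = gm$sites$pos[idx], score = vals,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  score_track(res$chrom, res$pos, res$score, "H", list())
}
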