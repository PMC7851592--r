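#' Genotype codes
#'
#' Unphased diploid genotypes at biallelic SNPs are stored as integer codes:
#' 0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#' `NA` = missing. The three non-missing codes are the "pseudo-alleles" that
#' multisite-genotype statistics operate on.
#'
#' @name genotype-codes
NULL

#' Construct a genotype matrix
#'
#' The substrate of every scan: an individuals-by-SNPs matrix of unphased
#' genotype codes plus site metadata (chromosome, 1-based position, ref/alt
#' alleles). Sites must be coordinate-sorted with no duplicates and every
#' site must carry at least one non-missing call.
#'
#' @param calls integer matrix, `n_samples x n_sites`, values in
#'   `{0, 1, 2, NA}` (see [genotype-codes]).
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param samples character vector of sample identifiers, one per row.
#' @return an object of class `genotype_matrix`: a list with elements
#'   `calls`, `sites`, `samples`.
#' @export
genotype_matrix <- function(calls, sites, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(
    nrow(calls) == length(samples),
    ncol(calls) == nrow(sites),
    all(c("chrom", "pos", "ref", "alt") %in% names(sites))
  )
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (any(sites$pos < 1L)) stop("site positions must be >= 1")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites)))) {
    sites <- sites[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  if (anyDuplicated(sites[, c("chrom", "pos")])) {
    stop("duplicate sites (same chromosome and position)")
  }
  bad <- !(calls %in% c(0L, 1L, 2L) | is.na(calls))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  if (ncol(calls) > 0L && any(colSums(!is.na(calls)) == 0L)) {
    stop("every site must have at least one non-missing call")
  }
  rownames(sites) <- NULL
  dimnames(calls) <- NULL
  structure(
    list(calls = calls, sites = sites, samples = as.character(samples)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d SNPs on %d chromosome(s)\n",
    length(x$samples), nrow(x$sites), length(unique(x$sites$chrom))
  ))
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

n_samples <- function(x) length(x$samples)
n_sites <- function(x) nrow(x$sites)

#' Subset a genotype matrix by site index and/or sample
#'
#' @param gm a [genotype_matrix()].
#' @param sites integer or logical index over sites.
#' @param samples integer, logical or character index over samples.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, sites = NULL, samples = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  calls <- gm$calls
  site_df <- gm$sites
  samp <- gm$samples
  if (!is.null(samples)) {
    if (is.character(samples)) {
      idx <- match(samples, samp)
      if (anyNA(idx)) {
        stop("unknown sample(s): ", paste(samples[is.na(idx)], collapse = ", "))
      }
      samples <- idx
    }
    calls <- calls[samples, , drop = FALSE]
    samp <- samp[samples]
  }
  if (!is.null(sites)) {
    calls <- calls[, sites, drop = FALSE]
    site_df <- site_df[sites, , drop = FALSE]
  }
  genotype_matrix(calls, site_df, samp)
}

#' Write a genotype matrix as TSV (debugging aid)
#'
#' One row per sample, one column per site (named `chrom:pos`); missing
#' calls written as `NA`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @export
write_genotype_tsv <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  m <- gm$calls
  colnames(m) <- paste0(gm$sites$chrom, ":", gm$sites$pos)
  df <- data.frame(sample = gm$samples, m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
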