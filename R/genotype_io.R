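#' Site-filter configuration
#'
#' Filtering applied when a VCF is loaded: only biallelic SNPs are ever
#' retained; on top of that, records are dropped when their FILTER value is
#' not in `keep_filters`, or when the fraction of missing genotype calls
#' exceeds `max_missing`. Remaining missing calls are kept in the matrix and
#' handled per-statistic downstream.
#'
#' @param max_missing maximum tolerated per-site missing-call fraction
#'   (default 0.10).
#' @param keep_filters FILTER values accepted (default `PASS` and `.`).
#' @return a `site_filter_config` list.
#' @export
site_filters <- function(max_missing = 0.10, keep_filters = c("PASS", ".")) {
  stopifnot(max_missing >= 0, max_missing <= 1, length(keep_filters) >= 1)
  structure(list(max_missing = max_missing, keep_filters = keep_filters),
            class = "site_filter_config")
}

## GT string -> code. Any allele index > 1 or "." makes the call missing;
## multiallelic records never reach this point (dropped earlier).
.gt_to_code <- function(gt) {
  gt <- sub(":.*$", "", gt)
  a <- strsplit(gt, "[/|]")
  vapply(a, function(al) {
    if (length(al) != 2L || any(al == ".") || any(is.na(al))) return(NA_integer_)
    al <- suppressWarnings(as.integer(al))
    if (anyNA(al) || any(al > 1L)) return(NA_integer_)
    sum(al)
  }, integer(1))
}

#' Read a VCF into a genotype matrix
#'
#' Loads GT calls with \pkg{vcfR}, keeps biallelic SNPs only (single-base
#' REF and ALT, no comma in ALT), applies the FILTER-column and
#' missing-fraction policies of [site_filters()], and returns a
#' coordinate-sorted [genotype_matrix()].
#'
#' @param path VCF file (plain or bgzipped).
#' @param sample_subset optional character vector of samples to keep.
#' @param filters a [site_filters()] configuration.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, sample_subset = NULL, filters = site_filters()) {
  if (!file.exists(path)) stop("cannot read VCF: file not found: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  gt_raw <- vcf@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L) stop("VCF has no genotype columns")
  vcf_samples <- colnames(gt_raw)[-1L]
  if (!is.null(sample_subset)) {
    missing_s <- setdiff(sample_subset, vcf_samples)
    if (length(missing_s)) {
      stop("unknown sample name(s): ", paste(missing_s, collapse = ", "))
    }
    keep_s <- sample_subset
  } else {
    keep_s <- vcf_samples
  }

  ref <- fix$REF
  alt <- fix$ALT
  filt <- fix$FILTER
  filt[is.na(filt)] <- "."
  snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE) &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  keep <- snp & filt %in% filters$keep_filters
  if (!any(keep)) stop("zero sites remain after biallelic-SNP/FILTER filtering")

  gt <- gt_raw[keep, keep_s, drop = FALSE]
  codes <- apply(gt, 2L, .gt_to_code)
  if (is.null(dim(codes))) codes <- matrix(codes, nrow = 1L)
  calls <- t(codes)  # samples x sites

  miss_frac <- colMeans(is.na(calls))
  ok <- miss_frac <= filters$max_missing & colSums(!is.na(calls)) > 0L
  if (!any(ok)) stop("zero sites remain after missing-fraction filtering")
  calls <- calls[, ok, drop = FALSE]
  sites <- data.frame(
    chrom = fix$CHROM[keep][ok],
    pos = as.integer(fix$POS[keep][ok]),
    ref = ref[keep][ok],
    alt = alt[keep][ok],
    stringsAsFactors = FALSE
  )
  genotype_matrix(calls, sites, keep_s)
}

#' Extract the multisite genotypes of a symmetric SNP window
#'
#' Returns the window of `window_snps` consecutive SNPs centred on the focal
#' SNP, one multisite genotype (row) per sample. The window must lie
#' entirely on the focal SNP's chromosome; if the focal SNP is closer than
#' `(window_snps - 1) / 2` to either chromosome end the focal SNP has no
#' window and `NULL` is returned (no score at this SNP — not an error).
#'
#' @param gm a [genotype_matrix()].
#' @param focal_index site index (over the whole matrix) of the focal SNP.
#' @param window_snps odd window size in SNPs.
#' @return integer matrix `n_samples x window_snps` of genotype codes with
#'   attributes `chrom` and `focal_pos`, or `NULL` near a chromosome edge.
#' @export
window_genotypes <- function(gm, focal_index, window_snps) {
  stopifnot(inherits(gm, "genotype_matrix"),
            window_snps >= 1, window_snps %% 2 == 1)
  if (focal_index < 1L || focal_index > n_sites(gm)) {
    stop("focal_index out of range")
  }
  half <- (window_snps - 1L) / 2L
  chrom <- gm$sites$chrom[focal_index]
  lo <- focal_index - half
  hi <- focal_index + half
  if (lo < 1L || hi > n_sites(gm)) return(NULL)
  if (gm$sites$chrom[lo] != chrom || gm$sites$chrom[hi] != chrom) return(NULL)
  w <- gm$calls[, lo:hi, drop = FALSE]
  attr(w, "chrom") <- chrom
  attr(w, "focal_pos") <- gm$sites$pos[focal_index]
  w
}

#' Nucleotide diversity from a filtered SNP matrix
#'
#' Per-SNP unbiased expected heterozygosity
#' \eqn{2 p (1-p) \cdot 2n_c / (2n_c - 1)}, where \eqn{p} is the
#' alternate-allele frequency over the \eqn{2 n_c} non-missing chromosomes at
#' the site, summed over SNPs and divided by the number of callable sites.
#' Genome-wide diversity needs the callable-site denominator from the
#' upstream calling pipeline; when it is not supplied the SNP count is used
#' instead and the estimate is flagged as variant-sites-only (an upper
#' envelope useful for relative comparisons, not an absolute pi).
#'
#' @param gm a [genotype_matrix()].
#' @param callable_sites optional total number of callable sites.
#' @return diversity estimate (a fraction), with attribute `denominator`
#'   set to `"callable_sites"` or `"variant-sites-only"`.
#' @export
nucleotide_diversity <- function(gm, callable_sites = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"), n_sites(gm) >= 1)
  nc <- colSums(!is.na(gm$calls))           # non-missing diploids per site
  alt <- colSums(gm$calls, na.rm = TRUE)    # alt allele count
  chrom_n <- 2 * nc
  p <- alt / chrom_n
  per_site <- 2 * p * (1 - p) * chrom_n / (chrom_n - 1)
  per_site[chrom_n <= 1] <- 0
  total <- sum(per_site)
  if (is.null(callable_sites)) {
    est <- total / n_sites(gm)
    attr(est, "denominator") <- "variant-sites-only"
  } else {
    if (callable_sites < n_sites(gm)) {
      stop("callable_sites must be >= number of SNPs in the matrix")
    }
    est <- total / callable_sites
    attr(est, "denominator") <- "callable_sites"
  }
  est
}
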