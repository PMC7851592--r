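#' Per-SNP Weir--Cockerham Fst between two cohorts
#'
#' The two-population diploid variance-components estimator (theta), using
#' per-population non-missing sample sizes, alternate-allele frequencies and
#' observed heterozygote proportions. Sites are matched across cohorts by
#' (chromosome, position, ref, alt); sites present with swapped ref/alt are
#' reconciled by recoding the second cohort, other allele conflicts are
#' dropped with a message. Theta is undefined (NA) when the pooled sample is
#' monomorphic (all variance components zero). Negative estimates are
#' retained.
#'
#' @param pop_a,pop_b [genotype_matrix()] objects.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `a_component`, `b_component`, `c_component`, `fst`.
#' @export
wc_fst_per_snp <- function(pop_a, pop_b) {
  stopifnot(inherits(pop_a, "genotype_matrix"), inherits(pop_b, "genotype_matrix"))
  key_a <- paste(pop_a$sites$chrom, pop_a$sites$pos)
  key_b <- paste(pop_b$sites$chrom, pop_b$sites$pos)
  common <- intersect(key_a, key_b)
  if (length(common) == 0L) stop("empty site intersection between cohorts")
  ia <- match(common, key_a)
  ib <- match(common, key_b)

  same <- pop_a$sites$ref[ia] == pop_b$sites$ref[ib] &
          pop_a$sites$alt[ia] == pop_b$sites$alt[ib]
  swapped <- pop_a$sites$ref[ia] == pop_b$sites$alt[ib] &
             pop_a$sites$alt[ia] == pop_b$sites$ref[ib]
  drop_n <- sum(!same & !swapped)
  if (drop_n > 0L) {
    message(sprintf("dropping %d site(s) with irreconcilable allele coding", drop_n))
  }
  keep <- same | swapped
  if (!any(keep)) stop("zero shared sites remain after allele reconciliation")
  ia <- ia[keep]; ib <- ib[keep]; swapped <- swapped[keep]

  ca <- pop_a$calls[, ia, drop = FALSE]
  cb <- pop_b$calls[, ib, drop = FALSE]
  if (any(swapped)) {
    cb[, swapped] <- 2L - cb[, swapped, drop = FALSE]
  }

  comp <- .wc_components(ca, cb)
  denom <- comp$a + comp$b + comp$c
  fst <- ifelse(denom == 0, NA_real_, comp$a / denom)
  out <- data.frame(
    chrom = pop_a$sites$chrom[ia], pos = pop_a$sites$pos[ia],
    ref = pop_a$sites$ref[ia], alt = pop_a$sites$alt[ia],
    a_component = comp$a, b_component = comp$b, c_component = comp$c,
    fst = fst, stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## vectorised two-population theta components over site columns
.wc_components <- function(ca, cb) {
  r <- 2
  n1 <- colSums(!is.na(ca)); n2 <- colSums(!is.na(cb))
  p1 <- colSums(ca, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(cb, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(ca == 1L, na.rm = TRUE) / n1
  h2 <- colSums(cb == 1L, na.rm = TRUE) / n2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Mean per-SNP Fst in sliding windows
#'
#' Arithmetic mean of the defined per-SNP theta values over SNPs whose
#' position falls in `[start, start + window_bp)`, windows anchored at
#' position 1 and advancing by `step_bp`. Windows with fewer than
#' `min_snps` defined values get `mean_fst = NA`. "Mean per-SNP Fst" is an
#' average of per-SNP ratios; set `ratio_of_means = TRUE` for the
#' ratio-of-summed-components alternative.
#'
#' @param snp_fst output of [wc_fst_per_snp()].
#' @param window_bp window span in bp (default 10000).
#' @param step_bp step in bp (default 1000).
#' @param min_snps minimum defined per-SNP values per window (default 5).
#' @param ratio_of_means if `TRUE`, window value is
#'   `sum(a) / sum(a + b + c)` instead of `mean(a / (a + b + c))`.
#' @return data.frame with `chrom`, `window_start`, `window_end` (1-based
#'   inclusive start, exclusive end), `n_snps`, `mean_fst`.
#' @export
fst_windows <- function(snp_fst, window_bp = 10000L, step_bp = 1000L,
                        min_snps = 5L, ratio_of_means = FALSE) {
  stopifnot(window_bp > 0, step_bp > 0, min_snps >= 1)
  res <- lapply(unique(snp_fst$chrom), function(ch) {
    d <- snp_fst[snp_fst$chrom == ch, , drop = FALSE]
    d <- d[order(d$pos), , drop = FALSE]
    maxpos <- max(d$pos)
    starts <- seq.int(1L, maxpos, by = step_bp)
    lo <- findInterval(starts - 1L, d$pos) + 1L
    hi <- findInterval(starts + window_bp - 1L, d$pos)
    n_def <- mean_fst <- numeric(length(starts))
    for (w in seq_along(starts)) {
      if (hi[w] < lo[w]) { n_def[w] <- 0; mean_fst[w] <- NA_real_; next }
      vals <- d$fst[lo[w]:hi[w]]
      av <- d$a_component[lo[w]:hi[w]]
      dv <- av + d$b_component[lo[w]:hi[w]] + d$c_component[lo[w]:hi[w]]
      def <- !is.na(vals)
      n_def[w] <- sum(def)
      if (n_def[w] < min_snps) {
        mean_fst[w] <- NA_real_
      } else if (ratio_of_means) {
        mean_fst[w] <- sum(av[def]) / sum(dv[def])
      } else {
        mean_fst[w] <- mean(vals[def])
      }
    }
    data.frame(chrom = ch, window_start = starts,
               window_end = starts + window_bp, n_snps = as.integer(n_def),
               mean_fst = mean_fst, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Window Fst as a score track
#'
#' Defined windows only, positioned at their midpoints, so window Fst can
#' feed the same outlier calling as the homogeneity scans.
#'
#' @param windows output of [fst_windows()].
#' @return a [score_track()] with `statistic = "Fst"`.
#' @export
fst_track <- function(windows) {
  def <- !is.na(windows$mean_fst)
  if (!any(def)) stop("no defined Fst windows")
  w <- windows[def, , drop = FALSE]
  score_track(w$chrom, (w$window_start + w$window_end - 1L) %/% 2L,
              w$mean_fst, "Fst", list())
}

#' Write Fst windows as BED-like TSV (0-based half-open coordinates)
#'
#' @param windows output of [fst_windows()].
#' @param path output file.
#' @export
write_fst_bed <- function(windows, path) {
  df <- data.frame(chrom = windows$chrom,
                   start = windows$window_start - 1L,
                   end = windows$window_end - 1L,
                   n_snps = windows$n_snps,
                   mean_fst = windows$mean_fst)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
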