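# Independent brute-force oracles, deliberately written as direct
# transcriptions of the definitions (no sharing with package internals).

# random genotype matrix with optional missingness
make_test_matrix <- function(n, L, seed, miss = 0, chrom = "chr1") {
  set.seed(seed)
  calls <- matrix(sample(0:2, n * L, replace = TRUE), nrow = n)
  if (miss > 0) {
    calls[sample(length(calls), round(miss * length(calls)))] <- NA
  }
  # guarantee at least one non-missing call per site
  for (j in which(colSums(!is.na(calls)) == 0)) calls[1, j] <- 0L
  pos <- sort(sample.int(L * 200L, L))
  genotype_matrix(calls,
                  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "C"),
                  sprintf("s%02d", seq_len(n)))
}

# G12 from ranked class counts, straight from the formula
g12_ref <- function(counts) {
  counts <- sort(counts, decreasing = TRUE)
  p <- counts / sum(counts)
  if (length(p) <= 2) return(1)
  (p[1] + p[2])^2 + sum(p[-c(1, 2)]^2)
}

# spectrum by literal definition: identical rows, NA matches nothing
spectrum_ref <- function(w) {
  n <- nrow(w)
  counts <- integer(0)
  used <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (used[i]) next
    if (anyNA(w[i, ])) { counts <- c(counts, 1L); used[i] <- TRUE; next }
    cls <- i
    if (i < n) for (j in (i + 1):n) {
      if (used[j] || anyNA(w[j, ])) next
      if (all(w[i, ] == w[j, ])) cls <- c(cls, j)
    }
    used[cls] <- TRUE
    counts <- c(counts, length(cls))
  }
  sort(counts, decreasing = TRUE)
}

# per-focal naive G12 scan over one chromosome's calls
naive_g12_chrom <- function(calls, window) {
  L <- ncol(calls)
  half <- (window - 1) / 2
  vals <- rep(NA_real_, L)
  if (L < window) return(vals)
  for (f in (half + 1):(L - half)) {
    w <- calls[, (f - half):(f + half), drop = FALSE]
    vals[f] <- g12_ref(spectrum_ref(w))
  }
  vals
}

# naive tract length: expand stepwise from the focal SNP
naive_tract <- function(a, b, f) {
  eq <- function(t) !is.na(a[t]) && !is.na(b[t]) && a[t] == b[t]
  if (!eq(f)) return(0L)
  lo <- f; hi <- f
  while (lo > 1 && eq(lo - 1)) lo <- lo - 1
  while (hi < length(a) && eq(hi + 1)) hi <- hi + 1
  hi - lo + 1L
}

# naive H scan over one chromosome's calls
naive_h_chrom <- function(calls) {
  n <- nrow(calls); L <- ncol(calls)
  pairs <- utils::combn(n, 2)
  vapply(seq_len(L), function(f) {
    mean(apply(pairs, 2, function(p)
      naive_tract(calls[p[1], ], calls[p[2], ], f)))
  }, numeric(1))
}

# brute-force greedy outlier calling on a (chrom, pos, score) data.frame
naive_top_loci <- function(df, k, radius) {
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  alive <- rep(TRUE, nrow(df))
  out <- df[0, c("chrom", "pos", "score")]
  repeat {
    cand <- which(alive)
    if (!length(cand) || nrow(out) >= k) break
    best <- cand[order(-df$score[cand], df$chrom[cand], df$pos[cand])][1]
    out <- rbind(out, df[best, c("chrom", "pos", "score")])
    alive <- alive & !(df$chrom == df$chrom[best] &
                         abs(df$pos - df$pos[best]) <= radius)
  }
  rownames(out) <- NULL
  out
}

# nearest gene by exhaustive scan
naive_nearest <- function(chrom, pos, genes) {
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (!nrow(g)) return(list(gene_id = NA_character_, dist = Inf))
  best_d <- Inf; best <- NA_character_; best_start <- Inf
  for (i in seq_len(nrow(g))) {
    d <- if (pos >= g$start[i] && pos <= g$end[i]) 0 else
      min(abs(pos - g$start[i]), abs(pos - g$end[i]))
    if (d < best_d || (d == best_d && g$start[i] < best_start)) {
      best_d <- d; best <- g$gene_id[i]; best_start <- g$start[i]
    }
  }
  list(gene_id = best, dist = best_d)
}

# reference enrichment walk, written independently as a plain loop
naive_enrichment <- function(scores, categories, genes, r_max, min_genes,
                             mask_kb) {
  cat_members <- split(categories$gene_id, categories$category_id)
  ranking <- scores$gene_id
  found <- character(0); found_r <- integer(0)
  r <- 1
  while (r <= r_max && r <= length(ranking)) {
    progressed <- TRUE
    while (progressed) {
      progressed <- FALSE
      top <- ranking[1:min(r, length(ranking))]
      for (cid in sort(names(cat_members))) {
        if (cid %in% found) next
        inset <- top[top %in% cat_members[[cid]]]
        if (length(inset) >= min_genes) {
          found <- c(found, cid); found_r <- c(found_r, r)
          contrib <- inset[1:min_genes]
          drop <- character(0)
          for (g in contrib) {
            gi <- which(genes$gene_id == g)
            lo <- genes$start[gi] - mask_kb * 1000
            hi <- genes$end[gi] + mask_kb * 1000
            for (h in ranking) {
              hj <- which(genes$gene_id == h)
              if (genes$chrom[hj] == genes$chrom[gi] &&
                  genes$end[hj] >= lo && genes$start[hj] <= hi) {
                drop <- c(drop, h)
              }
            }
          }
          ranking <- setdiff(ranking, drop)
          progressed <- TRUE
          break
        }
      }
    }
    r <- r + 1
  }
  data.frame(category_id = found, rank = found_r, stringsAsFactors = FALSE)
}

# spread-out gene fixture used by enrichment tests: genes far apart so the
# 30-kb masking never couples two genes
spread_genes <- function(n, gap = 100000L, chrom = "chr1") {
  starts <- seq(10000L, by = gap, length.out = n)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)), chrom = chrom,
             start = starts, end = starts + 2000L, strand = "+",
             stringsAsFactors = FALSE)
}
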