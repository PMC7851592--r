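#' Read a gene-to-category map
#'
#' Two-column TSV (`gene_id`, `category_id`), one membership per line;
#' categories may overlap.
#'
#' @param path TSV file.
#' @return data.frame with columns `gene_id`, `category_id`.
#' @export
read_category_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "category_id") %in% names(df))) {
    stop("category map needs columns gene_id and category_id")
  }
  unique(df[, c("gene_id", "category_id")])
}

## category_id -> character vector of member gene ids
.category_list <- function(categories) {
  split(categories$gene_id, categories$category_id)
}

#' Rank-walk GO enrichment with iterative gene-cluster masking
#'
#' Walks the gene ranking downward. A category becomes a discovery the
#' first time at least `min_genes` of the genes ranked so far belong to it.
#' Each discovery masks genes whose interval intersects the region within
#' `mask_kb` kb upstream/downstream of the `min_genes` contributing genes
#' (the first `min_genes` members by rank), and subsequent ranks are
#' recomputed over the surviving genes — this stops clustered paralogs that
#' share one homogeneity signal from yielding repeated discoveries.
#'
#' @param scores ranked gene scores from [gene_scores()].
#' @param categories gene-to-category map (data.frame `gene_id`,
#'   `category_id`).
#' @param genes gene table from [read_genes()] (intervals drive masking).
#' @param r_max deepest rank examined (default 50).
#' @param min_genes genes required for a discovery (default 3).
#' @param mask_kb masking margin in kb around contributing genes
#'   (default 30).
#' @return list: `discoveries` data.frame (`category_id`, `rank`,
#'   `genes` comma-joined contributing genes), `curve` data.frame
#'   (`r`, `cumulative`), `masked_genes` character vector.
#' @export
go_enrichment <- function(scores, categories, genes, r_max = 50L,
                          min_genes = 3L, mask_kb = 30L) {
  stopifnot(nrow(scores) >= 1, nrow(categories) >= 1)
  cat_list <- .category_list(categories)
  gene_row <- stats::setNames(seq_len(nrow(genes)), genes$gene_id)

  surviving <- scores$gene_id               # rank order, best first
  discovered <- character(0)
  disc_rank <- integer(0)
  disc_genes <- list()
  masked <- character(0)

  mask_by <- function(contrib) {
    margin <- mask_kb * 1000
    hit <- rep(FALSE, length(surviving))
    for (g in contrib) {
      ri <- gene_row[[g]]
      lo <- genes$start[ri] - margin
      hi <- genes$end[ri] + margin
      rows <- gene_row[surviving]
      hit <- hit | (genes$chrom[rows] == genes$chrom[ri] &
                    genes$end[rows] >= lo & genes$start[rows] <= hi)
    }
    surviving[hit]
  }

  r <- 1L
  while (r <= r_max && r <= length(surviving)) {
    repeat {
      top <- surviving[seq_len(min(r, length(surviving)))]
      new_disc <- NULL
      for (cid in setdiff(names(cat_list), discovered)) {
        members <- top[top %in% cat_list[[cid]]]
        if (length(members) >= min_genes) {
          new_disc <- cid
          contrib <- members[seq_len(min_genes)]  # first min_genes by rank
          break
        }
      }
      if (is.null(new_disc)) break
      discovered <- c(discovered, new_disc)
      disc_rank <- c(disc_rank, r)
      disc_genes[[new_disc]] <- contrib
      dropped <- mask_by(contrib)
      masked <- c(masked, dropped)
      surviving <- setdiff(surviving, dropped)
    }
    r <- r + 1L
  }

  curve <- data.frame(r = seq_len(r_max),
                      cumulative = vapply(seq_len(r_max), function(rr)
                        sum(disc_rank <= rr), integer(1)))
  discoveries <- data.frame(
    category_id = discovered, rank = disc_rank,
    genes = vapply(discovered, function(cid)
      paste(disc_genes[[cid]], collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  rownames(discoveries) <- NULL
  list(discoveries = discoveries, curve = curve, masked_genes = unique(masked))
}

#' Permutation estimate of expected false enrichment discoveries
#'
#' Shuffles the scores across the scored genes (annotation geometry and
#' category membership fixed), re-runs the full [go_enrichment()] walk, and
#' averages the cumulative discovery count per rank over permutations. The
#' result is the expected number of discoveries at each rank when gene
#' scores carry no signal — the gray reference curve to plot against the
#' observed one.
#'
#' @inheritParams go_enrichment
#' @param n_permutations number of score shuffles (default 100).
#' @param seed RNG seed.
#' @return data.frame `r`, `expected_false_discoveries`, `mc_se`
#'   (Monte-Carlo standard error of the mean).
#' @export
enrichment_fdr <- function(scores, categories, genes, r_max = 50L,
                           min_genes = 3L, mask_kb = 30L,
                           n_permutations = 100L, seed = 1L) {
  stopifnot(n_permutations >= 2)
  set.seed(as.integer(seed))
  counts <- matrix(0L, nrow = n_permutations, ncol = r_max)
  for (b in seq_len(n_permutations)) {
    perm <- scores
    perm$score <- sample(perm$score)
    perm <- perm[order(-perm$score, perm$gene_id), , drop = FALSE]
    perm$rank <- seq_len(nrow(perm))
    res <- go_enrichment(perm, categories, genes, r_max = r_max,
                         min_genes = min_genes, mask_kb = mask_kb)
    counts[b, ] <- res$curve$cumulative
  }
  data.frame(
    r = seq_len(r_max),
    expected_false_discoveries = colMeans(counts),
    mc_se = apply(counts, 2L, stats::sd) / sqrt(n_permutations)
  )
}

#' Category membership test for an a-priori gene set
#'
#' Asks whether candidate loci hit a given category's genes more often than
#' loci placed at random. Candidate positions are permuted along the genome
#' (uniformly over scored focal positions, preserving count and spacing, as
#' in [distance_null_test()]), nearest-gene sets re-derived, and the
#' in-category gene count recorded per permutation. Two p-values are
#' returned: `p_fisher`, a two-sided Fisher's exact test of the observed
#' 2x2 table (in-category vs not) against permutation-calibrated expected
#' margins, and `p_perm`, the direct permutation tail probability of seeing
#' at least the observed in-category count.
#'
#' @param candidate_genes character vector of genes hit by candidates.
#' @param category_genes character vector of the category's member genes.
#' @param genes gene table from [read_genes()].
#' @param candidates candidate data.frame (`chrom`, `pos`).
#' @param track a [score_track()] defining the permutation pool.
#' @param n_permutations permutations (default 100).
#' @param mask_radius_bp spacing constraint (default 100000).
#' @param seed RNG seed.
#' @return list with `p_fisher`, `p_perm`, `observed_in_category`,
#'   `expected_in_category`.
#' @export
category_test <- function(candidate_genes, category_genes, genes, candidates,
                          track, n_permutations = 100L,
                          mask_radius_bp = 100000L, seed = 1L) {
  stopifnot(length(candidate_genes) >= 1)
  x_obs <- sum(unique(candidate_genes) %in% category_genes)
  n_obs <- length(unique(candidate_genes))
  set.seed(as.integer(seed))
  perm_in <- perm_tot <- integer(n_permutations)
  for (b in seq_len(n_permutations)) {
    pos <- .sample_spaced_positions(track, nrow(candidates), mask_radius_bp)
    hits <- nearest_gene(pos, genes)
    gset <- unique(hits$gene_id[!is.na(hits$gene_id)])
    perm_in[b] <- sum(gset %in% category_genes)
    perm_tot[b] <- length(gset)
  }
  exp_in <- mean(perm_in)
  exp_tot <- mean(perm_tot)
  tab <- matrix(c(x_obs, n_obs - x_obs,
                  round(exp_in), max(0L, round(exp_tot - exp_in))), nrow = 2)
  p_fisher <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
    else stats::fisher.test(tab)$p.value
  p_perm <- (1 + sum(perm_in >= x_obs)) / (n_permutations + 1)
  list(p_fisher = p_fisher, p_perm = p_perm,
       observed_in_category = x_obs, expected_in_category = exp_in)
}
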