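#' Read gene annotations from BED or GFF3
#'
#' BED gives intervals and names only; GFF3 additionally attaches CDS
#' segments (features of type `CDS` whose `Parent` chain resolves to the
#' gene, or whose `Parent` is the gene itself). All coordinates are returned
#' 1-based inclusive; \pkg{rtracklayer} handles the BED 0-based half-open
#' convention. Genes are sorted by coordinate and deduplicated by id.
#'
#' @param path a `.bed`, `.gff`, `.gff3` (optionally gzipped) file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`; attribute `cds` is a data.frame (`gene_id`, `start`, `end`)
#'   of CDS segments (possibly empty).
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    ids <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0("gene", seq_along(gr))
    genes <- data.frame(
      gene_id = ids,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
    cds <- data.frame(gene_id = character(0), start = integer(0),
                      end = integer(0))
  } else if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    type <- as.character(gr$type)
    g <- gr[type == "gene"]
    if (length(g) == 0L) stop("no gene features in GFF3: ", path)
    gid <- as.character(g$ID)
    genes <- data.frame(
      gene_id = gid,
      chrom = as.character(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g), end = GenomicRanges::end(g),
      strand = as.character(GenomicRanges::strand(g)),
      stringsAsFactors = FALSE
    )
    ## map transcript id -> gene id so CDS Parent=transcript resolves
    tx <- gr[type %in% c("mRNA", "transcript")]
    tx_parent <- vapply(as.list(tx$Parent), function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1))
    tx_map <- stats::setNames(tx_parent, as.character(tx$ID))
    cd <- gr[type == "CDS"]
    if (length(cd)) {
      par <- vapply(as.list(cd$Parent), function(p)
        if (length(p)) as.character(p[1]) else NA_character_, character(1))
      owner <- ifelse(par %in% genes$gene_id, par, unname(tx_map[par]))
      keep <- !is.na(owner) & owner %in% genes$gene_id
      cds <- data.frame(gene_id = owner[keep],
                        start = GenomicRanges::start(cd)[keep],
                        end = GenomicRanges::end(cd)[keep],
                        stringsAsFactors = FALSE)
      ## one transcript's worth of CDS per gene: drop duplicated segments
      cds <- unique(cds)
      cds <- cds[order(cds$gene_id, cds$start), , drop = FALSE]
    } else {
      cds <- data.frame(gene_id = character(0), start = integer(0),
                        end = integer(0))
    }
  } else {
    stop("unsupported annotation format: .", ext, " (want BED or GFF3)")
  }
  if (any(genes$start > genes$end)) stop("gene with start > end")
  genes <- genes[!duplicated(genes$gene_id), , drop = FALSE]
  genes <- genes[order(genes$chrom, genes$start, genes$end), , drop = FALSE]
  rownames(genes) <- NULL
  if (nrow(genes) == 0L) stop("zero genes parsed from ", path)
  attr(genes, "cds") <- cds
  genes
}

#' Nearest protein-coding gene for each candidate locus
#'
#' Distance is measured from the candidate's focal position to the nearest
#' gene boundary; 0 when the position lies inside the gene interval. Ties
#' are broken by smaller gene start. Candidates on chromosomes without
#' genes get `NA` gene and infinite distance.
#'
#' @param candidates data.frame with `chrom` and `pos` (e.g. from
#'   [call_top_loci()]).
#' @param genes gene table from [read_genes()].
#' @return `candidates` with added columns `gene_id` and `gene_distance`.
#' @export
nearest_gene <- function(candidates, genes) {
  gene_id <- character(nrow(candidates))
  dist <- numeric(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    g <- genes[genes$chrom == candidates$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L) { gene_id[i] <- NA_character_; dist[i] <- Inf; next }
    p <- candidates$pos[i]
    d <- ifelse(p >= g$start & p <= g$end, 0,
                pmin(abs(p - g$start), abs(p - g$end)))
    j <- which(d == min(d))
    if (length(j) > 1L) j <- j[which.min(g$start[j])]
    gene_id[i] <- g$gene_id[j]
    dist[i] <- d[j]
  }
  candidates$gene_id <- gene_id
  candidates$gene_distance <- dist
  candidates
}

#' Keep candidates within a maximum distance of a gene
#'
#' The boundary is inclusive: a candidate exactly `max_distance` away is
#' retained.
#'
#' @param candidates data.frame with `chrom`, `pos`.
#' @param genes gene table from [read_genes()].
#' @param max_distance bp cutoff (default 20000).
#' @return annotated subset of `candidates`.
#' @export
filter_by_gene_distance <- function(candidates, genes, max_distance = 20000) {
  ann <- nearest_gene(candidates, genes)
  out <- ann[!is.na(ann$gene_id) & ann$gene_distance <= max_distance, ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

## sample `size` focal positions from a track, re-applying the candidate
## spacing constraint (no two picks within mask_radius_bp on a chromosome)
.sample_spaced_positions <- function(track, size, mask_radius_bp) {
  ord <- sample.int(nrow(track))
  sel <- integer(0)
  sel_chrom <- character(0); sel_pos <- integer(0)
  for (i in ord) {
    ch <- track$chrom[i]; p <- track$pos[i]
    same <- sel_chrom == ch
    if (any(same) && min(abs(sel_pos[same] - p)) <= mask_radius_bp) next
    sel <- c(sel, i)
    sel_chrom <- c(sel_chrom, ch); sel_pos <- c(sel_pos, p)
    if (length(sel) == size) break
  }
  if (length(sel) < size) {
    stop("too few scored positions to draw ", size,
         " spaced permutation positions")
  }
  track[sel, c("chrom", "pos"), drop = FALSE]
}

#' Permutation test of candidate-to-gene distances
#'
#' Tests whether candidate loci sit systematically nearer to (or farther
#' from) genes than random scored focal positions. Each permutation draws
#' the same number of positions uniformly without replacement from the
#' scored focal positions genome-wide, re-applying the candidate spacing
#' constraint, and records their nearest-gene distances. Observed distances
#' are compared against the pooled permuted distances with a two-sided
#' Wilcoxon rank-sum test (exact for small samples, normal approximation
#' with continuity correction otherwise, as in [stats::wilcox.test()]).
#'
#' @param candidates data.frame with `chrom`, `pos`.
#' @param genes gene table from [read_genes()].
#' @param track a [score_track()]; its positions define the resampling pool.
#' @param n_permutations at least 100 (default 100).
#' @param mask_radius_bp spacing constraint used when candidates were
#'   called (default 100000).
#' @param seed RNG seed.
#' @return list: `observed` distances, `permuted` pooled distances,
#'   `p_value`, `observed_median`, `null_median`.
#' @export
distance_null_test <- function(candidates, genes, track,
                               n_permutations = 100L,
                               mask_radius_bp = 100000L, seed = 1L) {
  stopifnot(n_permutations >= 100)
  obs <- nearest_gene(candidates, genes)$gene_distance
  set.seed(as.integer(seed))
  perm <- unlist(lapply(seq_len(n_permutations), function(b) {
    pos <- .sample_spaced_positions(track, nrow(candidates), mask_radius_bp)
    nearest_gene(pos, genes)$gene_distance
  }))
  wt <- suppressWarnings(stats::wilcox.test(obs, perm, alternative = "two.sided",
                                            exact = length(obs) <= 20))
  list(observed = obs, permuted = perm, p_value = wt$p.value,
       observed_median = stats::median(obs),
       null_median = stats::median(perm))
}

#' Score genes by the maximal in-gene focal-SNP statistic
#'
#' A gene's score is the maximum track value among focal SNPs whose
#' position lies inside the gene interval; genes containing no scored focal
#' SNP are unscored and absent from the ranking. Rank 1 is the highest
#' score; ties are broken by gene id.
#'
#' @param track a [score_track()].
#' @param genes gene table from [read_genes()].
#' @return data.frame `gene_id`, `score`, `rank` (rank-sorted).
#' @export
gene_scores <- function(track, genes) {
  score <- rep(NA_real_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    v <- track$score[track$chrom == genes$chrom[i] &
                     track$pos >= genes$start[i] & track$pos <= genes$end[i]]
    if (length(v)) score[i] <- max(v)
  }
  scored <- !is.na(score)
  if (!any(scored)) stop("no gene contains a scored focal SNP")
  out <- data.frame(gene_id = genes$gene_id[scored], score = score[scored],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Classify in-gene SNPs as intronic, synonymous or nonsynonymous
#'
#' SNPs outside every CDS segment are intronic. For CDS SNPs the reference
#' codon and the alternate-substituted codon are translated with the
#' standard nuclear code (reverse-complementing on the minus strand) and
#' compared. SNP reference alleles are checked against the reference
#' sequence; mismatches are an error.
#'
#' @param gene one row of a gene table whose [read_genes()] `cds` attribute
#'   (or the `cds` argument) has segments for this gene.
#' @param gm a [genotype_matrix()].
#' @param reference a named [Biostrings::DNAStringSet] (names =
#'   chromosomes, full chromosome sequences) or a file path to a FASTA.
#' @param cds optional data.frame (`gene_id`, `start`, `end`) overriding
#'   the gene table's attribute.
#' @return data.frame per in-gene SNP: `pos`, `ref`, `alt`, `effect`,
#'   `codon_number`, `ref_aa`, `alt_aa` (codon fields NA for intronic).
#' @export
coding_effect_report <- function(gene, gm, reference, cds = NULL) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
  }
  if (is.null(cds)) cds <- attr(gene, "cds")
  cds <- cds[cds$gene_id == gene$gene_id, , drop = FALSE]
  cds <- cds[order(cds$start), , drop = FALSE]
  if (nrow(cds) == 0L) stop("gene ", gene$gene_id, " has no CDS segments")
  cds_len <- sum(cds$end - cds$start + 1L)
  if (cds_len %% 3L != 0L) {
    stop("CDS length of ", gene$gene_id, " is not a multiple of 3")
  }
  if (!gene$chrom %in% names(reference)) {
    stop("reference has no sequence for chromosome ", gene$chrom)
  }
  chrom_chars <- strsplit(as.character(reference[[gene$chrom]]), "")[[1]]
  if (length(chrom_chars) < gene$end) {
    stop("reference sequence does not cover gene ", gene$gene_id)
  }

  in_gene <- which(gm$sites$chrom == gene$chrom &
                   gm$sites$pos >= gene$start & gm$sites$pos <= gene$end)
  if (length(in_gene) == 0L) {
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), effect = character(0),
                      codon_number = integer(0), ref_aa = character(0),
                      alt_aa = character(0)))
  }

  ## genomic position of each CDS base, 5'->3' in coding orientation
  cds_pos <- unlist(lapply(seq_len(nrow(cds)), function(i)
    cds$start[i]:cds$end[i]))
  minus <- gene$strand == "-"
  if (minus) cds_pos <- rev(cds_pos)
  cds_seq <- chrom_chars[cds_pos]        # bases in coding order
  if (minus) cds_seq <- chartr("ACGTacgt", "TGCAtgca", cds_seq)

  translate1 <- function(codon) {
    as.character(Biostrings::translate(Biostrings::DNAString(codon)))
  }
  rows <- lapply(in_gene, function(si) {
    p <- gm$sites$pos[si]
    ref_al <- gm$sites$ref[si]; alt_al <- gm$sites$alt[si]
    ref_base <- chrom_chars[p]
    if (ref_base != ref_al) {
      stop(sprintf("ref allele %s at %s:%d does not match reference base %s",
                   ref_al, gene$chrom, p, ref_base))
    }
    ci <- match(p, cds_pos)
    if (is.na(ci)) {
      return(data.frame(pos = p, ref = ref_al, alt = alt_al,
                        effect = "intronic", codon_number = NA_integer_,
                        ref_aa = NA_character_, alt_aa = NA_character_,
                        stringsAsFactors = FALSE))
    }
    codon_number <- (ci - 1L) %/% 3L + 1L
    off <- (ci - 1L) %% 3L
    codon <- cds_seq[(codon_number - 1L) * 3L + 1:3]
    alt_coding <- if (minus) chartr("ACGTacgt", "TGCAtgca", alt_al) else alt_al
    alt_codon <- codon
    alt_codon[off + 1L] <- alt_coding
    ref_aa <- translate1(paste(codon, collapse = ""))
    alt_aa <- translate1(paste(alt_codon, collapse = ""))
    data.frame(pos = p, ref = ref_al, alt = alt_al,
               effect = if (ref_aa == alt_aa) "synonymous" else "nonsynonymous",
               codon_number = codon_number, ref_aa = ref_aa, alt_aa = alt_aa,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
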