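test_that("BED genes are read into 1-based inclusive coordinates", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t999\t2000\tgeneA", bed)
  g <- read_genes(bed)
  expect_equal(g$gene_id, "geneA")
  expect_equal(g$start, 1000L)
  expect_equal(g$end, 2000L)
})

test_that("GFF3 fixtures round-trip through write_gene_gff3/read_genes", {
  genes <- make_gene_fixture(8, 200000L, seed = 3)
  cds <- data.frame(gene_id = genes$gene_id[1],
                    start = genes$start[1] + c(0L, 300L),
                    end = genes$start[1] + c(149L, 449L))
  path <- tempfile(fileext = ".gff3")
  write_gene_gff3(genes, path, cds = cds)
  back <- read_genes(path)
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$strand, genes$strand)
  got_cds <- attr(back, "cds")
  expect_equal(got_cds$start, cds$start)
  expect_equal(got_cds$end, cds$end)
})

test_that("nearest_gene distances: inside is 0, outside is boundary distance", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      start = c(10000L, 50000L), end = c(20000L, 60000L),
                      strand = "+")
  cand <- data.frame(chrom = "chr1", pos = c(15000L, 35000L, 75000L))
  ann <- nearest_gene(cand, genes)
  expect_equal(ann$gene_distance, c(0, 15000, 15000))
  expect_equal(ann$gene_id, c("gA", "gA", "gB"))
  # no gene on the chromosome
  off <- nearest_gene(data.frame(chrom = "chrX", pos = 1L), genes)
  expect_true(is.infinite(off$gene_distance))
  # tie at equal distance resolved by smaller gene start
  tie <- nearest_gene(data.frame(chrom = "chr1", pos = 35000L), genes)
  expect_equal(tie$gene_id, "gA")
})

test_that("nearest_gene equals exhaustive search on random instances", {
  genes <- make_gene_fixture(30, 500000L, seed = 17)
  set.seed(18)
  cand <- data.frame(chrom = "chr1", pos = sample.int(500000L, 50))
  ann <- nearest_gene(cand, genes)
  for (i in seq_len(50)) {
    ref <- naive_nearest("chr1", cand$pos[i], genes)
    expect_equal(ann$gene_id[i], ref$gene_id)
    expect_equal(ann$gene_distance[i], ref$dist)
  }
})

test_that("gene-distance filter is inclusive at the cutoff", {
  genes <- data.frame(gene_id = "g", chrom = "chr1", start = 100000L,
                      end = 110000L, strand = "+")
  cand <- data.frame(chrom = "chr1", pos = c(80000L, 79999L, 105000L))
  kept <- filter_by_gene_distance(cand, genes, max_distance = 20000)
  expect_equal(kept$pos, c(80000L, 105000L))  # 20000 in, 20001 out
  expect_equal(kept$gene_distance, c(20000, 0))
})

test_that("a constructed fixture keeps exactly the near-gene candidates", {
  genes <- spread_genes(5, gap = 200000L)  # genes at 10k, 210k, ...
  pos <- c(genes$start[1:4] + 1000L,        # 4 inside genes
           genes$start[1:4] + 90000L,      # 4 far from any gene
           genes$end[5] + 300000L)         # 1 more distant locus
  cand <- data.frame(chrom = "chr1", pos = pos)
  kept <- filter_by_gene_distance(cand, genes, max_distance = 20000)
  expect_equal(nrow(kept), 4L)
  expect_true(all(kept$gene_distance == 0))
})

test_that("distance null test is deterministic and flags gene deserts", {
  genes <- spread_genes(12, gap = 40000L)  # genes cover 10k..450k
  set.seed(1)
  pos <- sort(sample.int(900000L, 4000))
  tr <- score_track("chr1", pos, rnorm(4000), "test")
  # candidates forced into the gene desert beyond 500 kb
  desert <- tr$pos[tr$pos > 600000]
  cand <- data.frame(chrom = "chr1",
                     pos = desert[seq(1, length(desert), length.out = 12)])
  res <- distance_null_test(cand, genes, tr, n_permutations = 100,
                            mask_radius_bp = 10000, seed = 7)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$observed_median, res$null_median)
  res2 <- distance_null_test(cand, genes, tr, n_permutations = 100,
                             mask_radius_bp = 10000, seed = 7)
  expect_identical(res$p_value, res2$p_value)
  expect_error(distance_null_test(cand, genes, tr, n_permutations = 10),
               "n_permutations")
})

test_that("distance null p-values are roughly uniform under the null", {
  genes <- spread_genes(10, gap = 60000L)
  set.seed(2)
  tr <- score_track("chr1", sort(sample.int(600000L, 3000)), rnorm(3000), "t")
  ps <- vapply(1:12, function(s) {
    set.seed(1000 + s)
    draw <- .subset2(tr, "pos")[sample(nrow(tr), 10)]
    cand <- data.frame(chrom = "chr1", pos = draw)
    distance_null_test(cand, genes, tr, n_permutations = 100,
                       mask_radius_bp = 1, seed = s)$p_value
  }, numeric(1))
  # calibration: not systematically tiny, spread over (0, 1)
  expect_gt(mean(ps > 0.05), 0.5)
  expect_gt(stats::sd(ps), 0.05)
})

test_that("gene_scores takes the in-gene maximum and ranks genes", {
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                      start = c(100L, 1000L, 5000L),
                      end = c(500L, 2000L, 6000L), strand = "+")
  tr <- score_track("chr1", c(150, 300, 450, 1200, 1800),
                    c(0.2, 0.9, 0.4, 0.5, 0.3), "G12")
  gs <- gene_scores(tr, genes)
  expect_equal(gs$gene_id, c("gA", "gB"))   # gC has no focal SNP
  expect_equal(gs$score, c(0.9, 0.5))
  expect_equal(gs$rank, c(1L, 2L))
})

test_that("gene_scores recovers a planted ranking", {
  genes <- spread_genes(20, gap = 50000L)
  set.seed(5)
  planted <- sample(seq(0.05, 1, length.out = 20))
  pts <- do.call(rbind, lapply(seq_len(20), function(i) {
    data.frame(pos = genes$start[i] + c(200L, 700L, 1500L),
               score = c(planted[i] / 2, planted[i], planted[i] / 3))
  }))
  tr <- score_track("chr1", pts$pos, pts$score, "G12")
  gs <- gene_scores(tr, genes)
  expect_equal(nrow(gs), 20L)
  expect_equal(gs$gene_id[1], genes$gene_id[which.max(planted)])
  expect_equal(sort(gs$rank), 1:20)
  expect_equal(gs$score[match(genes$gene_id, gs$gene_id)], planted)
})

# coding-effect fixture: two genes carrying the same 6-codon CDS, one on
# each strand, with planted synonymous/nonsynonymous/intronic SNPs
coding_fixture <- function() {
  seq <- rep("A", 100)
  seq[11:19] <- strsplit("ATGCACGGT", "")[[1]]   # CDS1 (+): M H G
  seq[31:39] <- strsplit("GATTACTAA", "")[[1]]   # CDS2 (+): D Y *
  # minus-strand copy: reverse-complement segments, swapped order
  seq[71:79] <- rev(chartr("ACGT", "TGCA", strsplit("ATGCACGGT", "")[[1]]))
  seq[51:59] <- rev(chartr("ACGT", "TGCA", strsplit("GATTACTAA", "")[[1]]))
  ref <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
  names(ref) <- "chr1"
  genes <- data.frame(gene_id = c("plus", "minus"), chrom = "chr1",
                      start = c(11L, 51L), end = c(39L, 79L),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  cds <- data.frame(gene_id = c("plus", "plus", "minus", "minus"),
                    start = c(11L, 31L, 51L, 71L),
                    end = c(19L, 39L, 59L, 79L))
  list(ref = ref, genes = genes, cds = cds, chars = seq)
}

test_that("coding effects: synonymous, nonsynonymous and intronic SNPs", {
  fx <- coding_fixture()
  sites <- data.frame(chrom = "chr1", pos = c(14L, 16L, 25L, 33L),
                      ref = fx$chars[c(14, 16, 25, 33)],
                      alt = c("G", "T", "G", "C"))
  gm <- genotype_matrix(matrix(1L, nrow = 2, ncol = 4), sites, c("a", "b"))
  rep_plus <- coding_effect_report(fx$genes[1, ], gm, fx$ref, cds = fx$cds)
  expect_equal(rep_plus$effect,
               c("nonsynonymous", "synonymous", "intronic", "synonymous"))
  # CAC (His) -> CAT stays histidine; codon number is 2
  expect_equal(rep_plus$codon_number[2], 2L)
  expect_equal(rep_plus$ref_aa[2], "H")
  expect_equal(rep_plus$alt_aa[2], "H")
  # GAT -> GAC stays aspartate in codon 4
  expect_equal(rep_plus$codon_number[4], 4L)
  expect_equal(rep_plus$ref_aa[4], "D")
})

test_that("minus-strand classification equals the plus-strand construction", {
  fx <- coding_fixture()
  # genomic pos 76 is coding position 4 (codon 2 base 1) on the minus gene;
  # pos 74 is coding position 6 (codon 2 base 3)
  sites <- data.frame(chrom = "chr1", pos = c(74L, 76L),
                      ref = fx$chars[c(74, 76)], alt = c("A", "C"))
  gm <- genotype_matrix(matrix(1L, nrow = 2, ncol = 2), sites, c("a", "b"))
  rep_minus <- coding_effect_report(fx$genes[2, ], gm, fx$ref, cds = fx$cds)
  expect_equal(rep_minus$effect[rep_minus$pos == 74],  "synonymous")
  expect_equal(rep_minus$effect[rep_minus$pos == 76],  "nonsynonymous")
  expect_equal(rep_minus$codon_number, c(2L, 2L))
  expect_equal(rep_minus$ref_aa, c("H", "H"))
})

test_that("reference mismatches and broken frames are errors", {
  fx <- coding_fixture()
  sites <- data.frame(chrom = "chr1", pos = 14L, ref = "T", alt = "G")
  gm <- genotype_matrix(matrix(1L, nrow = 1, ncol = 1), sites, "a")
  expect_error(coding_effect_report(fx$genes[1, ], gm, fx$ref, cds = fx$cds),
               "does not match")
  bad_cds <- fx$cds
  bad_cds$end[1] <- 18L  # CDS length no longer divisible by 3
  expect_error(coding_effect_report(fx$genes[1, ], gm, fx$ref, cds = bad_cds),
               "multiple of 3")
})
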