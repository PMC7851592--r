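#' Simulation configuration for founder-mosaic genotype cohorts
#'
#' The generator builds each haplotype as a copying mosaic over a small
#' founder pool: starting from a uniformly chosen founder, it switches to a
#' uniformly chosen founder with probability `switch_probability` at each
#' successive SNP. This yields realistic linkage-block structure at desk
#' scale without a coalescent simulator. Per-SNP founder allele frequencies
#' follow a Beta law truncated so every SNP is polymorphic in the founder
#' pool; inter-SNP spacing is exponential with mean `mean_spacing_bp`, so
#' the default 201-SNP scan window spans about 29 kb.
#'
#' @param n_individuals diploid sample size (default 29).
#' @param n_snps SNPs per chromosome (default 10000).
#' @param n_chromosomes chromosome count (default 1).
#' @param n_founders founder-haplotype pool size K (default 40).
#' @param switch_probability per-SNP founder-switch rate (default 0.02).
#' @param beta_shape1,beta_shape2 Beta law for founder allele frequencies
#'   (default 0.5, 0.5).
#' @param mean_spacing_bp mean inter-SNP distance in bp (default 144).
#' @param sweeps list of [sweep_spec()] entries injected after the neutral
#'   mosaic is built.
#' @param two_pop optional `list(n_individuals_b =, drift =)`: simulate a
#'   second cohort from the same founder pool with founder-choice weights
#'   redrawn under a Dirichlet-style drift parameter (gamma weights with
#'   variance `drift`; `drift = 0` gives identical weight laws).
#' @param seed RNG seed; (config, seed) fully determines the cohort.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_individuals = 29L, n_snps = 10000L,
                       n_chromosomes = 1L, n_founders = 40L,
                       switch_probability = 0.02,
                       beta_shape1 = 0.5, beta_shape2 = 0.5,
                       mean_spacing_bp = 144, sweeps = list(),
                       two_pop = NULL, seed = 1L) {
  stopifnot(n_individuals >= 1, n_snps >= 1, n_chromosomes >= 1,
            n_founders >= 1, switch_probability >= 0, switch_probability <= 1,
            mean_spacing_bp > 0)
  if (!is.null(two_pop)) {
    stopifnot(is.list(two_pop), two_pop$n_individuals_b >= 1,
              two_pop$drift >= 0)
  }
  structure(list(
    n_individuals = as.integer(n_individuals), n_snps = as.integer(n_snps),
    n_chromosomes = as.integer(n_chromosomes),
    n_founders = as.integer(n_founders),
    switch_probability = switch_probability,
    beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
    mean_spacing_bp = mean_spacing_bp, sweeps = sweeps, two_pop = two_pop,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Sweep specification
#'
#' A sweep replaces the states of the selected carrier haplotypes across a
#' SNP span with one of `n_sweep_haplotypes` novel founder segments:
#' 1 segment emulates a hard sweep (one long frequent haplotype), 2 or more
#' a soft sweep. Carrier haplotypes are assigned individual-first (both
#' haplotypes of a carrier individual take the same segment), so carrier
#' individuals share a multisite genotype across the span.
#'
#' @param chrom chromosome name (default `"chr1"`).
#' @param center_pos sweep centre in bp (matched to the nearest SNP).
#' @param span_snps sweep span in SNPs.
#' @param carrier_frequency fraction of haplotypes carrying the sweep,
#'   in (0, 1].
#' @param n_sweep_haplotypes number of distinct sweeping segments
#'   (default 1 = hard).
#' @param pop `"A"`, `"B"` or `"both"` for two-population cohorts
#'   (default `"A"`).
#' @return a `sweep_spec` list.
#' @export
sweep_spec <- function(chrom = "chr1", center_pos, span_snps,
                       carrier_frequency, n_sweep_haplotypes = 1L,
                       pop = "A") {
  stopifnot(carrier_frequency > 0, carrier_frequency <= 1,
            n_sweep_haplotypes >= 1, span_snps >= 1,
            pop %in% c("A", "B", "both"))
  list(chrom = chrom, center_pos = center_pos,
       span_snps = as.integer(span_snps),
       carrier_frequency = carrier_frequency,
       n_sweep_haplotypes = as.integer(n_sweep_haplotypes), pop = pop)
}

## founder alleles (K x L), polymorphic in the pool at every SNP
.draw_founders <- function(K, L, shape1, shape2) {
  f <- stats::rbeta(L, shape1, shape2)
  founders <- matrix(stats::rbinom(K * L, 1L, rep(f, each = K)), nrow = K)
  mono <- which(colSums(founders) %in% c(0L, K))
  for (j in mono) {
    i <- sample.int(K, 1L)
    founders[i, j] <- 1L - founders[i, j]
  }
  founders
}

## one mosaic haplotype over founders (K x L) with switch prob sp
.copy_mosaic <- function(founders, sp, weights) {
  K <- nrow(founders); L <- ncol(founders)
  s <- c(TRUE, stats::runif(L - 1L) < sp)
  seg <- cumsum(s)
  fps <- sample.int(K, seg[L], replace = TRUE, prob = weights)
  founders[cbind(fps[seg], seq_len(L))]
}

.mosaic_pop <- function(founders_by_chrom, n_ind, sp, weights) {
  lapply(founders_by_chrom, function(fd) {
    haps <- matrix(0L, nrow = 2L * n_ind, ncol = ncol(fd))
    for (h in seq_len(2L * n_ind)) haps[h, ] <- .copy_mosaic(fd, sp, weights)
    haps
  })
}

.haps_to_matrix <- function(haps_by_chrom, sites_by_chrom, prefix) {
  calls <- do.call(cbind, lapply(haps_by_chrom, function(h) {
    odd <- seq(1L, nrow(h), by = 2L)
    h[odd, , drop = FALSE] + h[odd + 1L, , drop = FALSE]
  }))
  sites <- do.call(rbind, sites_by_chrom)
  n_ind <- nrow(calls)
  genotype_matrix(calls, sites, sprintf("%s%02d", prefix, seq_len(n_ind)))
}

#' Simulate a neutral founder-mosaic cohort
#'
#' Builds the neutral cohort(s) described by `config`, ignoring its
#' `sweeps` (use [inject_sweep()] or [simulate_cohort()] for sweeps).
#' Returns a `sim_cohort` carrying the genotype matrix (or two, for
#' two-population configs), the underlying haplotypes (needed for sweep
#' injection), an empty truth table, and the config.
#'
#' @param config a [sim_config()].
#' @return a `sim_cohort` list: `matrix_a`, `matrix_b` (or `NULL`),
#'   `haplotypes_a`, `haplotypes_b`, `sites` (per-chromosome list),
#'   `truth` (data.frame of injected sweeps), `config`.
#' @export
simulate_neutral <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  founders <- list(); sites <- list()
  for (ch in chroms) {
    fd <- .draw_founders(config$n_founders, config$n_snps,
                         config$beta_shape1, config$beta_shape2)
    gaps <- pmax(1, round(stats::rexp(config$n_snps,
                                      1 / config$mean_spacing_bp)))
    pos <- cumsum(gaps)
    founders[[ch]] <- fd
    sites[[ch]] <- data.frame(chrom = ch, pos = as.integer(pos),
                              ref = "A", alt = "G",
                              stringsAsFactors = FALSE)
  }
  K <- config$n_founders
  if (is.null(config$two_pop)) {
    w <- rep(1 / K, K)
    haps_a <- .mosaic_pop(founders, config$n_individuals,
                          config$switch_probability, w)
    haps_b <- NULL
  } else {
    drift <- config$two_pop$drift
    draw_w <- function() {
      if (drift == 0) return(rep(1 / K, K))
      w <- stats::rgamma(K, shape = 1 / drift, rate = 1 / drift)
      w / sum(w)
    }
    w_a <- draw_w(); w_b <- draw_w()
    haps_a <- .mosaic_pop(founders, config$n_individuals,
                          config$switch_probability, w_a)
    haps_b <- .mosaic_pop(founders, config$two_pop$n_individuals_b,
                          config$switch_probability, w_b)
  }
  cohort <- structure(list(
    matrix_a = .haps_to_matrix(haps_a, sites, "A"),
    matrix_b = if (is.null(haps_b)) NULL else
      .haps_to_matrix(haps_b, sites, "B"),
    haplotypes_a = haps_a, haplotypes_b = haps_b, sites = sites,
    truth = data.frame(
      pop = character(0), chrom = character(0), center_pos = integer(0),
      start_pos = integer(0), end_pos = integer(0), span_snps = integer(0),
      carrier_frequency = numeric(0), n_sweep_haplotypes = integer(0),
      stringsAsFactors = FALSE
    ),
    config = config
  ), class = "sim_cohort")
  cohort
}

## apply a sweep's segment replacement to one population's haplotypes
.apply_sweep_to_pop <- function(haps, span_idx, segments, carrier_frequency) {
  n_hap <- nrow(haps)
  n_carr <- ceiling(carrier_frequency * n_hap)
  if (n_carr < nrow(segments)) {
    stop("carrier_frequency * 2n must be >= n_sweep_haplotypes")
  }
  n_ind <- n_hap / 2L
  ind <- sample.int(n_ind, ceiling(n_carr / 2))
  hap_idx <- as.vector(rbind(2L * ind - 1L, 2L * ind))[seq_len(n_carr)]
  seg_of <- rep(seq_len(nrow(segments)), length.out = length(ind))
  for (k in seq_along(ind)) {
    rows <- intersect(c(2L * ind[k] - 1L, 2L * ind[k]), hap_idx)
    haps[rows, span_idx] <-
      matrix(segments[seg_of[k], ], nrow = length(rows), ncol = length(span_idx),
             byrow = TRUE)
  }
  haps
}

#' Inject a hard or soft sweep into a simulated cohort
#'
#' Draws `n_sweep_haplotypes` novel segments and overwrites the selected
#' carrier haplotypes across the span, then rebuilds the genotype matrices
#' and records the sweep in the truth table. For `pop = "both"` the same
#' segments are planted in both cohorts (a shared, pre-split sweep);
#' otherwise the sweep is population-private (post-split).
#'
#' @param cohort a `sim_cohort` from [simulate_neutral()].
#' @param spec a [sweep_spec()].
#' @return the updated `sim_cohort`.
#' @export
inject_sweep <- function(cohort, spec) {
  stopifnot(inherits(cohort, "sim_cohort"))
  sites <- cohort$sites[[spec$chrom]]
  if (is.null(sites)) stop("no such chromosome: ", spec$chrom)
  L <- nrow(sites)
  center <- which.min(abs(sites$pos - spec$center_pos))
  half <- (spec$span_snps - 1L) %/% 2L
  lo <- center - half
  hi <- lo + spec$span_snps - 1L
  if (lo < 1L || hi > L) stop("sweep span exceeds chromosome")
  span_idx <- lo:hi
  segments <- matrix(stats::rbinom(spec$n_sweep_haplotypes * length(span_idx),
                                   1L, 0.5),
                     nrow = spec$n_sweep_haplotypes)
  pops <- if (spec$pop == "both") c("A", "B") else spec$pop
  for (p in pops) {
    slot <- if (p == "A") "haplotypes_a" else "haplotypes_b"
    if (is.null(cohort[[slot]])) stop("cohort has no population ", p)
    cohort[[slot]][[spec$chrom]] <- .apply_sweep_to_pop(
      cohort[[slot]][[spec$chrom]], span_idx, segments,
      spec$carrier_frequency)
  }
  cohort$matrix_a <- .haps_to_matrix(cohort$haplotypes_a, cohort$sites, "A")
  if (!is.null(cohort$haplotypes_b)) {
    cohort$matrix_b <- .haps_to_matrix(cohort$haplotypes_b, cohort$sites, "B")
  }
  cohort$truth <- rbind(cohort$truth, data.frame(
    pop = spec$pop, chrom = spec$chrom,
    center_pos = sites$pos[center],
    start_pos = sites$pos[lo], end_pos = sites$pos[hi],
    span_snps = spec$span_snps,
    carrier_frequency = spec$carrier_frequency,
    n_sweep_haplotypes = spec$n_sweep_haplotypes,
    stringsAsFactors = FALSE
  ))
  cohort
}

#' Simulate a cohort with its configured sweeps
#'
#' [simulate_neutral()] followed by [inject_sweep()] for every entry of
#' `config$sweeps`, all under the single seed, so regeneration from
#' (config, seed) is bit-identical.
#'
#' @param config a [sim_config()].
#' @return a `sim_cohort`.
#' @export
simulate_cohort <- function(config) {
  cohort <- simulate_neutral(config)
  for (spec in config$sweeps) cohort <- inject_sweep(cohort, spec)
  cohort
}

#' Simulate a two-population cohort
#'
#' Requires `config$two_pop`; otherwise identical to [simulate_cohort()].
#'
#' @param config a [sim_config()] with `two_pop` set.
#' @return a `sim_cohort` with `matrix_a` and `matrix_b`.
#' @export
simulate_two_pops <- function(config) {
  if (is.null(config$two_pop)) stop("config$two_pop is not set")
  simulate_cohort(config)
}

#' Write a genotype matrix as a minimal GT-only VCF
#'
#' Plain-text VCFv4.2 with CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO/FORMAT
#' columns and unphased GT calls (`0/0`, `0/1`, `1/1`, `./.`).
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_strings <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=sweepscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  ), con)
  codes <- gm$calls
  for (j in seq_len(n_sites(gm))) {
    g <- ifelse(is.na(codes[, j]), "./.", gt_strings[codes[, j] + 1L])
    writeLines(paste(c(gm$sites$chrom[j], gm$sites$pos[j], ".",
                       gm$sites$ref[j], gm$sites$alt[j], ".", "PASS", ".",
                       "GT", g), collapse = "\t"), con)
  }
  invisible(path)
}

#' Generate a gene-annotation fixture
#'
#' Random non-overlapping gene intervals along one chromosome, optionally
#' with a tight cluster of paralog-like genes (to exercise enrichment
#' masking) and a random reference sequence. Deterministic given `seed`.
#' The returned reference is synthetic (random bases).
#'
#' @param n_genes number of scattered genes.
#' @param genome_bp chromosome length in bp.
#' @param chrom chromosome name (default `"chr1"`).
#' @param gene_bp gene length range (default `c(2000, 6000)`).
#' @param cluster optional `list(n =, width =)`: additionally place `n`
#'   genes inside a `width`-bp region (ids `clustA`, `clustB`, ...).
#' @param with_reference also build a random reference sequence
#'   (default `FALSE`).
#' @param seed RNG seed.
#' @return gene table as from [read_genes()] (empty `cds` attribute);
#'   if `with_reference`, the reference is attached as attribute
#'   `reference` (a [Biostrings::DNAStringSet]).
#' @export
make_gene_fixture <- function(n_genes, genome_bp, chrom = "chr1",
                              gene_bp = c(2000L, 6000L), cluster = NULL,
                              with_reference = FALSE, seed = 1L) {
  set.seed(as.integer(seed))
  starts <- sort(sample.int(max(1L, genome_bp - gene_bp[2]), n_genes))
  lens <- sample(gene_bp[1]:gene_bp[2], n_genes, replace = TRUE)
  ends <- pmin(starts + lens, genome_bp)
  genes <- data.frame(
    gene_id = sprintf("gene%03d", seq_len(n_genes)),
    chrom = chrom, start = starts, end = ends,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )
  if (!is.null(cluster)) {
    anchor <- sample.int(max(1L, genome_bp - cluster$width), 1L)
    cl_starts <- sort(anchor +
                        sample.int(cluster$width - 1000L, cluster$n))
    cl <- data.frame(
      gene_id = paste0("clust", LETTERS[seq_len(cluster$n)]),
      chrom = chrom, start = cl_starts,
      end = cl_starts + 800L,
      strand = "+", stringsAsFactors = FALSE
    )
    genes <- rbind(genes, cl)
  }
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  attr(genes, "cds") <- data.frame(gene_id = character(0),
                                   start = integer(0), end = integer(0))
  if (with_reference) {
    seq <- paste(sample(c("A", "C", "G", "T"), genome_bp, replace = TRUE),
                 collapse = "")
    ref <- Biostrings::DNAStringSet(seq)
    names(ref) <- chrom
    attr(genes, "reference") <- ref
  }
  genes
}

#' Write a gene table as BED
#'
#' 0-based half-open coordinates, name column = gene id.
#'
#' @param genes gene table.
#' @param path output file.
#' @export
write_gene_bed <- function(genes, path) {
  bed <- data.frame(chrom = genes$chrom, start = genes$start - 1L,
                    end = genes$end, name = genes$gene_id,
                    score = 0L, strand = genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a gene table (with CDS segments) as GFF3
#'
#' @param genes gene table; CDS segments taken from its `cds` attribute or
#'   the `cds` argument.
#' @param path output file.
#' @param cds optional data.frame (`gene_id`, `start`, `end`).
#' @export
write_gene_gff3 <- function(genes, path, cds = NULL) {
  if (is.null(cds)) cds <- attr(genes, "cds")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    writeLines(paste(genes$chrom[i], "sweepscan", "gene", genes$start[i],
                     genes$end[i], ".", genes$strand[i], ".",
                     paste0("ID=", genes$gene_id[i]), sep = "\t"), con)
    if (!is.null(cds) && nrow(cds)) {
      seg <- cds[cds$gene_id == genes$gene_id[i], , drop = FALSE]
      for (k in seq_len(nrow(seg))) {
        writeLines(paste(genes$chrom[i], "sweepscan", "CDS", seg$start[k],
                         seg$end[k], ".", genes$strand[i], "0",
                         paste0("ID=", genes$gene_id[i], ".cds", k,
                                ";Parent=", genes$gene_id[i]), sep = "\t"),
                   con)
      }
    }
  }
  invisible(path)
}

#' Generate a gene-to-category fixture
#'
#' Random category memberships over the supplied genes; `forced` plants
#' specific memberships (e.g. a category shared by clustered paralogs).
#'
#' @param genes gene table.
#' @param n_categories number of random categories.
#' @param genes_per_category size of each random category (scalar or
#'   range `c(min, max)`).
#' @param forced optional named list `category_id -> gene_id vector`.
#' @param seed RNG seed.
#' @return data.frame `gene_id`, `category_id`.
#' @export
make_category_fixture <- function(genes, n_categories,
                                  genes_per_category = 3L, forced = NULL,
                                  seed = 1L) {
  set.seed(as.integer(seed))
  if (length(genes_per_category) == 1L) {
    genes_per_category <- rep(genes_per_category, 2L)
  }
  out <- lapply(seq_len(n_categories), function(k) {
    sz <- sample(genes_per_category[1]:genes_per_category[2], 1L)
    data.frame(gene_id = sample(genes$gene_id, min(sz, nrow(genes))),
               category_id = sprintf("CAT%03d", k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(forced)) {
    for (cid in names(forced)) {
      out <- rbind(out, data.frame(gene_id = forced[[cid]],
                                   category_id = cid,
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  unique(out)
}

#' Write a category map as TSV
#'
#' @param categories data.frame `gene_id`, `category_id`.
#' @param path output file.
#' @export
write_category_tsv <- function(categories, path) {
  utils::write.table(categories[, c("gene_id", "category_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
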