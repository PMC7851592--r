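#' Pipeline configuration
#'
#' All scan, calling, annotation, enrichment and comparison parameters with
#' their standard defaults, plus the master seed. The config is serialized
#' verbatim into the run manifest for provenance.
#'
#' @param window_snps G12 window (default 201).
#' @param fst_window_bp,fst_step_bp Fst window span and step
#'   (default 10000 / 1000).
#' @param fst_min_snps minimum defined SNPs per Fst window (default 5).
#' @param top_k candidates per statistic (default 100).
#' @param mask_radius_bp candidate masking radius (default 100000).
#' @param max_gene_distance_bp candidate-to-gene cutoff (default 20000).
#' @param r_max,min_genes,mask_kb enrichment walk parameters
#'   (default 50 / 3 / 30).
#' @param n_permutations permutations for the enrichment FDR
#'   (default 100).
#' @param alpha cross-population "elevated" tail (default 0.05).
#' @param seed master seed; per-stage seeds are derived from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(window_snps = 201L, fst_window_bp = 10000L,
                            fst_step_bp = 1000L, fst_min_snps = 5L,
                            top_k = 100L, mask_radius_bp = 100000L,
                            max_gene_distance_bp = 20000L, r_max = 50L,
                            min_genes = 3L, mask_kb = 30L,
                            n_permutations = 100L, alpha = 0.05,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

## deterministic per-stage child seed (stable under stage reordering)
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Run the full sweep-scan pipeline
#'
#' genotype load, G12 and H scans, Fst (when a second cohort is given),
#' outlier calling per statistic, gene annotation and distance filtering,
#' GO enrichment with permutation FDR, and cross-population comparison.
#' All tabular outputs are written as TSV under `out_dir` together with a
#' JSON manifest (parameters, seed, input checksums, per-stage row
#' counts). Outputs are byte-identical across reruns with the same inputs,
#' config and seed.
#'
#' @param vcf_a VCF of the focal cohort.
#' @param genes_path BED or GFF3 gene annotation.
#' @param categories_path TSV gene-to-category map.
#' @param out_dir output directory (created if absent).
#' @param vcf_b optional VCF of the comparison cohort; when `NULL` the Fst
#'   and cross-population stages are skipped.
#' @param config a [pipeline_config()].
#' @return invisible list of all stage results plus the manifest.
#' @export
run_full <- function(vcf_a, genes_path, categories_path, out_dir,
                     vcf_b = NULL, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  tick <- function(name) stages <<- c(stages, name)
  outfile <- function(name) file.path(out_dir, name)

  ## genotype_io
  gm_a <- read_vcf(vcf_a)
  gm_b <- if (!is.null(vcf_b)) read_vcf(vcf_b) else NULL
  tick("genotype_io")

  ## sweep_stats
  g12_a <- g12_scan(gm_a, config$window_snps)
  h_a <- h_scan(gm_a)
  write_track_tsv(g12_a, outfile("g12_a.tsv"))
  write_track_tsv(h_a, outfile("h_a.tsv"))
  tick("sweep_stats")

  ## differentiation
  fst_win <- fst_tr <- NULL
  if (!is.null(gm_b)) {
    snp_fst <- wc_fst_per_snp(gm_a, gm_b)
    fst_win <- fst_windows(snp_fst, config$fst_window_bp, config$fst_step_bp,
                           config$fst_min_snps)
    fst_tr <- fst_track(fst_win)
    utils::write.table(snp_fst, outfile("fst_per_snp.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_fst_bed(fst_win, outfile("fst_windows.bed"))
    tick("differentiation")
  }

  ## outliers
  cand <- list(
    G12 = call_top_loci(g12_a, config$top_k, config$mask_radius_bp),
    H = call_top_loci(h_a, config$top_k, config$mask_radius_bp)
  )
  if (!is.null(fst_tr)) {
    cand$Fst <- call_top_loci(fst_tr, config$top_k, config$mask_radius_bp)
  }
  for (nm in names(cand)) {
    write_candidates(cand[[nm]],
                     outfile(sprintf("candidates_%s.tsv", tolower(nm))),
                     outfile(sprintf("candidates_%s.bed", tolower(nm))))
  }
  tick("outliers")

  ## annotation
  genes <- read_genes(genes_path)
  near <- lapply(cand, filter_by_gene_distance, genes = genes,
                 max_distance = config$max_gene_distance_bp)
  for (nm in names(near)) {
    utils::write.table(near[[nm]],
                       outfile(sprintf("candidates_%s_genes.tsv", tolower(nm))),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  gscore <- gene_scores(g12_a, genes)
  utils::write.table(gscore, outfile("gene_scores_g12.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tick("annotation")

  ## enrichment
  categories <- read_category_map(categories_path)
  enr <- go_enrichment(gscore, categories, genes, config$r_max,
                       config$min_genes, config$mask_kb)
  fdr <- enrichment_fdr(gscore, categories, genes, config$r_max,
                        config$min_genes, config$mask_kb,
                        config$n_permutations,
                        stage_seed(config$seed, "enrichment"))
  utils::write.table(enr$discoveries, outfile("enrichment_discoveries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fdr, outfile("enrichment_fdr.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tick("enrichment")

  ## crosspop
  xpop <- NULL
  if (!is.null(gm_b)) {
    h_b <- h_scan(gm_b)
    write_track_tsv(h_b, outfile("h_b.tsv"))
    xpop <- compare_candidates(cand$H, h_b, config$alpha)
    utils::write.table(xpop$comparison, outfile("crosspop_h.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tick("crosspop")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sweepscan")),
    parameters = unclass(config),
    inputs = list(
      vcf_a = unname(tools::md5sum(vcf_a)),
      vcf_b = if (is.null(vcf_b)) NULL else unname(tools::md5sum(vcf_b)),
      genes = unname(tools::md5sum(genes_path)),
      categories = unname(tools::md5sum(categories_path))
    ),
    stages_completed = stages,
    counts = list(
      samples_a = length(gm_a$samples), snps_a = nrow(gm_a$sites),
      samples_b = if (is.null(gm_b)) NULL else length(gm_b$samples),
      candidates = lapply(cand, nrow),
      candidates_near_genes = lapply(near, nrow),
      enrichment_discoveries = nrow(enr$discoveries)
    )
  )
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(matrix_a = gm_a, matrix_b = gm_b, g12 = g12_a, h = h_a,
                 fst_windows = fst_win, candidates = cand,
                 candidates_near_genes = near, gene_scores = gscore,
                 enrichment = enr, fdr = fdr, crosspop = xpop,
                 manifest = manifest))
}
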