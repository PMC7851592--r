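test_that("cohort regeneration from (config, seed) is bit-identical", {
  cfg <- sim_config(n_individuals = 8, n_snps = 500, seed = 101,
                    two_pop = list(n_individuals_b = 4, drift = 0.2),
                    sweeps = list(sweep_spec(center_pos = 40000,
                                             span_snps = 101,
                                             carrier_frequency = 0.5,
                                             pop = "A")))
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$matrix_a$calls, c2$matrix_a$calls)
  expect_identical(c1$matrix_b$calls, c2$matrix_b$calls)
  expect_identical(c1$sites, c2$sites)
  expect_identical(c1$truth, c2$truth)
  c3 <- simulate_cohort(sim_config(n_individuals = 8, n_snps = 500,
                                   seed = 102))
  expect_false(identical(c1$matrix_a$calls, c3$matrix_a$calls))
})

test_that("degenerate limits: one founder vs all-independent founders", {
  one <- simulate_cohort(sim_config(n_individuals = 5, n_snps = 60,
                                    n_founders = 1, switch_probability = 0,
                                    seed = 1))
  expect_true(all(g12_scan(one$matrix_a, 5L)$score == 1))
  expect_true(all(h_scan(one$matrix_a)$score == 60))
  many <- simulate_cohort(sim_config(n_individuals = 10, n_snps = 400,
                                     n_founders = 40,
                                     switch_probability = 0, seed = 2))
  tr <- g12_scan(many$matrix_a, 51L)
  floor_ <- (10 + 2) / 10^2
  expect_lt(median(tr$score), 0.2)
  expect_gte(min(tr$score), floor_ - 1e-12)
})

test_that("default-scale neutral cohorts stay unsaturated", {
  co <- simulate_cohort(sim_config(n_individuals = 29, n_snps = 4000,
                                   seed = 3))
  tr <- g12_scan(co$matrix_a, 201L)
  expect_lt(median(tr$score), 0.2)
  expect_true(all(tr$score < 1))
})

test_that("hard-sweep injection plants a dominant genotype class", {
  cf <- 11 / 29
  cfg <- sim_config(n_individuals = 29, n_snps = 2000, seed = 4,
                    sweeps = list(sweep_spec(center_pos = 140000,
                                             span_snps = 301,
                                             carrier_frequency = cf)))
  co <- simulate_cohort(cfg)
  center_idx <- which(co$matrix_a$sites$pos == co$truth$center_pos)
  w <- window_genotypes(co$matrix_a, center_idx, 201L)
  spec <- genotype_spectrum(w)
  expect_gte(spec[1], 11L)
  expect_equal(co$truth$span_snps, 301L)
  expect_equal(co$truth$n_sweep_haplotypes, 1L)
})

test_that("soft-sweep injection yields several frequent classes", {
  cfg <- sim_config(n_individuals = 24, n_snps = 2000, seed = 5,
                    sweeps = list(sweep_spec(center_pos = 140000,
                                             span_snps = 301,
                                             carrier_frequency = 0.6,
                                             n_sweep_haplotypes = 3)))
  co <- simulate_cohort(cfg)
  center_idx <- which(co$matrix_a$sites$pos == co$truth$center_pos)
  spec <- genotype_spectrum(window_genotypes(co$matrix_a, center_idx, 201L))
  expect_gte(sum(spec >= 3), 3)  # three frequent carrier classes
})

test_that("a singleton carrier is invisible to G12", {
  n <- 10
  base <- sim_config(n_individuals = n, n_snps = 600, seed = 6)
  neutral <- simulate_cohort(base)
  cfg <- sim_config(n_individuals = n, n_snps = 600, seed = 6,
                    sweeps = list(sweep_spec(center_pos = 40000,
                                             span_snps = 101,
                                             carrier_frequency = 1 / (2 * n))))
  co <- simulate_cohort(cfg)
  tr_n <- g12_scan(neutral$matrix_a, 101L)
  tr_s <- g12_scan(co$matrix_a, 101L)
  # one replaced haplotype leaves the class spectrum near-neutral: no new
  # shared class can appear, so scores cannot exceed the neutral run's max
  expect_lte(max(tr_s$score), max(tr_n$score) + 1e-12)
})

test_that("sweep injection validates its span and carrier counts", {
  co <- simulate_cohort(sim_config(n_individuals = 6, n_snps = 200, seed = 7))
  expect_error(inject_sweep(co, sweep_spec(center_pos = 100,
                                           span_snps = 500,
                                           carrier_frequency = 0.5)),
               "span exceeds")
  expect_error(inject_sweep(co, sweep_spec(chrom = "chr9", center_pos = 100,
                                           span_snps = 50,
                                           carrier_frequency = 0.5)),
               "no such chromosome")
  expect_error(inject_sweep(co, sweep_spec(center_pos = 10000,
                                           span_snps = 51,
                                           carrier_frequency = 1 / 12,
                                           n_sweep_haplotypes = 3)),
               "n_sweep_haplotypes")
})

test_that("two-population drift behaves monotonically", {
  base <- function(drift, seed) {
    co <- simulate_cohort(sim_config(n_individuals = 10, n_snps = 800,
                                     seed = seed,
                                     two_pop = list(n_individuals_b = 10,
                                                    drift = drift)))
    mean(wc_fst_per_snp(co$matrix_a, co$matrix_b)$fst, na.rm = TRUE)
  }
  no_drift <- mean(vapply(1:3, function(s) base(0, s), numeric(1)))
  high_drift <- mean(vapply(1:3, function(s) base(2, s), numeric(1)))
  expect_lt(abs(no_drift), 0.05)
  expect_gt(high_drift, no_drift + 0.02)
})

test_that("truth tables record exactly the injected sweeps", {
  cfg <- sim_config(n_individuals = 8, n_snps = 1000, seed = 8,
                    sweeps = list(
                      sweep_spec(center_pos = 30000, span_snps = 101,
                                 carrier_frequency = 0.5),
                      sweep_spec(center_pos = 100000, span_snps = 151,
                                 carrier_frequency = 0.8,
                                 n_sweep_haplotypes = 2)))
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$truth), 2L)
  expect_equal(co$truth$span_snps, c(101L, 151L))
  expect_equal(co$truth$n_sweep_haplotypes, c(1L, 2L))
  expect_true(all(co$truth$start_pos < co$truth$center_pos))
  expect_true(all(co$truth$center_pos < co$truth$end_pos))
})

test_that("gene and category fixtures are deterministic and well formed", {
  g1 <- make_gene_fixture(12, 300000L, cluster = list(n = 3, width = 25000L),
                          seed = 5)
  g2 <- make_gene_fixture(12, 300000L, cluster = list(n = 3, width = 25000L),
                          seed = 5)
  expect_identical(g1, g2)
  cl <- g1[grepl("^clust", g1$gene_id), ]
  expect_equal(nrow(cl), 3L)
  expect_lte(max(cl$end) - min(cl$start), 25000L)
  expect_true(all(g1$start <= g1$end))
  cats1 <- make_category_fixture(g1, 5, c(3, 4), seed = 2)
  cats2 <- make_category_fixture(g1, 5, c(3, 4), seed = 2)
  expect_identical(cats1, cats2)
  expect_true(all(cats1$gene_id %in% g1$gene_id))
})
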