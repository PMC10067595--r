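# The synthetic pooled-sequencing generator: conservation, determinism,
# concentration at high depth, and the written fixture bundle.

test_that("sim_config validates its parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(p_high_core = 1.2), "0, 1")
  expect_error(sim_config(mean_depth = 0), "positive")
  expect_error(sim_config(n_animals = 4, bulk_size = 3), "bulk_size")
  expect_error(sim_config(causal_chrom = 5), "out of range")
})

test_that("base counts are conserved and seeds reproduce bit-identically", {
  cfg <- small_sim_config(seed = 11)
  sim <- simulate_pools(cfg)
  s <- sim$sites
  expect_equal(s$high_A + s$high_C + s$high_G + s$high_T, s$high_depth)
  expect_equal(s$low_A + s$low_C + s$low_G + s$low_T, s$low_depth)
  expect_true(all(s$ref != s$alt))
  expect_true(all(s$pos >= 1))

  sim2 <- simulate_pools(small_sim_config(seed = 11))
  expect_identical(sim$sites, sim2$sites)
  expect_identical(sim$truth$dosage, sim2$truth$dosage)

  sim3 <- simulate_pools(small_sim_config(seed = 12))
  expect_false(identical(sim$sites, sim3$sites))
})

test_that("deep error-free sequencing concentrates at the core frequencies", {
  cfg <- small_sim_config(p_high_core = 1, p_low_core = 0,
                          error_rate = 0, mean_depth = 10000,
                          triallelic_fraction = 0, seed = 3)
  sim <- simulate_pools(cfg)
  i <- sim$truth$causal_marker_row
  s <- sim$sites[i, ]
  alt_col <- paste0(c("high_", "low_"), s$alt)
  high_f <- s[[alt_col[1]]] / s$high_depth
  low_f <- s[[alt_col[2]]] / s$low_depth
  expect_lt(abs(high_f - 1), 0.02)
  expect_lt(abs(low_f - 0), 0.02)
})

test_that("mean causal-core ED does not decrease with pool divergence", {
  core_ed <- function(p_hi, p_lo, seed) {
    cfg <- small_sim_config(p_high_core = p_hi, p_low_core = p_lo,
                            seed = seed)
    sim <- simulate_pools(cfg)
    s <- sim$sites
    core <- s$chrom == sim$truth$causal_chrom &
      abs(s$pos - cfg$causal_center_bp) < cfg$causal_halfwidth_bp / 4 &
      s$high_depth > 0 & s$low_depth > 0
    fr <- pool_frequencies(s[core, ])
    mean(compute_ed(fr$high, fr$low))
  }
  deltas <- rbind(c(0.5, 0.5), c(0.65, 0.35), c(0.85, 0.15))
  means <- sapply(seq_len(nrow(deltas)), function(k)
    mean(sapply(1:5, function(s) core_ed(deltas[k, 1], deltas[k, 2], s))))
  expect_true(all(diff(means) >= 0))
})

test_that("phenotypes follow the additive dosage model", {
  cfg <- small_sim_config(effect_size = 0, trait_noise_sd = 0, seed = 5)
  sim <- simulate_pools(cfg)
  ph <- simulate_phenotypes(cfg, sim$truth)
  expect_true(all(ph$milk_trait == cfg$trait_baseline))

  cfg2 <- small_sim_config(effect_size = 4, trait_baseline = 0.8,
                           trait_noise_sd = 0.1, n_animals = 103, seed = 5)
  sim2 <- simulate_pools(cfg2)
  ph2 <- simulate_phenotypes(cfg2, sim2$truth)
  d <- sim2$truth$dosage
  expect_gt(sum(d == 2), 0)
  diff_obs <- mean(ph2$milk_trait[d == 2]) - mean(ph2$milk_trait[d == 0])
  se <- 0.1 * sqrt(1 / sum(d == 2) + 1 / sum(d == 0))
  expect_lt(abs(diff_obs - 8), 3 * se)

  ph3 <- simulate_phenotypes(cfg2, sim2$truth)
  expect_identical(ph2, ph3)

  bad_truth <- sim2$truth
  bad_truth$dosage <- bad_truth$dosage[1:10]
  expect_error(simulate_phenotypes(cfg2, bad_truth), "dosages")
})

test_that("the fixture bundle is consistent and round-trips", {
  cfg <- small_sim_config(seed = 21, n_snps_per_chrom = 300)
  sim <- simulate_pools(cfg)
  ph <- simulate_phenotypes(cfg, sim$truth)
  out <- file.path(tempdir(), "bundle_test")
  manifest <- write_fixture_bundle(sim$sites, sim$truth, ph, out, cfg)

  # VCF has exactly two sample columns
  hdr <- grep("^#CHROM", readLines(manifest$vcf), value = TRUE)
  expect_length(strsplit(hdr, "\t")[[1]], 11)

  # round-trip: write then parse recovers the counts
  back <- read_pool_vcf(manifest$vcf)
  for (col in c("chrom", "pos", "ref", "alt", "n_alleles",
                paste0("high_", c("A", "C", "G", "T")),
                paste0("low_", c("A", "C", "G", "T")),
                "high_depth", "low_depth")) {
    expect_equal(back[[col]], sim$sites[[col]], info = col)
  }

  # annotation covers every emitted SNP exactly once
  ann <- read_annotation(manifest$annotation)
  expect_equal(nrow(ann), nrow(sim$sites))
  expect_false(any(duplicated(paste(ann$chrom, ann$pos))))

  # the causal gene is in the causal term
  db <- read_gene_sets(manifest$gene_sets)
  expect_true(manifest$causal_gene %in% db$terms$TERM_CAUSAL)

  # genotype table covers all animals at the causal marker
  gt <- read_genotypes(manifest$genotypes)
  causal_gt <- gt[gt$marker_id == manifest$causal_marker, ]
  expect_setequal(causal_gt$animal_id, names(sim$truth$dosage))

  unlink(out, recursive = TRUE)
})
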