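#' Simulation configuration for synthetic pooled-sequencing data
#'
#' Collects every knob of the synthetic BSA-seq world: genome layout, the
#' planted causal locus, pool allele frequencies at the causal core,
#' sequencing depth and error, and the animal-level phenotype model used for
#' marker validation. Defaults describe two 10 Mb chromosomes with 10,000
#' SNPs each, a single causal locus whose pool allele frequencies diverge to
#' 0.85 (high bulk) vs 0.15 (low bulk) at the core with linear linkage decay
#' over 1 Mb, 30X mean pool depth, and a 103-animal cohort from which two
#' 3-animal bulks are drawn.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp chromosome length in bp.
#' @param n_snps_per_chrom SNPs per chromosome.
#' @param causal_chrom index of the chromosome carrying the causal locus.
#' @param causal_center_bp center of the causal locus (bp).
#' @param causal_halfwidth_bp half-width of the causal interval (bp); the
#'   expected pool frequency interpolates linearly from the core value back
#'   to the shared background over this distance.
#' @param p_high_core,p_low_core alternate-allele frequency of the high / low
#'   bulk at the causal core, in `[0, 1]`.
#' @param background_freq_range range of the shared background alternate
#'   allele frequency, drawn Uniform per site.
#' @param mean_depth expected reads per pool per site.
#' @param depth_law depth distribution; only `"poisson"` is implemented.
#' @param error_rate per-base miscall probability; a miscalled read lands
#'   uniformly on one of the three other bases.
#' @param triallelic_fraction fraction of sites given a third allele, solely
#'   to exercise the biallelic filter.
#' @param n_animals number of phenotyped animals.
#' @param bulk_size animals per bulk (`2 * bulk_size <= n_animals`).
#' @param causal_allele_freq population frequency of the causal alternate
#'   allele used to draw per-animal dosages (Hardy-Weinberg).
#' @param trait_baseline baseline trait value (ng/mL) for dosage-0 animals.
#' @param effect_size additive trait shift per causal allele copy (ng/mL).
#' @param trait_noise_sd phenotype noise SD (ng/mL).
#' @param seed integer seed; a fixed seed makes the whole bundle
#'   bit-reproducible.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_chromosomes = 2,
                       chrom_length_bp = 1e7,
                       n_snps_per_chrom = 10000,
                       causal_chrom = 1,
                       causal_center_bp = 5e6,
                       causal_halfwidth_bp = 1e6,
                       p_high_core = 0.85,
                       p_low_core = 0.15,
                       background_freq_range = c(0.2, 0.8),
                       mean_depth = 30,
                       depth_law = "poisson",
                       error_rate = 0.001,
                       triallelic_fraction = 0.01,
                       n_animals = 103,
                       bulk_size = 3,
                       causal_allele_freq = 0.25,
                       trait_baseline = 0.8,
                       effect_size = 4.0,
                       trait_noise_sd = 0.1,
                       seed = 1L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.numeric(chrom_length_bp),
              n_snps_per_chrom = as.integer(n_snps_per_chrom),
              causal_chrom = as.integer(causal_chrom),
              causal_center_bp = as.numeric(causal_center_bp),
              causal_halfwidth_bp = as.numeric(causal_halfwidth_bp),
              p_high_core = p_high_core, p_low_core = p_low_core,
              background_freq_range = background_freq_range,
              mean_depth = mean_depth, depth_law = depth_law,
              error_rate = error_rate,
              triallelic_fraction = triallelic_fraction,
              n_animals = as.integer(n_animals),
              bulk_size = as.integer(bulk_size),
              causal_allele_freq = causal_allele_freq,
              trait_baseline = trait_baseline,
              effect_size = effect_size,
              trait_noise_sd = trait_noise_sd,
              seed = as.integer(seed))
  if (cfg$p_high_core < 0 || cfg$p_high_core > 1 ||
      cfg$p_low_core < 0 || cfg$p_low_core > 1) {
    stop_config("p_high_core and p_low_core must lie in [0, 1]")
  }
  if (cfg$mean_depth <= 0) stop_config("mean_depth must be positive")
  if (cfg$error_rate < 0 || cfg$error_rate > 1) {
    stop_config("error_rate must lie in [0, 1]")
  }
  if (any(c(cfg$n_chromosomes, cfg$n_snps_per_chrom, cfg$chrom_length_bp,
            cfg$n_animals, cfg$bulk_size) <= 0)) {
    stop_config("all counts and lengths must be positive")
  }
  if (2L * cfg$bulk_size > cfg$n_animals) {
    stop_config("need 2 * bulk_size <= n_animals")
  }
  if (cfg$causal_chrom < 1L || cfg$causal_chrom > cfg$n_chromosomes) {
    stop_config("causal_chrom out of range")
  }
  if (!identical(cfg$depth_law, "poisson")) {
    stop_config("depth_law: only 'poisson' is implemented")
  }
  if (cfg$causal_allele_freq < 0 || cfg$causal_allele_freq > 1) {
    stop_config("causal_allele_freq must lie in [0, 1]")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Scatter miscalled reads uniformly over the three non-source bases.
# counts: n x 4 base-count matrix; src: column index of the source base per
# row; n_err: miscalls to move out of src per row. Modifies counts in place.
redistribute_errors <- function(counts, src, n_err) {
  hit <- which(n_err > 0L)
  for (i in hit) {
    others <- setdiff(1:4, src[i])
    spread <- rmultinom(1, n_err[i], rep(1 / 3, 3))[, 1]
    counts[i, src[i]] <- counts[i, src[i]] - n_err[i]
    counts[i, others] <- counts[i, others] + spread
  }
  counts
}

#' Simulate two pooled-sequencing bulks with a planted causal locus
#'
#' Draws per-site read counts for a high-trait and a low-trait pool over a
#' multichromosome SNP panel. Outside the causal interval both pools share
#' one background alternate-allele frequency per site; inside it the
#' expected frequency interpolates linearly from the background to the core
#' values `p_high_core` / `p_low_core` as positions approach the causal
#' center. Per-pool depths are Poisson, alternate reads Binomial, and
#' sequencing errors move reads uniformly onto the other three bases. A
#' small fraction of sites receives a third allele to exercise the biallelic
#' filter downstream.
#'
#' @param config a [sim_config()].
#' @return a list with elements `sites` (a `pooled_sites` data frame, one row
#'   per SNP with per-pool A/C/G/T counts and depths) and `truth` (causal
#'   interval, per-site true pool frequencies, the causal marker, and
#'   per-animal causal-allele dosages for [simulate_phenotypes()]).
#' @seealso [write_fixture_bundle()] to serialize a full input set.
#' @export
simulate_pools <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  per_chrom <- vector("list", config$n_chromosomes)
  p_high_all <- p_low_all <- numeric(0)
  for (ci in seq_len(config$n_chromosomes)) {
    n <- config$n_snps_per_chrom
    chrom <- sprintf("chr%d", ci)
    pos <- sort(sample.int(config$chrom_length_bp, n))
    ref_i <- sample.int(4, n, replace = TRUE)
    alt_shift <- sample.int(3, n, replace = TRUE)
    alt_i <- ((ref_i - 1L + alt_shift) %% 4L) + 1L

    p_bg <- runif(n, config$background_freq_range[1],
                  config$background_freq_range[2])
    p_high <- p_bg
    p_low <- p_bg
    if (ci == config$causal_chrom && config$causal_halfwidth_bp > 0) {
      d <- abs(pos - config$causal_center_bp)
      w <- pmax(0, 1 - d / config$causal_halfwidth_bp)
      p_high <- p_bg + w * (config$p_high_core - p_bg)
      p_low <- p_bg + w * (config$p_low_core - p_bg)
    }

    sim_pool <- function(p) {
      depth <- rpois(n, config$mean_depth)
      alt_reads <- rbinom(n, depth, p)
      ref_reads <- depth - alt_reads
      cnt <- matrix(0L, n, 4, dimnames = list(NULL, BASES))
      cnt[cbind(seq_len(n), ref_i)] <- ref_reads
      cnt[cbind(seq_len(n), alt_i)] <- cnt[cbind(seq_len(n), alt_i)] + alt_reads
      if (config$error_rate > 0) {
        cnt <- redistribute_errors(cnt, ref_i,
                                   rbinom(n, ref_reads, config$error_rate))
        cnt <- redistribute_errors(cnt, alt_i,
                                   rbinom(n, alt_reads, config$error_rate))
      }
      cnt
    }
    cnt_high <- sim_pool(p_high)
    cnt_low <- sim_pool(p_low)

    # inject triallelic sites: move ~10% of each pool's reads to a third base
    n_tri <- round(config$triallelic_fraction * n)
    if (n_tri > 0) {
      tri <- sample.int(n, n_tri)
      for (i in tri) {
        third <- setdiff(1:4, c(ref_i[i], alt_i[i]))[sample.int(2, 1)]
        for (cntname in c("cnt_high", "cnt_low")) {
          cnt <- get(cntname)
          take <- min(cnt[i, ref_i[i]], max(1L, round(0.1 * sum(cnt[i, ]))))
          cnt[i, ref_i[i]] <- cnt[i, ref_i[i]] - take
          cnt[i, third] <- cnt[i, third] + take
          assign(cntname, cnt)
        }
      }
    }

    # alleles actually observable in a VCF record: the designated ALT plus
    # every other non-REF base carrying reads in either pool (miscalls
    # included — those sites are later dropped by the biallelic filter)
    observed <- (cnt_high + cnt_low) > 0
    observed[cbind(seq_len(n), alt_i)] <- TRUE
    observed[cbind(seq_len(n), ref_i)] <- FALSE
    n_alleles <- 1L + rowSums(observed)
    alt2 <- vapply(seq_len(n), function(i) {
      extra <- setdiff(which(observed[i, ]), alt_i[i])
      if (length(extra)) BASES[extra[1]] else NA_character_
    }, character(1))

    per_chrom[[ci]] <- data.frame(
      chrom = chrom, pos = pos,
      ref = BASES[ref_i], alt = BASES[alt_i],
      alt2 = alt2,
      n_alleles = n_alleles,
      high_A = cnt_high[, 1], high_C = cnt_high[, 2],
      high_G = cnt_high[, 3], high_T = cnt_high[, 4],
      low_A = cnt_low[, 1], low_C = cnt_low[, 2],
      low_G = cnt_low[, 3], low_T = cnt_low[, 4],
      high_depth = rowSums(cnt_high), low_depth = rowSums(cnt_low),
      stringsAsFactors = FALSE)
    p_high_all <- c(p_high_all, p_high)
    p_low_all <- c(p_low_all, p_low)
  }
  sites <- do.call(rbind, per_chrom)
  rownames(sites) <- NULL
  class(sites) <- c("pooled_sites", "data.frame")

  causal_chrom_name <- sprintf("chr%d", config$causal_chrom)
  on_causal <- sites$chrom == causal_chrom_name & sites$n_alleles == 2L
  d_center <- abs(sites$pos - config$causal_center_bp)
  d_center[!on_causal] <- Inf
  marker_row <- which.min(d_center)

  animal_id <- sprintf("G%03d", seq_len(config$n_animals))
  dosage <- rbinom(config$n_animals, 2, config$causal_allele_freq)
  names(dosage) <- animal_id

  truth <- list(
    causal_chrom = causal_chrom_name,
    causal_start = max(1, config$causal_center_bp - config$causal_halfwidth_bp),
    causal_end = min(config$chrom_length_bp,
                     config$causal_center_bp + config$causal_halfwidth_bp),
    p_high = p_high_all, p_low = p_low_all,
    causal_marker = site_id(sites$chrom[marker_row], sites$pos[marker_row]),
    causal_marker_row = marker_row,
    dosage = dosage)
  class(truth) <- "bsa_truth"
  list(sites = sites, truth = truth)
}

#' Simulate animal-level phenotypes from causal-allele dosages
#'
#' Each animal's milk trait is `trait_baseline + effect_size * dosage` plus
#' Gaussian noise, truncated at zero (concentrations cannot be negative).
#' The blood trait follows the same genotype effect at roughly half the
#' scale, mirroring the weaker blood/milk agreement seen in pooled-trait
#' cohorts.
#'
#' @param config a [sim_config()].
#' @param truth the truth record from [simulate_pools()] (supplies per-animal
#'   dosages).
#' @return a data frame with columns `animal_id`, `milk_trait`, `blood_trait`
#'   (ng/mL).
#' @export
simulate_phenotypes <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (length(truth$dosage) != config$n_animals) {
    stop_config("truth record has ", length(truth$dosage),
                " dosages but config expects ", config$n_animals, " animals")
  }
  set.seed(config$seed + 1L)
  n <- config$n_animals
  dosage <- as.numeric(truth$dosage)
  milk <- pmax(0, config$trait_baseline + config$effect_size * dosage +
                 rnorm(n, 0, config$trait_noise_sd))
  blood <- pmax(0, 0.5 * config$trait_baseline +
                  0.5 * config$effect_size * dosage +
                  rnorm(n, 0, config$trait_noise_sd))
  data.frame(animal_id = names(truth$dosage),
             milk_trait = milk, blood_trait = blood,
             stringsAsFactors = FALSE)
}

genotype_string <- function(ref, alt, dosage) {
  a <- ifelse(dosage == 2, alt, ref)
  b <- ifelse(dosage == 0, ref, alt)
  paste0(pmin(a, b), pmax(a, b))  # alphabetical normalization
}

#' Write a complete synthetic input bundle to disk
#'
#' Serializes the simulated world as the file set the pipeline consumes: a
#' two-sample VCF (`HIGH_BULK`, `LOW_BULK`, FORMAT `GT:AD:DP`), a phenotype
#' CSV, an individual genotype TSV at the causal marker plus `n_null_markers`
#' unlinked markers, a per-SNP annotation TSV assigning sites to synthetic
#' genes tiled along the chromosomes, and a gene-set TSV in which the term
#' `TERM_CAUSAL` contains the causal gene. All files are plain text.
#'
#' @param sites,truth output of [simulate_pools()].
#' @param phenotypes output of [simulate_phenotypes()].
#' @param out_dir output directory (created if needed).
#' @param config the [sim_config()] used (drives seeds and gene layout).
#' @param n_null_markers number of unlinked validation markers.
#' @return the manifest (named list of file paths plus the seed), invisibly
#'   written to `manifest.json` as well.
#' @export
write_fixture_bundle <- function(sites, truth, phenotypes, out_dir, config,
                                 n_null_markers = 8) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- list(
    vcf = file.path(out_dir, "pools.vcf"),
    phenotypes = file.path(out_dir, "phenotypes.csv"),
    genotypes = file.path(out_dir, "genotypes.tsv"),
    annotation = file.path(out_dir, "annotation.tsv"),
    gene_sets = file.path(out_dir, "gene_sets.tsv"),
    manifest = file.path(out_dir, "manifest.json"))

  write_pool_vcf(sites, paths$vcf)
  write_atomic(paths$phenotypes, function(p)
    utils::write.csv(phenotypes, p, row.names = FALSE, quote = FALSE))

  set.seed(config$seed + 2L)
  # gene tiling: one synthetic gene per 100 kb block
  block <- 1e5
  gene_of <- function(chrom, pos) {
    sprintf("GENE_%s_%04d", sub("^chr", "", chrom), pos %/% block + 1)
  }
  genes <- gene_of(sites$chrom, sites$pos)
  n <- nrow(sites)
  region_class <- sample(REGION_CLASSES, n, replace = TRUE,
                         prob = c(0.05, 0.50, 0.20, 0.02, 0.03, 0.18, 0.02))
  mutation_class <- rep(NA_character_, n)
  exonic <- region_class == "exonic"
  mutation_class[exonic] <- sample(MUTATION_CLASSES, sum(exonic),
                                   replace = TRUE,
                                   prob = c(0.55, 0.40, 0.03, 0.02))
  aa <- rep(".", n)
  nonsyn <- !is.na(mutation_class) & mutation_class != "synonymous"
  aa[nonsyn] <- paste(sample(LETTERS[1:20], sum(nonsyn), TRUE),
                      sample(LETTERS[1:20], sum(nonsyn), TRUE), sep = "/")
  mr <- truth$causal_marker_row
  region_class[mr] <- "exonic"
  mutation_class[mr] <- "non-synonymous"
  aa[mr] <- "E/Q"
  ann <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    ref = sites$ref, alt = sites$alt,
                    gene_id = genes, region_class = region_class,
                    mutation_class = ifelse(is.na(mutation_class), ".",
                                            mutation_class),
                    aa_change = aa, stringsAsFactors = FALSE)
  write_atomic(paths$annotation, function(p)
    write.table(ann, p, sep = "\t", row.names = FALSE, quote = FALSE))

  # gene sets: one causal term plus random terms over the gene universe
  set.seed(config$seed + 3L)
  universe <- unique(genes)
  causal_gene <- genes[mr]
  terms <- list(TERM_CAUSAL = unique(c(causal_gene,
                                       sample(universe,
                                              min(4, length(universe))))))
  max_term <- max(2L, min(50L, length(universe) %/% 2L))
  min_term <- min(10L, max_term)
  for (t in seq_len(30)) {
    terms[[sprintf("TERM_%04d", t)]] <-
      sample(universe, sample(min_term:max_term, 1))
  }
  gs <- data.frame(
    term_id = rep(names(terms), lengths(terms)),
    gene_id = unlist(terms, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_atomic(paths$gene_sets, function(p)
    write.table(gs, p, sep = "\t", row.names = FALSE, quote = FALSE))

  # genotype table: causal marker from truth dosages + unlinked null markers
  set.seed(config$seed + 4L)
  ids <- names(truth$dosage)
  biallelic <- which(sites$n_alleles == 2L)
  null_rows <- sample(setdiff(biallelic, mr), n_null_markers)
  gt <- data.frame(animal_id = ids,
                   marker_id = truth$causal_marker,
                   genotype = genotype_string(sites$ref[mr], sites$alt[mr],
                                              truth$dosage),
                   stringsAsFactors = FALSE)
  for (r in null_rows) {
    q <- runif(1, 0.1, 0.5)
    dos <- rbinom(length(ids), 2, q)
    gt <- rbind(gt, data.frame(
      animal_id = ids,
      marker_id = site_id(sites$chrom[r], sites$pos[r]),
      genotype = genotype_string(sites$ref[r], sites$alt[r], dos),
      stringsAsFactors = FALSE))
  }
  write_atomic(paths$genotypes, function(p)
    write.table(gt, p, sep = "\t", row.names = FALSE, quote = FALSE))

  manifest <- c(lapply(paths[names(paths) != "manifest"], normalizePath),
                list(seed = config$seed,
                     causal_marker = truth$causal_marker,
                     causal_gene = causal_gene,
                     n_sites = n))
  write_atomic(paths$manifest, function(p)
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE))
  invisible(manifest)
}
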