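# Pipeline orchestration: one configuration object, one function per
# subcommand, and a small CLI front end (`bsaed simulate|scan|enrich|
# validate|all`).

#' Pipeline configuration
#'
#' One serialized source of truth for a run: input/output paths, the two
#' sample names, and every tunable with its default — wild-pool fixation
#' cutoff 0.95, minimum pool depth 10X, loess span 0.05 and degree 2,
#' threshold at median + 3 SD, candidate cuts (alt frequency > 0.75, ED >
#' 0.5), enrichment q cutoff 0.05. Unknown fields are rejected so typos in
#' config files fail loudly.
#'
#' @param ... fields to override; see Details in the package vignette.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    vcf = NULL, annotation = NULL, gene_sets = NULL,
    phenotypes = NULL, genotypes = NULL, out_dir = "bsaed_out",
    high_sample = "HIGH_BULK", low_sample = "LOW_BULK",
    wt_fixation_cutoff = 0.95, min_pool_depth = 10,
    span = 0.05, degree = 2, threshold_k = 3,
    max_gap_snps = 0, min_region_snps = 1,
    freq_cut = 0.75, ed_cut = 0.5, q_cutoff = 0.05,
    channel = "milk", seed = 1L,
    # synthetic-data overrides passed through to sim_config()
    sim = list())
  override <- list(...)
  if (length(override) == 1 && is.list(override[[1]]) &&
      is.null(names(override))) {
    override <- override[[1]]
  }
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown)) {
    stop_config("unknown configuration field(s): ",
                paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, override)
  for (fld in c("wt_fixation_cutoff", "freq_cut", "q_cutoff")) {
    if (cfg[[fld]] < 0 || cfg[[fld]] > 1) {
      stop_config(fld, " must lie in [0, 1]")
    }
  }
  if (cfg$span <= 0 || cfg$min_pool_depth < 0 || cfg$threshold_k < 0) {
    stop_config("span must be positive; min_pool_depth and threshold_k ",
                "non-negative")
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a JSON file
#' @param path JSON file whose keys match [pipeline_config()] fields.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  pipeline_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

ensure_out_dir <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir)) {
    stop_config("cannot create out_dir: ", config$out_dir)
  }
  config$out_dir
}

#' Simulate a synthetic input bundle
#'
#' Generates pooled read counts with a planted causal locus, phenotypes,
#' genotypes and gene sets, and writes the full fixture bundle into
#' `out_dir` (see [write_fixture_bundle()]).
#'
#' @param config a [pipeline_config()]; `config$sim` entries override
#'   [sim_config()] defaults, and `config$seed` seeds the generator.
#' @return the bundle manifest, invisibly.
#' @export
cmd_simulate <- function(config) {
  out <- ensure_out_dir(config)
  sc <- do.call(sim_config, utils::modifyList(list(seed = config$seed),
                                              config$sim))
  log_info("simulating ", sc$n_chromosomes, " x ", sc$n_snps_per_chrom,
           " sites (seed ", sc$seed, ")")
  sim <- simulate_pools(sc)
  phen <- simulate_phenotypes(sc, sim$truth)
  manifest <- write_fixture_bundle(sim$sites, sim$truth, phen, out, sc)
  log_info("bundle written to ", out)
  invisible(manifest)
}

#' Run the ED association scan
#'
#' Reads the two-pool VCF, applies the pre-association filters, computes
#' ED and ED^4, smooths per chromosome, derives the median + k SD
#' threshold, calls regions and selects candidate SNPs. Writes
#' `track.tsv`, `regions.bed`, `candidates.tsv` and `scan_summary.json`
#' into `out_dir`. An empty post-filter site set produces empty outputs
#' with a warning, not an error.
#'
#' @param config a [pipeline_config()] with `vcf` set (and optionally
#'   `annotation`).
#' @return `list(scores, threshold, regions, candidates, report)`,
#'   invisibly.
#' @export
cmd_scan <- function(config) {
  if (is.null(config$vcf)) stop_config("cmd_scan requires config$vcf")
  out <- ensure_out_dir(config)
  sites <- read_pool_vcf(config$vcf, config$high_sample, config$low_sample)
  log_info("read ", nrow(sites), " sites from ", config$vcf)
  flt <- apply_pre_ed_filters(sites, config$wt_fixation_cutoff,
                              config$min_pool_depth)
  rep <- flt$report
  log_info("filters: ", rep$n_input, " in, ",
           rep$n_removed_multiallelic, " multiallelic, ",
           rep$n_removed_wt_fixed, " wt-fixed, ",
           rep$n_removed_low_depth, " low-depth, ",
           rep$n_retained, " retained")
  ann <- if (!is.null(config$annotation)) read_annotation(config$annotation)

  if (rep$n_retained == 0) {
    warning("no sites survive the pre-association filters; ",
            "writing empty outputs")
    scores <- data.frame(chrom = character(), pos = integer(),
                         ed = numeric(), ed4 = numeric(),
                         fitted = numeric(), high_alt_freq = numeric(),
                         low_alt_freq = numeric())
    regions <- call_regions(data.frame(chrom = character(),
                                       pos = integer(),
                                       fitted = numeric()), Inf)
    cand <- select_candidates(regions, scores, ann,
                              config$freq_cut, config$ed_cut)
    thr <- list(median_fitted = NA, sd_fitted = NA, threshold = NA)
  } else {
    scores <- fit_local_polynomial(association_scores(flt$sites),
                                   span = config$span,
                                   degree = config$degree)
    thr <- compute_threshold(scores$fitted, k = config$threshold_k)
    log_info("association threshold (median + ", config$threshold_k,
             " SD): ", signif(thr$threshold, 6))
    regions <- call_regions(scores, thr, config$max_gap_snps,
                            config$min_region_snps)
    cand <- select_candidates(regions, scores, ann,
                              config$freq_cut, config$ed_cut)
    log_info(nrow(regions), " region(s), ", nrow(cand),
             " candidate SNP(s)")
  }
  write_track_tsv(scores, file.path(out, "track.tsv"))
  write_regions_bed(regions, file.path(out, "regions.bed"))
  write_candidates_tsv(cand, file.path(out, "candidates.tsv"))
  summary <- list(filter_report = unclass(rep),
                  threshold = thr[c("median_fitted", "sd_fitted",
                                    "threshold")],
                  n_regions = nrow(regions), n_candidates = nrow(cand),
                  config = config[c("wt_fixation_cutoff", "min_pool_depth",
                                    "span", "degree", "threshold_k",
                                    "freq_cut", "ed_cut", "seed")])
  write_atomic(file.path(out, "scan_summary.json"), function(p)
    jsonlite::write_json(summary, p, auto_unbox = TRUE, pretty = TRUE,
                         na = "null"))
  invisible(list(scores = scores, threshold = thr, regions = regions,
                 candidates = cand, report = rep))
}

#' Gene-set enrichment of the scan's candidate genes
#'
#' Reads the candidate table written by [cmd_scan()] (or `candidates` in
#' memory), extracts the unique annotated genes, and tests them against the
#' gene-set database. Writes `enrichment.tsv`.
#'
#' @param config a [pipeline_config()] with `gene_sets` set.
#' @param candidates optional in-memory candidate table; defaults to
#'   `out_dir/candidates.tsv`.
#' @return the enrichment data frame, invisibly.
#' @export
cmd_enrich <- function(config, candidates = NULL) {
  if (is.null(config$gene_sets)) {
    stop_config("cmd_enrich requires config$gene_sets (--gene-sets)")
  }
  out <- ensure_out_dir(config)
  if (is.null(candidates)) {
    cpath <- file.path(out, "candidates.tsv")
    if (!file.exists(cpath)) {
      stop_config("no candidate table; run cmd_scan first or pass one")
    }
    candidates <- read.delim(cpath, stringsAsFactors = FALSE,
                             na.strings = ".")
  }
  db <- read_gene_sets(config$gene_sets)
  genes <- unique(candidates$gene_id[!is.na(candidates$gene_id)])
  log_info("enrichment: ", length(genes), " candidate gene(s) vs ",
           length(db$terms), " term(s), background ", db$background)
  res <- enrich(genes, db, q_cutoff = config$q_cutoff)
  write_atomic(file.path(out, "enrichment.tsv"), function(p)
    write.table(res, p, sep = "\t", row.names = FALSE, quote = FALSE))
  invisible(res)
}

#' Marker-phenotype validation tests
#'
#' Runs the Pearson dosage test on every marker of the genotype table
#' against the chosen trait channel and writes `marker_tests.tsv`.
#'
#' @param config a [pipeline_config()] with `phenotypes` and `genotypes`
#'   set.
#' @return the marker test data frame, invisibly.
#' @export
cmd_validate <- function(config) {
  if (is.null(config$phenotypes) || is.null(config$genotypes)) {
    stop_config("cmd_validate requires config$phenotypes and ",
                "config$genotypes")
  }
  out <- ensure_out_dir(config)
  phen <- read_phenotypes(config$phenotypes)
  gt <- read_genotypes(config$genotypes)
  res <- validate_markers(gt, phen, channel = config$channel)
  log_info("validated ", nrow(res), " marker(s); min p = ",
           if (nrow(res)) signif(min(res$p_value), 3) else NA)
  write_atomic(file.path(out, "marker_tests.tsv"), function(p)
    write.table(res, p, sep = "\t", row.names = FALSE, quote = FALSE))
  invisible(res)
}

#' Full pipeline run
#'
#' With no `vcf` configured, first simulates a bundle into `out_dir` and
#' runs on it; otherwise uses the configured inputs. Executes scan,
#' enrichment (if gene sets available) and validation (if phenotypes and
#' genotypes available), then writes a human-readable `summary.txt` and a
#' machine-readable `summary.json`.
#'
#' @param config a [pipeline_config()].
#' @return list of stage results, invisibly.
#' @export
cmd_all <- function(config) {
  out <- ensure_out_dir(config)
  if (is.null(config$vcf)) {
    manifest <- cmd_simulate(config)
    config$vcf <- manifest$vcf
    config$annotation <- config$annotation %||% manifest$annotation
    config$gene_sets <- config$gene_sets %||% manifest$gene_sets
    config$phenotypes <- config$phenotypes %||% manifest$phenotypes
    config$genotypes <- config$genotypes %||% manifest$genotypes
  }
  scan <- cmd_scan(config)
  enr <- if (!is.null(config$gene_sets)) cmd_enrich(config)
  val <- if (!is.null(config$phenotypes) && !is.null(config$genotypes)) {
    cmd_validate(config)
  }
  summary <- list(
    seed = config$seed,
    filter_report = unclass(scan$report),
    threshold = scan$threshold$threshold,
    n_regions = nrow(scan$regions),
    n_candidates = nrow(scan$candidates),
    n_terms_tested = if (!is.null(enr)) nrow(enr) else NA,
    n_terms_significant = if (!is.null(enr)) sum(enr$significant) else NA,
    n_markers_tested = if (!is.null(val)) nrow(val) else NA,
    best_marker = if (!is.null(val) && nrow(val)) {
      val$marker_id[which.min(val$p_value)]
    } else NA)
  write_atomic(file.path(out, "summary.json"), function(p)
    jsonlite::write_json(summary, p, auto_unbox = TRUE, pretty = TRUE,
                         na = "null"))
  write_atomic(file.path(out, "summary.txt"), function(p) {
    lines <- c(
      "bsaed pipeline summary",
      sprintf("seed:                 %s", summary$seed),
      sprintf("sites in / retained:  %d / %d",
              summary$filter_report$n_input,
              summary$filter_report$n_retained),
      sprintf("association threshold: %s", signif(summary$threshold, 6)),
      sprintf("regions / candidates: %d / %d", summary$n_regions,
              summary$n_candidates),
      sprintf("terms tested / significant: %s / %s",
              summary$n_terms_tested, summary$n_terms_significant),
      sprintf("markers tested:       %s (best: %s)",
              summary$n_markers_tested, summary$best_marker))
    writeLines(lines, p)
  })
  invisible(list(scan = scan, enrichment = enr, validation = val,
                 summary = summary))
}

cli_usage <- function() {
  paste(
    "usage: bsaed <simulate|scan|enrich|validate|all> [options]",
    "  --config FILE   JSON configuration (pipeline_config fields)",
    "  --seed N        override the seed",
    "  --out DIR       override out_dir",
    "  --vcf FILE --annotation FILE --gene-sets FILE",
    "  --phenotypes FILE --genotypes FILE",
    sep = "\n")
}

parse_cli_args <- function(args) {
  if (!length(args)) stop_config("no subcommand given\n", cli_usage())
  cmd <- args[[1]]
  if (!cmd %in% c("simulate", "scan", "enrich", "validate", "all")) {
    stop_config("unknown subcommand '", cmd, "'\n", cli_usage())
  }
  args <- args[-1]
  flags <- list()
  i <- 1
  flag_map <- c("--config" = "config", "--seed" = "seed",
                "--out" = "out_dir", "--vcf" = "vcf",
                "--annotation" = "annotation",
                "--gene-sets" = "gene_sets",
                "--phenotypes" = "phenotypes",
                "--genotypes" = "genotypes")
  while (i <= length(args)) {
    a <- args[[i]]
    if (!a %in% names(flag_map)) {
      stop_config("unknown option '", a, "'\n", cli_usage())
    }
    if (i == length(args)) stop_config("option ", a, " needs a value")
    flags[[flag_map[[a]]]] <- args[[i + 1]]
    i <- i + 2
  }
  list(cmd = cmd, flags = flags)
}

#' Command-line entry point
#'
#' Dispatches `bsaed simulate|scan|enrich|validate|all`. Flags override
#' config-file values. Returns an exit status (0 on success) instead of
#' calling `quit()`, so it is testable in-process; the installed
#' `bin/bsaed` script forwards the status to the shell.
#'
#' @param args character vector of CLI arguments (default: the command
#'   line).
#' @return integer exit status, invisibly.
#' @export
bsaed_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    parsed <- parse_cli_args(args)
    flags <- parsed$flags
    cfg <- if (!is.null(flags$config)) {
      read_pipeline_config(flags$config)
    } else {
      pipeline_config()
    }
    if (!is.null(flags$seed)) cfg$seed <- as.integer(flags$seed)
    for (fld in c("out_dir", "vcf", "annotation", "gene_sets",
                  "phenotypes", "genotypes")) {
      if (!is.null(flags[[fld]])) cfg[[fld]] <- flags[[fld]]
    }
    switch(parsed$cmd,
           simulate = cmd_simulate(cfg),
           scan = cmd_scan(cfg),
           enrich = cmd_enrich(cfg),
           validate = cmd_validate(cfg),
           all = cmd_all(cfg))
    0L
  }, error = function(e) {
    message("bsaed: error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
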