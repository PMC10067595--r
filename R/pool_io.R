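# IO for the two-pool VCF and the auxiliary tables (annotation, phenotypes,
# gene sets) plus the scan outputs (track TSV, regions BED, candidates TSV).

#' Read a two-pool VCF into a pooled site table
#'
#' Parses a VCF 4.2 file with per-sample allele depths (`AD`) for one
#' high-trait and one low-trait bulk and assembles per-site four-base read
#' counts: the REF depth goes to the REF base, each ALT depth to its ALT
#' base, all other bases zero. Records with missing `AD` in a sample get
#' depth 0 for that pool. `n_alleles` is 1 plus the number of ALT alleles;
#' multiallelic records are kept here and removed later by
#' [apply_pre_ed_filters()].
#'
#' @param path VCF file (plain text or bgzip).
#' @param high_sample,low_sample sample names of the high- and low-trait
#'   bulks as they appear in the VCF header.
#' @return a `pooled_sites` data frame (chrom, pos, ref, alt, per-pool
#'   A/C/G/T counts, depths, `n_alleles`).
#' @export
read_pool_vcf <- function(path, high_sample = "HIGH_BULK",
                          low_sample = "LOW_BULK") {
  if (!file.exists(path)) stop_config("VCF not found: ", path)
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  samp <- colnames(vcf)
  for (s in c(high_sample, low_sample)) {
    if (!s %in% samp) {
      stop_config("sample '", s, "' not present in VCF header (has: ",
                  paste(samp, collapse = ", "), ")")
    }
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt_l <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_l)
  alt_chr <- as.character(unlist(alt_l))
  alt1 <- character(length(n_alt))
  alt2 <- rep(NA_character_, length(n_alt))
  idx <- cumsum(n_alt) - n_alt + 1L
  alt1 <- alt_chr[idx]
  alt2[n_alt >= 2] <- alt_chr[idx[n_alt >= 2] + 1L]

  geno <- VariantAnnotation::geno(vcf)
  if (!"AD" %in% names(geno)) stop_parse("VCF has no AD FORMAT field")
  ad <- geno$AD
  n <- length(pos)

  counts_for <- function(sample) {
    cnt <- matrix(0L, n, 4, dimnames = list(NULL, BASES))
    adx <- ad[, sample]
    if (!is.list(adx)) adx <- as.list(adx)
    for (i in seq_len(n)) {
      v <- adx[[i]]
      if (is.null(v) || all(is.na(v))) next
      v[is.na(v)] <- 0L
      if (!ref[i] %in% BASES) {
        stop_parse("record ", i, ": non-SNV REF allele '", ref[i], "'")
      }
      cnt[i, ref[i]] <- v[1]
      alleles <- alt_chr[seq.int(idx[i], length.out = n_alt[i])]
      for (k in seq_len(n_alt[i])) {
        if (length(v) >= k + 1 && alleles[k] %in% BASES) {
          cnt[i, alleles[k]] <- cnt[i, alleles[k]] + v[k + 1]
        }
      }
    }
    cnt
  }
  cnt_high <- counts_for(high_sample)
  cnt_low <- counts_for(low_sample)

  sites <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt1, alt2 = alt2,
    n_alleles = 1L + n_alt,
    high_A = cnt_high[, 1], high_C = cnt_high[, 2],
    high_G = cnt_high[, 3], high_T = cnt_high[, 4],
    low_A = cnt_low[, 1], low_C = cnt_low[, 2],
    low_G = cnt_low[, 3], low_T = cnt_low[, 4],
    high_depth = rowSums(cnt_high), low_depth = rowSums(cnt_low),
    stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  class(sites) <- c("pooled_sites", "data.frame")
  sites
}

#' Write a pooled site table as a two-sample VCF
#'
#' Inverse of [read_pool_vcf()]: emits VCF 4.2 with FORMAT `GT:AD:DP` and the
#' two pools as samples `HIGH_BULK` and `LOW_BULK`. The ALT column lists the
#' designated alternate allele first, then every other non-reference base
#' carrying reads in either pool, so `AD` accounts for every read and the
#' write/read cycle is a fixpoint. Genotypes are coarse pool-level calls
#' (0/0, 0/1, 1/1 from the pool alternate frequency) kept for VCF validity;
#' the analysis relies on `AD` only.
#'
#' @param sites a `pooled_sites` data frame.
#' @param path output path.
#' @param high_sample,low_sample sample names to write.
#' @export
write_pool_vcf <- function(sites, path, high_sample = "HIGH_BULK",
                           low_sample = "LOW_BULK") {
  n <- nrow(sites)
  cnt_h <- as.matrix(sites[paste0("high_", BASES)])
  cnt_l <- as.matrix(sites[paste0("low_", BASES)])
  colnames(cnt_h) <- colnames(cnt_l) <- BASES
  ref_i <- match(sites$ref, BASES)
  alt_i <- match(sites$alt, BASES)
  sample_field <- function(cnt, alleles, i) {
    ad <- paste(cnt[i, alleles], collapse = ",")
    dep <- sum(cnt[i, ])
    f <- if (dep > 0) cnt[i, alleles[2]] / dep else NA
    gt <- if (dep == 0) "./."
          else if (f >= 0.8) "1/1" else if (f <= 0.2) "0/0" else "0/1"
    paste0(gt, ":", ad, ":", dep)
  }
  rows <- vapply(seq_len(n), function(i) {
    # ALT = designated alt first, then every other base with reads
    extra <- setdiff(which(cnt_h[i, ] + cnt_l[i, ] > 0),
                     c(ref_i[i], alt_i[i]))
    alleles <- c(ref_i[i], alt_i[i], extra)
    paste(sites$chrom[i], sites$pos[i], ".", sites$ref[i],
          paste(BASES[alleles[-1]], collapse = ","), ".", "PASS", ".",
          "GT:AD:DP", sample_field(cnt_h, alleles, i),
          sample_field(cnt_l, alleles, i), sep = "\t")
  }, character(1))
  body <- rows
  contigs <- vapply(split(sites$pos, sites$chrom), max, numeric(1)) + 1000
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs),
            as.integer(contigs)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", high_sample, low_sample, sep = "\t"))
  write_atomic(path, function(p) writeLines(c(header, body), p))
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_parse(what, ": missing required column(s): ",
               paste(missing, collapse = ", "))
  }
}

#' Read a per-SNP functional annotation table
#'
#' Tab-delimited with header columns `chrom, pos, ref, alt, gene_id,
#' region_class, mutation_class, aa_change`. `region_class` must come from
#' the closed vocabulary exonic / intronic / ncRNA / UTR5 / UTR3 /
#' intergenic / splicing; `'.'` marks a missing mutation class or amino-acid
#' change.
#'
#' @param path annotation TSV.
#' @return a data frame of annotation records.
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
  require_columns(df, c("chrom", "pos", "ref", "alt", "gene_id",
                        "region_class"), "annotation")
  bad <- setdiff(unique(df$region_class), c(REGION_CLASSES, NA))
  if (length(bad)) {
    stop_parse("annotation: unknown region_class value(s): ",
               paste(bad, collapse = ", "))
  }
  if (is.null(df$mutation_class)) df$mutation_class <- NA_character_
  if (is.null(df$aa_change)) df$aa_change <- NA_character_
  df
}

#' Read an animal-level phenotype table
#'
#' CSV with columns `animal_id, milk_trait, blood_trait` (concentrations in
#' ng/mL, non-negative).
#'
#' @param path phenotype CSV.
#' @return a data frame of phenotype records.
#' @export
read_phenotypes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("animal_id", "milk_trait", "blood_trait"),
                  "phenotypes")
  if (any(df$milk_trait < 0, na.rm = TRUE) ||
      any(df$blood_trait < 0, na.rm = TRUE)) {
    stop_parse("phenotypes: trait values must be non-negative")
  }
  df$animal_id <- as.character(df$animal_id)
  df
}

#' Read a gene-set membership file
#'
#' Two-column TSV `term_id, gene_id`, one row per membership. The background
#' size `N` defaults to the number of distinct genes in the file (i.e. the
#' annotated-gene universe).
#'
#' @param path gene-set TSV.
#' @param background optional background gene count overriding the default.
#' @return an object of class `gene_set_db`: `list(terms = <named list of
#'   gene vectors>, background = N)`.
#' @export
read_gene_sets <- function(path, background = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  require_columns(df, c("term_id", "gene_id"), "gene sets")
  terms <- lapply(split(df$gene_id, df$term_id), unique)
  db <- list(terms = terms,
             background = background %||% length(unique(df$gene_id)))
  if (length(terms) && db$background < max(lengths(terms))) {
    stop_config("background smaller than the largest term")
  }
  class(db) <- "gene_set_db"
  db
}

#' Read an individual genotype table
#'
#' TSV with columns `animal_id, marker_id, genotype` where genotype is a
#' two-allele string (e.g. `"CG"`, alphabetically normalized) or `'.'` /
#' empty for missing.
#'
#' @param path genotype TSV.
#' @return a data frame with normalized genotype strings (NA when missing).
#' @export
read_genotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c(".", ""))
  require_columns(df, c("animal_id", "marker_id", "genotype"), "genotypes")
  df$animal_id <- as.character(df$animal_id)
  ok <- is.na(df$genotype) | grepl("^[ACGT]{2}$", df$genotype)
  if (!all(ok)) {
    stop_parse("genotypes: malformed genotype string(s): ",
               paste(unique(df$genotype[!ok]), collapse = ", "))
  }
  gt <- df$genotype[!is.na(df$genotype)]
  a1 <- substr(gt, 1, 1); a2 <- substr(gt, 2, 2)
  df$genotype[!is.na(df$genotype)] <- paste0(pmin(a1, a2), pmax(a1, a2))
  df
}

#' Write candidate regions as BED3+
#'
#' Converts 1-based inclusive SNP-anchored intervals to BED's 0-based
#' half-open convention: `start = first SNP pos - 1`, `end = last SNP pos`.
#' An empty region set yields a header-only file.
#'
#' @param regions data frame from [call_regions()].
#' @param path output BED path.
#' @export
write_regions_bed <- function(regions, path) {
  write_atomic(path, function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines("#chrom\tstart\tend\tn_snps\tpeak_fitted", con)
    if (!is.null(regions) && nrow(regions)) {
      writeLines(paste(regions$chrom, regions$start_pos - 1L,
                       regions$end_pos, regions$n_snps,
                       signif(regions$peak_fitted, 6), sep = "\t"), con)
    }
  })
}

#' Write the candidate SNP table
#' @param candidates data frame from [select_candidates()].
#' @param path output TSV path.
#' @export
write_candidates_tsv <- function(candidates, path) {
  write_atomic(path, function(p)
    write.table(candidates, p, sep = "\t", row.names = FALSE,
                quote = FALSE, na = "."))
}

#' Write / read the per-SNP scan track
#'
#' Columns: chrom, pos, ed, ed4, fitted, high_alt_freq, low_alt_freq.
#' `read_track_tsv` is the exact inverse (used for round-trip checks and
#' plotting downstream).
#'
#' @param scores scored site table (see [association_scores()]).
#' @param path TSV path.
#' @export
write_track_tsv <- function(scores, path) {
  keep <- intersect(c("chrom", "pos", "ed", "ed4", "fitted",
                      "high_alt_freq", "low_alt_freq"), names(scores))
  write_atomic(path, function(p)
    write.table(scores[keep], p, sep = "\t", row.names = FALSE,
                quote = FALSE, na = "."))
}

#' @rdname write_track_tsv
#' @export
read_track_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
}
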