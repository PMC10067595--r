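# Shared fixture builders. Everything is generated in code; no binary data.

# A pooled_sites row from explicit per-pool base counts (A, C, G, T order).
make_site <- function(chrom = "chr1", pos = 100, ref = "A", alt = "G",
                      high = c(10, 0, 10, 0), low = c(10, 0, 10, 0),
                      n_alleles = 2, alt2 = NA_character_) {
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   alt2 = alt2, n_alleles = as.integer(n_alleles),
                   high_A = high[1], high_C = high[2], high_G = high[3],
                   high_T = high[4],
                   low_A = low[1], low_C = low[2], low_G = low[3],
                   low_T = low[4],
                   high_depth = sum(high), low_depth = sum(low),
                   stringsAsFactors = FALSE)
  class(df) <- c("pooled_sites", "data.frame")
  df
}

bind_sites <- function(...) {
  df <- do.call(rbind, lapply(list(...), as.data.frame))
  rownames(df) <- NULL
  class(df) <- c("pooled_sites", "data.frame")
  df
}

# Small, fast simulation world used across tests.
small_sim_config <- function(...) {
  args <- utils::modifyList(
    list(n_chromosomes = 2, chrom_length_bp = 2e6,
         n_snps_per_chrom = 1000, causal_center_bp = 1e6,
         causal_halfwidth_bp = 2e5),
    list(...))
  do.call(sim_config, args)
}

# A tiny hand-written two-sample VCF; returns its path.
write_mini_vcf <- function(body_lines,
                           samples = c("HIGH_BULK", "LOW_BULK"),
                           path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body_lines), path)
  path
}

vcf_line <- function(chrom, pos, ref, alt, high, low) {
  paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT:AD:DP",
        high, low, sep = "\t")
}

# Random four-base frequency vectors (rows sum to 1).
random_freqs <- function(n) {
  m <- matrix(runif(4 * n), n, 4)
  m / rowSums(m)
}

# Independent term-by-term ED evaluation (the oracle the fast path is
# checked against).
ed_oracle <- function(high, low) {
  vapply(seq_len(nrow(high)), function(i) {
    s <- 0
    for (b in 1:4) s <- s + (high[i, b] - low[i, b])^2
    sqrt(s)
  }, numeric(1))
}

# Exhaustive-enumeration hypergeometric upper tail: enumerate every n-subset
# of a background of N genes of which the first M are in the term.
hyper_enum <- function(N, M, n, m) {
  if (n == 0) return(as.numeric(m == 0))
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= M) >= m)
}
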