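# Per-sample genotype classification from pooled read counts, and the three
# pre-association site filters.

#' Classify a sample's genotype from ref/alt read counts
#'
#' Implements the pooled-read purity rules: a site covered by fewer than 5
#' reads in a sample is missing (`"NA"`); alternate-read frequency >= 0.8
#' calls a homozygous alternate, <= 0.2 a homozygous reference; frequencies
#' strictly between call a heterozygote only when BOTH alleles are supported
#' by at least 4 reads, otherwise the site is missing. Depth is
#' `ref_reads + alt_reads` (allele depths, not the DP field), so frequency
#' and call always use the same denominator.
#'
#' @param ref_reads,alt_reads non-negative read counts (vectorized).
#' @return a data frame with columns `call` (factor: `NA`, `hom_ref`,
#'   `hom_alt`, `het`) and `alt_frequency` (NA when depth is 0).
#' @export
classify_genotype <- function(ref_reads, alt_reads) {
  if (any(ref_reads < 0) || any(alt_reads < 0)) {
    stop("read counts must be non-negative")
  }
  n <- max(length(ref_reads), length(alt_reads))
  ref_reads <- rep_len(ref_reads, n)
  alt_reads <- rep_len(alt_reads, n)
  depth <- ref_reads + alt_reads
  freq <- ifelse(depth > 0, alt_reads / depth, NA_real_)
  call <- rep("NA", n)
  ok <- depth >= 5
  call[ok & freq >= 0.8] <- "hom_alt"
  call[ok & freq <= 0.2] <- "hom_ref"
  call[ok & freq > 0.2 & freq < 0.8 &
         ref_reads >= 4 & alt_reads >= 4] <- "het"
  data.frame(call = factor(call, levels = c("NA", "hom_ref", "hom_alt",
                                            "het")),
             alt_frequency = freq)
}

#' Apply the three pre-association site filters
#'
#' Removes, in order: (1) non-biallelic sites; (2) sites where any single
#' base reaches `wt_fixation_cutoff` (default 95%) of the wild-type (low
#' bulk) pool's reads — near-fixed in the wild pool, uninformative for the
#' scan; (3) sites with read depth below `min_pool_depth` (default 10X) in
#' either pool. Each removed site is attributed to the first rule it
#' matches, so the report's tallies sum to the input size.
#'
#' @param sites a `pooled_sites` data frame.
#' @param wt_fixation_cutoff base-frequency cutoff in the low pool
#'   (inclusive).
#' @param min_pool_depth minimum per-pool depth (strict: depth < cutoff is
#'   removed).
#' @return `list(sites = retained pooled_sites, report = filter_report)`.
#' @export
apply_pre_ed_filters <- function(sites, wt_fixation_cutoff = 0.95,
                                 min_pool_depth = 10) {
  n <- nrow(sites)
  if (n == 0) {
    report <- filter_report(0L, 0L, 0L, 0L)
    return(list(sites = sites, report = report))
  }
  multi <- sites$n_alleles != 2L
  low_cnt <- as.matrix(sites[paste0("low_", BASES)])
  max_low_freq <- ifelse(sites$low_depth > 0,
                         apply(low_cnt, 1, max) / pmax(sites$low_depth, 1),
                         NA_real_)
  wt_fixed <- !multi & !is.na(max_low_freq) &
    max_low_freq >= wt_fixation_cutoff
  low_depth <- !multi & !wt_fixed &
    (sites$high_depth < min_pool_depth | sites$low_depth < min_pool_depth)
  keep <- !(multi | wt_fixed | low_depth)
  retained <- sites[keep, , drop = FALSE]
  rownames(retained) <- NULL
  class(retained) <- c("pooled_sites", "data.frame")
  report <- filter_report(n, sum(multi), sum(wt_fixed), sum(low_depth))
  list(sites = retained, report = report)
}

filter_report <- function(n_input, n_multi, n_fixed, n_depth) {
  rep <- list(n_input = as.integer(n_input),
              n_removed_multiallelic = as.integer(n_multi),
              n_removed_wt_fixed = as.integer(n_fixed),
              n_removed_low_depth = as.integer(n_depth),
              n_retained = as.integer(n_input - n_multi - n_fixed - n_depth))
  stopifnot(rep$n_retained >= 0)
  class(rep) <- "filter_report"
  rep
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Site filter report\n",
      "  input sites:        ", x$n_input, "\n",
      "  removed multiallelic:", x$n_removed_multiallelic, "\n",
      "  removed wt-fixed:    ", x$n_removed_wt_fixed, "\n",
      "  removed low depth:   ", x$n_removed_low_depth, "\n",
      "  retained:            ", x$n_retained, "\n", sep = "")
  invisible(x)
}
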