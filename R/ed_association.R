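# The ED association scan: pool base frequencies, the Euclidean-distance
# statistic and its fourth power, local polynomial smoothing per chromosome,
# the median + 3 SD threshold, region calling and candidate selection.

#' Per-pool base frequencies at each site
#'
#' Divides each pool's A/C/G/T counts by that pool's depth. The 10X depth
#' filter guarantees positive depths upstream; zero-depth input is an error
#' here rather than silently producing NaN frequencies.
#'
#' @param sites a `pooled_sites` data frame.
#' @return `list(high = , low = )`, each an `n x 4` matrix with columns
#'   A, C, G, T whose rows sum to 1.
#' @export
pool_frequencies <- function(sites) {
  if (any(sites$high_depth == 0) || any(sites$low_depth == 0)) {
    stop("zero-depth pool encountered; run apply_pre_ed_filters() first")
  }
  high <- as.matrix(sites[paste0("high_", BASES)]) / sites$high_depth
  low <- as.matrix(sites[paste0("low_", BASES)]) / sites$low_depth
  colnames(high) <- colnames(low) <- BASES
  list(high = high, low = low)
}

#' Euclidean distance between two pools' base-frequency vectors
#'
#' \deqn{ED = \sqrt{\sum_{b \in \{A,C,G,T\}} (f_{mut,b} - f_{wt,b})^2}}
#'
#' where \eqn{f_{mut,b}} is the frequency of base `b` in the mutant (high
#' bulk) pool and \eqn{f_{wt,b}} in the wild-type (low bulk) pool. All four
#' terms are squared differences; ED is symmetric, zero iff the vectors are
#' equal, and bounded by \eqn{\sqrt 2} for frequency vectors (2 for
#' arbitrary unit-interval input).
#'
#' @param high,low frequency vectors of length 4, or `n x 4` matrices
#'   (rowwise distances).
#' @return ED value(s).
#' @export
compute_ed <- function(high, low) {
  if (is.null(dim(high))) high <- matrix(high, nrow = 1)
  if (is.null(dim(low))) low <- matrix(low, nrow = 1)
  stopifnot(ncol(high) == 4, ncol(low) == 4, nrow(high) == nrow(low))
  sqrt(rowSums((high - low)^2))
}

#' Fourth power of ED
#'
#' Raising ED to the fourth power stretches large pool divergences and
#' squashes the sampling-noise background, which is what the smoothed
#' association track is built from.
#'
#' @param ed non-negative ED value(s).
#' @return `ed^4`.
#' @export
ed_to_association <- function(ed) {
  if (any(ed < 0)) stop("ED must be non-negative")
  ed^4
}

#' Score retained sites: ED, ED^4 and pool alternate frequencies
#'
#' Convenience constructor of the association score table consumed by the
#' smoother and region caller.
#'
#' @param sites a filtered `pooled_sites` data frame (positive depths).
#' @return a data frame with `chrom, pos, ref, alt, ed, ed4, high_alt_freq,
#'   low_alt_freq`, sorted by chromosome then position.
#' @export
association_scores <- function(sites) {
  fr <- pool_frequencies(sites)
  i <- cbind(seq_len(nrow(sites)), match(sites$alt, BASES))
  scores <- data.frame(
    chrom = sites$chrom, pos = sites$pos,
    ref = sites$ref, alt = sites$alt,
    ed = compute_ed(fr$high, fr$low),
    high_alt_freq = fr$high[i], low_alt_freq = fr$low[i],
    stringsAsFactors = FALSE)
  scores$ed4 <- ed_to_association(scores$ed)
  scores <- scores[order(scores$chrom, scores$pos), ]
  rownames(scores) <- NULL
  scores
}

#' Smooth ED^4 along each chromosome by local polynomial regression
#'
#' Fits a tricube-weighted local polynomial (loess) of `ed4` against genomic
#' position independently per chromosome and evaluates it at every retained
#' SNP. The span is the fraction of a chromosome's SNPs in each local
#' window; chromosomes with too few sites for the requested degree fall back
#' to their mean with a warning, and the span is silently enlarged to the
#' minimum workable window when `span * n` is below `degree + 2`.
#'
#' @param scores score table from [association_scores()].
#' @param span smoothing span as a fraction of each chromosome's SNP count.
#' @param degree local polynomial degree.
#' @return `scores` with a `fitted` column appended.
#' @export
fit_local_polynomial <- function(scores, span = 0.05, degree = 2) {
  stopifnot(span > 0, degree >= 0)
  scores$fitted <- NA_real_
  for (ch in unique(scores$chrom)) {
    sel <- which(scores$chrom == ch)
    sel <- sel[order(scores$pos[sel])]
    n <- length(sel)
    if (n < degree + 2) {
      warning("chromosome ", ch, ": only ", n,
              " site(s); falling back to chromosome mean")
      scores$fitted[sel] <- mean(scores$ed4[sel])
      next
    }
    span_eff <- max(span, (degree + 2) / n)
    fit <- stats::loess(ed4 ~ pos, data = scores[sel, ],
                        span = span_eff, degree = degree,
                        family = "gaussian",
                        control = stats::loess.control(surface = "interpolate"))
    scores$fitted[sel] <- stats::fitted(fit)
  }
  if (any(!is.finite(scores$fitted))) {
    stop("non-finite fitted values produced by the smoother")
  }
  scores
}

#' Median + 3 SD association threshold
#'
#' The genome-wide association threshold is the median of the fitted
#' (smoothed ED^4) values over ALL retained sites, pooled across
#' chromosomes, plus three sample standard deviations (n - 1 denominator).
#'
#' @param fitted fitted values at every retained site (length >= 2).
#' @param k number of SDs above the median (default 3).
#' @return an `association_threshold`: `list(median_fitted, sd_fitted,
#'   threshold)`.
#' @export
compute_threshold <- function(fitted, k = 3) {
  fitted <- fitted[!is.na(fitted)]
  if (length(fitted) < 2) stop("need at least 2 fitted values")
  out <- list(median_fitted = stats::median(fitted),
              sd_fitted = stats::sd(fitted))
  out$threshold <- out$median_fitted + k * out$sd_fitted
  class(out) <- "association_threshold"
  out
}

threshold_value <- function(threshold) {
  if (inherits(threshold, "association_threshold")) threshold$threshold
  else as.numeric(threshold)
}

#' Call candidate regions above the association threshold
#'
#' A region is a maximal run of consecutive retained SNPs (in position order
#' within a chromosome) whose fitted values exceed the threshold strictly.
#' Up to `max_gap_snps` consecutive below-threshold SNPs may be bridged
#' without splitting a region (bridged SNPs are not members); regions with
#' fewer than `min_region_snps` member SNPs are dropped.
#'
#' @param scores fitted score table from [fit_local_polynomial()].
#' @param threshold an `association_threshold` or a plain number.
#' @param max_gap_snps below-threshold SNPs bridgeable inside a region.
#' @param min_region_snps minimum member SNPs per region.
#' @return a data frame `chrom, start_pos, end_pos, n_snps, peak_fitted`
#'   with a list column `members` of row indices into `scores`, sorted by
#'   chromosome and start.
#' @export
call_regions <- function(scores, threshold, max_gap_snps = 0,
                         min_region_snps = 1) {
  thr <- threshold_value(threshold)
  out <- list()
  for (ch in unique(scores$chrom)) {
    sel <- which(scores$chrom == ch)
    sel <- sel[order(scores$pos[sel])]
    above <- scores$fitted[sel] > thr
    if (!any(above)) next
    # group above-runs, merging across gaps of <= max_gap_snps below sites
    r <- rle(above)
    grp <- integer(length(above))
    g <- 0L
    pos_in_rle <- cumsum(r$lengths) - r$lengths + 1L
    last_above_grp <- 0L
    for (j in seq_along(r$lengths)) {
      idx <- pos_in_rle[j]:(pos_in_rle[j] + r$lengths[j] - 1L)
      if (r$values[j]) {
        if (last_above_grp > 0L && j >= 3L &&
            !r$values[j - 1L] && r$lengths[j - 1L] <= max_gap_snps) {
          grp[idx] <- last_above_grp
        } else {
          g <- g + 1L
          grp[idx] <- g
        }
        last_above_grp <- grp[idx[1]]
      }
    }
    for (gi in seq_len(g)) {
      members <- sel[grp == gi & above]
      if (length(members) < min_region_snps) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        start_pos = scores$pos[members[1]],
        end_pos = scores$pos[members[length(members)]],
        n_snps = length(members),
        peak_fitted = max(scores$fitted[members]),
        stringsAsFactors = FALSE)
      out[[length(out)]]$members <- I(list(members))
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start_pos = integer(),
                      end_pos = integer(), n_snps = integer(),
                      peak_fitted = numeric(),
                      members = I(list())))
  }
  regions <- do.call(rbind, out)
  regions <- regions[order(regions$chrom, regions$start_pos), ]
  rownames(regions) <- NULL
  regions
}

#' Select candidate SNPs inside associated regions
#'
#' A candidate SNP lies inside a called region and passes both marker cuts:
#' high-bulk (mutant-pool) alternate frequency strictly greater than
#' `freq_cut` and raw ED strictly greater than `ed_cut`. When an annotation
#' table is supplied, candidates are joined to it by chromosome and
#' position; unannotated candidates keep NA annotation fields.
#'
#' @param regions region table from [call_regions()].
#' @param scores fitted score table the regions index into.
#' @param annotations optional annotation data frame ([read_annotation()]).
#' @param freq_cut high-pool alternate frequency cut (strict).
#' @param ed_cut raw-ED cut (strict).
#' @return candidate data frame: score columns plus `region_id` and, if
#'   available, `gene_id, region_class, mutation_class, aa_change`.
#' @export
select_candidates <- function(regions, scores, annotations = NULL,
                              freq_cut = 0.75, ed_cut = 0.5) {
  if (nrow(regions) == 0) {
    cand <- scores[integer(0), ]
    cand$region_id <- integer(0)
  } else {
    idx <- unlist(regions$members)
    region_id <- rep(seq_len(nrow(regions)), lengths(regions$members))
    keep <- scores$high_alt_freq[idx] > freq_cut & scores$ed[idx] > ed_cut
    cand <- scores[idx[keep], , drop = FALSE]
    cand$region_id <- region_id[keep]
  }
  if (!is.null(annotations)) {
    key <- site_id(cand$chrom, cand$pos)
    akey <- site_id(annotations$chrom, annotations$pos)
    m <- match(key, akey)
    for (col in c("gene_id", "region_class", "mutation_class",
                  "aa_change")) {
      cand[[col]] <- annotations[[col]][m]
    }
  }
  rownames(cand) <- NULL
  cand
}
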