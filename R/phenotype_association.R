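# Phenotype-side logic: trait-level grouping, bulk selection, per-genotype
# summaries and the Pearson marker-trait test used for marker validation.

trait_channel <- function(records, channel = c("milk", "blood")) {
  channel <- match.arg(channel)
  records[[paste0(channel, "_trait")]]
}

#' Classify animals into low / mid / high trait groups
#'
#' Cutoffs follow the cohort design: trait values in `[0, low_max]` are
#' "low" (boundary inclusive), values strictly above `high_min` are "high",
#' everything between is "mid".
#'
#' @param records phenotype data frame ([read_phenotypes()]).
#' @param low_max upper bound of the low group (inclusive), ng/mL.
#' @param high_min lower bound of the high group (strict), ng/mL.
#' @param channel which trait to use, `"milk"` or `"blood"`.
#' @return `list(labels = factor(low/mid/high), proportions = named numeric
#'   summing to 1)`.
#' @export
classify_trait_groups <- function(records, low_max = 0.5, high_min = 1.0,
                                  channel = c("milk", "blood")) {
  if (low_max > high_min) stop_config("low_max must not exceed high_min")
  v <- trait_channel(records, channel)
  labels <- factor(ifelse(v <= low_max, "low",
                          ifelse(v > high_min, "high", "mid")),
                   levels = c("low", "mid", "high"))
  proportions <- if (length(v)) {
    prop <- table(labels) / length(v)
    setNames(as.numeric(prop), names(prop))
  } else {
    setNames(numeric(3), c("low", "mid", "high"))
  }
  list(labels = labels, proportions = proportions)
}

#' Select the high and low bulks from a phenotyped cohort
#'
#' Takes the `k` animals with the highest and the `k` with the lowest value
#' of the chosen trait. Ties at the boundary are broken deterministically by
#' ascending animal id.
#'
#' @param records phenotype data frame.
#' @param k animals per bulk.
#' @param channel trait channel.
#' @return `list(high = ids, low = ids)`, each of length `k`; the two sets
#'   are always disjoint.
#' @export
select_bulks <- function(records, k = 3, channel = c("milk", "blood")) {
  v <- trait_channel(records, channel)
  if (nrow(records) < 2 * k) {
    stop_config("need at least ", 2 * k, " records to draw two bulks of ",
                k)
  }
  ord_hi <- order(-v, records$animal_id)
  ord_lo <- order(v, records$animal_id)
  list(high = records$animal_id[ord_hi[seq_len(k)]],
       low = records$animal_id[ord_lo[seq_len(k)]])
}

marker_calls <- function(table, marker) {
  g <- table[table$marker_id == marker & !is.na(table$genotype), ]
  if (!nrow(g)) stop("no non-missing genotypes at marker ", marker)
  g
}

#' Genotype proportions at a marker
#'
#' Fractions over non-missing calls; the dominant (modal) genotype is
#' reported alongside.
#'
#' @param table genotype data frame ([read_genotypes()]).
#' @param marker marker id.
#' @return `list(proportions = named numeric summing to 1, dominant =
#'   genotype string, n = calls used)`.
#' @export
genotype_proportions <- function(table, marker) {
  g <- marker_calls(table, marker)
  tab <- table(g$genotype)
  prop <- setNames(as.numeric(tab) / nrow(g), names(tab))
  list(proportions = prop, dominant = names(prop)[which.max(prop)],
       n = nrow(g))
}

#' Mean trait value per genotype class at a marker
#'
#' @param table genotype data frame.
#' @param marker marker id.
#' @param phenotypes phenotype data frame.
#' @param channel trait channel.
#' @return named numeric vector of per-genotype arithmetic means; classes
#'   absent from the data are omitted.
#' @export
per_genotype_trait_means <- function(table, marker, phenotypes,
                                     channel = c("milk", "blood")) {
  g <- marker_calls(table, marker)
  m <- match(g$animal_id, phenotypes$animal_id)
  if (all(is.na(m))) stop("no genotyped animal has a phenotype record")
  v <- trait_channel(phenotypes, channel)[m]
  keep <- !is.na(v)
  means <- tapply(v[keep], g$genotype[keep], mean)
  setNames(as.numeric(means), names(means))
}

# Infer the counted (alternate) allele at a marker: the minor allele over
# non-missing calls, ties broken alphabetically.
infer_alt_allele <- function(genotypes) {
  alleles <- unlist(strsplit(genotypes, ""), use.names = FALSE)
  tab <- sort(table(alleles))
  names(tab)[1]
}

#' Pearson marker-trait association test
#'
#' Codes each genotype as the dosage (0/1/2 copies) of the alternate allele
#' — by default the minor allele at the marker, overridable — or as a binary
#' carrier indicator, then tests the Pearson correlation between dosage and
#' trait with the two-sided t test on n - 2 degrees of freedom. Constant
#' dosage or constant trait is a degenerate input and raises an error
#' rather than returning NaN.
#'
#' @param table genotype data frame.
#' @param marker marker id.
#' @param phenotypes phenotype data frame.
#' @param channel trait channel.
#' @param coding `"dosage"` (0/1/2 alternate-allele copies) or `"carrier"`
#'   (0/1 any copy).
#' @param alt_allele counted allele; default infers the minor allele.
#' @return a `marker_test` list: `marker_id, coding, alt_allele, pearson_r,
#'   p_value, n_used`.
#' @export
marker_trait_pearson <- function(table, marker, phenotypes,
                                 channel = c("milk", "blood"),
                                 coding = c("dosage", "carrier"),
                                 alt_allele = NULL) {
  coding <- match.arg(coding)
  g <- marker_calls(table, marker)
  m <- match(g$animal_id, phenotypes$animal_id)
  v <- trait_channel(phenotypes, channel)[m]
  keep <- !is.na(v)
  g <- g[keep, ]; v <- v[keep]
  if (nrow(g) < 3) stop("need at least 3 animals with genotype and trait")
  alt <- alt_allele %||% infer_alt_allele(g$genotype)
  dosage <- vapply(strsplit(g$genotype, ""),
                   function(a) sum(a == alt), numeric(1))
  if (coding == "carrier") dosage <- as.numeric(dosage > 0)
  if (length(unique(dosage)) < 2) {
    stop("degenerate input: constant genotype dosage at marker ", marker)
  }
  if (length(unique(v)) < 2) {
    stop("degenerate input: constant trait values at marker ", marker)
  }
  ct <- stats::cor.test(dosage, v, method = "pearson",
                        alternative = "two.sided")
  structure(list(marker_id = marker, coding = coding, alt_allele = alt,
                 pearson_r = unname(ct$estimate),
                 p_value = ct$p.value, n_used = nrow(g)),
            class = "marker_test")
}

#' Run the Pearson test on every marker in a genotype table
#'
#' @param table genotype data frame.
#' @param phenotypes phenotype data frame.
#' @param channel trait channel.
#' @param adjust apply BH adjustment across markers (off by default,
#'   matching raw p < 0.05 usage on a handful of validation markers).
#' @inheritParams marker_trait_pearson
#' @return data frame: `marker_id, alt_allele, pearson_r, p_value, n_used`
#'   (plus `q_value` when `adjust = TRUE`); markers with degenerate input
#'   are skipped with a message.
#' @export
validate_markers <- function(table, phenotypes,
                             channel = c("milk", "blood"),
                             coding = c("dosage", "carrier"),
                             adjust = FALSE) {
  markers <- unique(table$marker_id)
  rows <- lapply(markers, function(mk) {
    r <- tryCatch(marker_trait_pearson(table, mk, phenotypes, channel,
                                       coding),
                  error = function(e) {
                    log_info("marker ", mk, " skipped: ",
                             conditionMessage(e))
                    NULL
                  })
    if (is.null(r)) return(NULL)
    data.frame(marker_id = r$marker_id, alt_allele = r$alt_allele,
               pearson_r = r$pearson_r, p_value = r$p_value,
               n_used = r$n_used, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(marker_id = character(), alt_allele = character(),
                      pearson_r = numeric(), p_value = numeric(),
                      n_used = integer()))
  }
  res <- do.call(rbind, rows)
  if (adjust) res$q_value <- bh_adjust(res$p_value)
  rownames(res) <- NULL
  res
}
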