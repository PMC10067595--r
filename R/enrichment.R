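# Hypergeometric gene-set enrichment with Benjamini-Hochberg correction,
# plus annotation-class tallies.

#' Upper-tail hypergeometric probability
#'
#' Probability of drawing at least `m` term genes when `n` candidates are
#' drawn without replacement from a background of `N` genes of which `M`
#' belong to the term:
#' \deqn{P = 1 - \sum_{i=0}^{m-1} \binom{M}{i}\binom{N-M}{n-i} / \binom{N}{n}}
#' computed as the complementary tail sum in log space, so it is stable for
#' backgrounds up to at least 1e5 genes. `m = 0` gives exactly 1.
#'
#' @param N background gene count.
#' @param M genes annotated to the term (`0 <= M <= N`).
#' @param n candidate genes (`0 <= n <= N`).
#' @param m candidate genes in the term (`0 <= m <= min(n, M)`).
#' @return the exact upper-tail probability `P(X >= m)`.
#' @export
hypergeom_p <- function(N, M, n, m) {
  if (M < 0 || M > N || n < 0 || n > N || m < 0 || m > min(n, M)) {
    stop("hypergeometric parameters out of bounds: N=", N, " M=", M,
         " n=", n, " m=", m)
  }
  if (m == 0) return(1)
  i <- m:min(n, M)
  lg <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  min(1, exp(logsumexp(lg)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment ("Q values"); output order matches input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values in `[0, 1]`.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-set enrichment of a candidate gene list
#'
#' Tests every term with at least one candidate member against the
#' background with [hypergeom_p()], BH-adjusts across those terms, and
#' reports the rich factor `m / M`. Candidates outside the background are
#' dropped (with a message) before testing, matching the definition of the
#' background as the annotated-gene universe.
#'
#' @param candidate_genes character vector of candidate gene ids
#'   (deduplicated internally).
#' @param db a `gene_set_db` from [read_gene_sets()].
#' @param q_cutoff significance cutoff on the q-value (inclusive).
#' @return a data frame sorted by p-value: `term_id, N, M, n, m, p_value,
#'   q_value, rich_factor, significant`.
#' @export
enrich <- function(candidate_genes, db, q_cutoff = 0.05) {
  stopifnot(inherits(db, "gene_set_db"))
  empty <- data.frame(term_id = character(), N = integer(), M = integer(),
                      n = integer(), m = integer(), p_value = numeric(),
                      q_value = numeric(), rich_factor = numeric(),
                      significant = logical())
  if (!length(db$terms)) return(empty)
  candidate_genes <- unique(candidate_genes)
  universe <- unique(unlist(db$terms, use.names = FALSE))
  known <- candidate_genes %in% universe
  if (any(!known)) {
    log_info(sum(!known), " candidate gene(s) outside the background ",
             "dropped before enrichment")
  }
  cand <- candidate_genes[known]
  N <- db$background
  n <- length(cand)
  rows <- lapply(names(db$terms), function(term) {
    genes <- db$terms[[term]]
    m <- sum(cand %in% genes)
    if (m == 0) return(NULL)
    M <- length(genes)
    data.frame(term_id = term, N = N, M = M, n = n, m = m,
               p_value = hypergeom_p(N, M, n, m),
               rich_factor = m / M, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  res$q_value <- bh_adjust(res$p_value)
  res$significant <- res$q_value <= q_cutoff
  res <- res[order(res$p_value, res$term_id),
             c("term_id", "N", "M", "n", "m", "p_value", "q_value",
               "rich_factor", "significant")]
  rownames(res) <- NULL
  res
}

#' Tally annotation records by region and mutation class
#'
#' @param annotations annotation data frame ([read_annotation()]).
#' @return `list(region_class = , mutation_class = )`, named integer counts
#'   over the closed vocabularies (zeros included); the region-class counts
#'   sum to the number of records.
#' @export
tally_annotation_classes <- function(annotations) {
  tab_over <- function(x, vocab) {
    t <- table(factor(x, levels = vocab))
    setNames(as.integer(t), vocab)
  }
  list(region_class = tab_over(annotations$region_class, REGION_CLASSES),
       mutation_class = tab_over(annotations$mutation_class,
                                 MUTATION_CLASSES))
}
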