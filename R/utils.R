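# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

REGION_CLASSES <- c("exonic", "intronic", "ncRNA", "UTR5", "UTR3",
                    "intergenic", "splicing")
MUTATION_CLASSES <- c("synonymous", "non-synonymous", "stopgain", "stoploss")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("bsaed_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_parse <- function(...) {
  stop(structure(class = c("bsaed_parse_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Atomic write: writer(fun) gets a temp path in the same directory, which is
# renamed over `path` only on success.
write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("failed to write ", path)
  }
  invisible(path)
}

log_info <- function(...) message("[bsaed] ", ...)

# log-sum-exp for stable tail sums of log-probabilities
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

site_id <- function(chrom, pos) paste0(chrom, ":", pos)
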