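# The ED statistic, its fourth power, the per-chromosome smoother, the
# median + 3 SD threshold, region calling and candidate selection.

test_that("pool_frequencies normalizes counts per pool", {
  s <- make_site(high = c(12, 0, 8, 0), low = c(20, 0, 0, 0))
  fr <- pool_frequencies(s)
  expect_equal(fr$high[1, ], c(A = 0.6, C = 0, G = 0.4, T = 0))
  expect_equal(fr$low[1, ], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(rowSums(fr$high), 1, ignore_attr = TRUE)
  zero <- make_site(high = c(0, 0, 0, 0))
  expect_error(pool_frequencies(zero), "zero-depth")
})

test_that("compute_ed matches hand-evaluated cases", {
  f <- c(0.25, 0.25, 0.25, 0.25)
  expect_equal(compute_ed(f, f), 0)
  expect_equal(compute_ed(c(1, 0, 0, 0), c(0, 0, 0, 1)), sqrt(2))
  expect_equal(compute_ed(c(0.75, 0.25, 0, 0), c(0.25, 0.75, 0, 0)),
               sqrt(0.5))
  expect_equal(ed_to_association(sqrt(2)), 4)
  expect_equal(ed_to_association(sqrt(0.5)), 0.25)
  expect_equal(ed_to_association(0), 0)
  expect_error(ed_to_association(-0.1), "non-negative")
})

test_that("ED is symmetric, bounded and zero iff vectors are equal", {
  set.seed(101)
  h <- random_freqs(500)
  l <- random_freqs(500)
  ed_hl <- compute_ed(h, l)
  expect_equal(ed_hl, compute_ed(l, h))
  expect_true(all(ed_hl >= 0 & ed_hl <= 2))
  expect_true(all(compute_ed(h, h) < 1e-12))
  expect_true(all(ed_hl[rowSums(abs(h - l)) > 1e-6] > 0))
})

test_that("ed and ed4 agree with the term-by-term oracle to 1e-12", {
  set.seed(202)
  h <- random_freqs(1000)
  l <- random_freqs(1000)
  want <- ed_oracle(h, l)
  expect_equal(compute_ed(h, l), want, tolerance = 1e-12)
  expect_equal(ed_to_association(compute_ed(h, l)), want^4,
               tolerance = 1e-12)
})

test_that("the smoother reproduces constants and lines", {
  set.seed(7)
  scores <- data.frame(chrom = "chr1", pos = sort(sample.int(1e6, 200)),
                       ed4 = 0.37)
  fit <- fit_local_polynomial(scores, span = 0.1, degree = 2)
  expect_equal(fit$fitted, rep(0.37, 200), tolerance = 1e-9)

  scores$ed4 <- 1 + 2e-6 * scores$pos
  fit <- fit_local_polynomial(scores, span = 0.1, degree = 1)
  expect_equal(fit$fitted, scores$ed4, tolerance = 1e-6)

  # chromosomes are fitted independently
  two <- rbind(transform(scores, chrom = "chr1", ed4 = 0.1),
               transform(scores, chrom = "chr2", ed4 = 0.9))
  fit2 <- fit_local_polynomial(two, span = 0.1)
  expect_equal(unique(round(fit2$fitted[two$chrom == "chr1"], 9)), 0.1)
  expect_equal(unique(round(fit2$fitted[two$chrom == "chr2"], 9)), 0.9)

  # too few sites: chromosome mean with a warning
  tiny <- data.frame(chrom = "chrU", pos = c(1, 2, 3), ed4 = c(1, 2, 3))
  expect_warning(ft <- fit_local_polynomial(tiny, degree = 2),
                 "chromosome mean")
  expect_equal(ft$fitted, rep(2, 3))
})

test_that("the smoother recovers a noisy plateau, vs a one-point WLS oracle", {
  set.seed(42)
  n <- 10000
  pos <- sort(runif(n, 1, 1e7))
  center <- 5000
  plateau <- (center - 49):(center + 50)
  ed4 <- rnorm(n, 0, 0.05)
  ed4[plateau] <- ed4[plateau] + 0.5
  scores <- data.frame(chrom = "chr1", pos = pos, ed4 = ed4)
  fit <- fit_local_polynomial(scores, span = 0.02, degree = 2)
  expect_lt(abs(fit$fitted[center] - 0.5), 0.1)

  # independent tricube-weighted quadratic least squares at that one point
  x0 <- pos[center]
  q <- ceiling(0.02 * n)
  d <- abs(pos - x0)
  h <- sort(d)[q]
  w <- (1 - pmin(d / h, 1)^3)^3
  sel <- which(w > 0)
  xs <- (pos[sel] - x0) / h
  X <- cbind(1, xs, xs^2)
  beta <- solve(t(X) %*% (w[sel] * X), t(X) %*% (w[sel] * ed4[sel]))
  expect_lt(abs(fit$fitted[center] - beta[1]), 0.02)
})

test_that("compute_threshold implements median + 3 * sample SD", {
  expect_equal(compute_threshold(rep(0.3, 50))$threshold, 0.3)
  thr <- compute_threshold(c(0, 0, 0, 1))
  expect_equal(thr$median_fitted, 0)
  expect_equal(thr$sd_fitted, 0.5)
  expect_equal(thr$threshold, 1.5)
  step <- c(rep(0, 9900), rep(0.5, 100))
  expect_equal(compute_threshold(step)$threshold, 3 * sqrt(24.75 / 9999))
  expect_error(compute_threshold(0.4), "at least 2")
})

test_that("call_regions finds maximal above-threshold runs", {
  scores <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40),
                       fitted = c(0.1, 0.2, 0.2, 0.1))
  r <- call_regions(scores, 0.15)
  expect_equal(nrow(r), 1)
  expect_equal(r$start_pos, 20)
  expect_equal(r$end_pos, 30)
  expect_equal(r$n_snps, 2)

  expect_equal(nrow(call_regions(scores, 0.5)), 0)

  # gap bridging: one below-threshold site inside a run
  scores2 <- data.frame(chrom = "chr1", pos = 1:5 * 10,
                        fitted = c(0.3, 0.1, 0.3, 0.3, 0.05))
  expect_equal(nrow(call_regions(scores2, 0.2)), 2)
  r2 <- call_regions(scores2, 0.2, max_gap_snps = 1)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$n_snps, 3)  # the bridged site is not a member
  expect_equal(r2$start_pos, 10)
  expect_equal(r2$end_pos, 40)

  # minimum region size
  expect_equal(nrow(call_regions(scores2, 0.2, min_region_snps = 2)), 1)
})

test_that("select_candidates applies both marker cuts inside regions only", {
  scores <- data.frame(
    chrom = "chr1", pos = c(10, 20, 30, 40), ref = "A", alt = "G",
    ed = c(1.2, 0.4, 1.2, 1.2), ed4 = c(1.2, 0.4, 1.2, 1.2)^4,
    fitted = c(0.9, 0.9, 0.9, 0.0),
    high_alt_freq = c(0.9, 0.9, 0.6, 0.9),
    low_alt_freq = 0.1, stringsAsFactors = FALSE)
  regions <- call_regions(scores, 0.5)
  expect_equal(regions$n_snps, 3)
  ann <- data.frame(chrom = "chr1", pos = 10, ref = "A", alt = "G",
                    gene_id = "ASMT", region_class = "exonic",
                    mutation_class = "non-synonymous", aa_change = "E/Q",
                    stringsAsFactors = FALSE)
  cand <- select_candidates(regions, scores, ann)
  # pos 10 passes both cuts; 20 fails ED; 30 fails frequency; 40 is outside
  expect_equal(cand$pos, 10)
  expect_equal(cand$gene_id, "ASMT")
  # boundary values are strict
  scores$ed[1] <- 0.5
  expect_equal(nrow(select_candidates(regions, scores, NULL)), 0)
})
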