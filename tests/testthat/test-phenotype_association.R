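# Trait grouping, bulk selection, genotype summaries and the Pearson
# marker-trait test.

test_that("trait groups use inclusive-low / strict-high boundaries", {
  rec <- data.frame(animal_id = paste0("A", 1:3),
                    milk_trait = c(0.3, 0.7, 1.2),
                    blood_trait = c(0.1, 0.2, 0.3))
  g <- classify_trait_groups(rec)
  expect_equal(as.character(g$labels), c("low", "mid", "high"))
  expect_equal(sum(g$proportions), 1)

  edge <- data.frame(animal_id = c("A", "B"),
                     milk_trait = c(0.5, 1.0), blood_trait = c(0, 0))
  ge <- classify_trait_groups(edge)
  expect_equal(as.character(ge$labels), c("low", "mid"))

  empty <- classify_trait_groups(rec[0, ])
  expect_length(empty$labels, 0)
  expect_error(classify_trait_groups(rec, low_max = 2, high_min = 1),
               "low_max")
  # channel selection
  gb <- classify_trait_groups(rec, channel = "blood")
  expect_equal(as.character(gb$labels), c("low", "low", "low"))
})

test_that("select_bulks picks phenotype extremes with a stable tie-break", {
  # the six sequenced animals' printed milk values
  rec <- data.frame(
    animal_id = c("A1-1", "A1-2", "A1-3", "A2-1", "A2-2", "A2-3"),
    milk_trait = c(2.05, 2.09, 3.53, 0.67, 0.55, 0.72),
    blood_trait = c(1.04, 0.80, 0.70, 0.26, 0.52, 0.47))
  b <- select_bulks(rec, k = 3)
  expect_equal(b$high, c("A1-3", "A1-2", "A1-1"))
  expect_equal(b$low, c("A2-2", "A2-1", "A2-3"))

  b1 <- select_bulks(rec, k = 1)
  expect_equal(b1$high, "A1-3")
  expect_equal(b1$low, "A2-2")
  expect_error(select_bulks(rec, k = 4), "at least 8")

  tie <- data.frame(animal_id = c("B2", "B1", "B3", "B4"),
                    milk_trait = c(1, 1, 0.2, 0.1),
                    blood_trait = 0)
  expect_equal(select_bulks(tie, k = 1)$high, "B1")

  # property: the two bulks never overlap
  set.seed(77)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    r <- data.frame(animal_id = sprintf("X%02d", 1:n),
                    milk_trait = round(runif(n), 1), blood_trait = 0)
    bb <- select_bulks(r, k = 3)
    expect_length(intersect(bb$high, bb$low), 0)
  }
})

test_that("genotype proportions and per-genotype means are exact", {
  gt <- data.frame(animal_id = sprintf("A%03d", 1:100),
                   marker_id = "m147316",
                   genotype = c(rep("GG", 87), rep("CC", 4), rep("CG", 9)))
  p <- genotype_proportions(gt, "m147316")
  expect_equal(p$proportions[["GG"]], 0.87)
  expect_equal(p$proportions[["CC"]], 0.04)
  expect_equal(p$proportions[["CG"]], 0.09)
  expect_equal(p$dominant, "GG")
  expect_equal(sum(p$proportions), 1)

  gt$genotype[1] <- NA
  p2 <- genotype_proportions(gt, "m147316")
  expect_equal(p2$n, 99)
  expect_equal(sum(p2$proportions), 1)
  expect_error(genotype_proportions(gt[1, ], "m147316"), "non-missing")

  single <- data.frame(animal_id = "A1", marker_id = "m", genotype = "CT")
  expect_equal(genotype_proportions(single, "m")$proportions[["CT"]], 1)

  ph <- data.frame(animal_id = c("A1", "A2", "A3"),
                   milk_trait = c(5.0, 6.2, 1.0), blood_trait = 0)
  g3 <- data.frame(animal_id = c("A1", "A2", "A3"), marker_id = "m",
                   genotype = c("CC", "CC", "GG"))
  m <- per_genotype_trait_means(g3, "m", ph)
  expect_equal(m[["CC"]], 5.6)
  expect_equal(m[["GG"]], 1.0)
  expect_error(per_genotype_trait_means(
    data.frame(animal_id = "ZZ", marker_id = "m", genotype = "CC"),
    "m", ph), "phenotype")
})

test_that("the Pearson dosage test handles perfect and degenerate input", {
  ph <- data.frame(animal_id = sprintf("A%d", 1:6),
                   milk_trait = c(1, 2, 3, 1, 2, 3), blood_trait = 1)
  gt <- data.frame(animal_id = sprintf("A%d", 1:6), marker_id = "m",
                   genotype = c("AA", "AG", "GG", "AA", "AG", "GG"))
  r <- marker_trait_pearson(gt, "m", ph)
  # allele counts tie (6 A, 6 G): the tie-break counts A, so r is -1
  expect_equal(abs(r$pearson_r), 1)
  expect_lt(r$p_value, 1e-6)
  expect_equal(r$n_used, 6)
  r2 <- marker_trait_pearson(gt, "m", ph, alt_allele = "G")
  expect_equal(r2$pearson_r, 1)

  const <- gt
  const$genotype <- "AA"
  expect_error(marker_trait_pearson(const, "m", ph), "constant genotype")
  ph2 <- ph
  ph2$milk_trait <- 2
  expect_error(marker_trait_pearson(gt, "m", ph2), "constant trait")

  # carrier coding collapses dosages 1 and 2
  rc <- marker_trait_pearson(gt, "m", ph, coding = "carrier",
                             alt_allele = "G")
  expect_true(rc$pearson_r < 1)
})

test_that("validate_markers tests every marker and can BH-adjust", {
  set.seed(11)
  n <- 60
  ph <- data.frame(animal_id = sprintf("A%02d", 1:n),
                   milk_trait = rnorm(n, 1, 0.2), blood_trait = 1)
  dos <- rbinom(n, 2, 0.4)
  ph$milk_trait <- ph$milk_trait + 2 * dos
  gstr <- function(d, ref = "G", alt = "C") {
    a <- ifelse(d == 2, alt, ref)
    b <- ifelse(d == 0, ref, alt)
    paste0(pmin(a, b), pmax(a, b))
  }
  gt <- rbind(
    data.frame(animal_id = ph$animal_id, marker_id = "causal",
               genotype = gstr(dos)),
    data.frame(animal_id = ph$animal_id, marker_id = "null",
               genotype = gstr(rbinom(n, 2, 0.4))),
    data.frame(animal_id = ph$animal_id, marker_id = "degenerate",
               genotype = "AA"))
  expect_message(res <- validate_markers(gt, ph), "skipped")
  expect_equal(nrow(res), 2)
  expect_equal(res$marker_id[which.min(res$p_value)], "causal")
  resq <- suppressMessages(validate_markers(gt, ph, adjust = TRUE))
  expect_true(all(resq$q_value >= resq$p_value - 1e-15))
})
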