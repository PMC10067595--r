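---
title: "bsaed: methods, parameters and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bsaed: methods, parameters and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsaed)
```

## The problem and the model

Bulked segregant analysis for a quantitative trait starts from a phenotyped
cohort: the animals at the two tails of the trait distribution are pooled
into a high bulk and a low bulk, each sequenced as one sample. At a causal
locus (and at linked markers), the allele frequencies of the two pools
diverge; elsewhere they share the cohort's background frequency and differ
only by sampling noise.

`bsaed` scores each biallelic SNP by the Euclidean distance between the two
pools' four-base read-frequency vectors,

$$\mathrm{ED} = \sqrt{\sum_{b \in \{A,C,G,T\}} (f_{\mathrm{mut},b} -
  f_{\mathrm{wt},b})^2},$$

where the "mutant" pool is the high-trait bulk and the "wild-type" pool the
low-trait bulk (ED is symmetric, so this mapping only fixes vocabulary).
For two pools that differ only in the ref/alt balance, ED reduces to
$\sqrt{2}\,|\Delta f_{alt}|$, so it is bounded by $\sqrt 2$ at complete
divergence; the implementation's bound of 2 covers arbitrary unit-interval
input. Some printed renditions of this formula show plus signs inside the
C, G and T terms; a statistic with plus signs is nonzero for identical
pools and is not a distance, so all four terms are squared differences
here.

ED is raised to the fourth power. Squaring twice is a deliberately crude
noise gate: background ED at depth $d$ is of order $\sqrt{1/d}$, so ED⁴
scales as $1/d^2$ for noise while staying $O(1)$ at a true divergence.

### Smoothing and the threshold

The per-SNP ED⁴ values are smoothed along each chromosome with a
tricube-weighted local polynomial (`stats::loess`), degree 2, with the span
expressed as a fraction of that chromosome's SNPs (default 0.05). Fitting
is per chromosome; the association threshold is global: the **median plus
three sample standard deviations** (n−1 denominator) of the fitted values
over all retained sites genome-wide. Associated regions are maximal runs of
consecutive SNPs whose fitted value strictly exceeds the threshold;
candidate SNPs are in-region sites with high-pool alternate frequency
strictly above 0.75 and raw ED strictly above 0.5 (the frequency/ED cuts
apply to the raw quantities, not the smoothed track — the smoothed track
decides *where* the regions are, the raw values decide *which* SNPs inside
them are reportable markers).

### Site filters and genotype calls

Before scoring, three filters run in a fixed order, and each removed site
is attributed to the first rule it matches: (1) non-biallelic sites — more
than two distinct observed alleles; (2) sites where any single base holds
≥ 95% of the wild (low) pool's reads, i.e. near-fixed and uninformative;
(3) sites under 10X depth in either pool. Boundary semantics are read
literally: 95% inclusive, 10X strict.

Per-sample genotype classification from pooled frequencies (used for
reporting, not for the scan): depth < 5 is missing; alternate frequency
≥ 0.8 homozygous-alt, ≤ 0.2 homozygous-ref; in between, heterozygous only
when both alleles carry at least 4 reads, else missing. Depth is the sum of
allele depths (AD), not the DP field, so the call and the frequency always
share a denominator; DP is retained for reporting only.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `wt_fixation_cutoff` | 0.95 | fraction | wild-pool fixation filter, inclusive |
| `min_pool_depth` | 10 | reads | per-pool depth floor, strict |
| `span` | 0.05 | fraction of chrom SNPs | loess window; 0.05 of a dense scan covers a linkage-scale neighborhood |
| `degree` | 2 | — | local quadratic follows peak curvature without chasing noise |
| `threshold_k` | 3 | SDs | median + 3 SD association threshold |
| `max_gap_snps` | 0 | SNPs | below-threshold SNPs bridgeable inside a region |
| `min_region_snps` | 1 | SNPs | minimum member SNPs per region |
| `freq_cut` | 0.75 | fraction | candidate high-pool alt-frequency cut, strict |
| `ed_cut` | 0.5 | ED | candidate raw-ED cut, strict |
| `q_cutoff` | 0.05 | — | BH-adjusted significance for enrichment |

## Enrichment and marker validation

Candidate genes (the unique annotated genes of the candidate SNPs) are
tested per term with the exact upper-tail hypergeometric probability

$$P(X \ge m) = 1 - \sum_{i=0}^{m-1}
  \frac{\binom{M}{i}\binom{N-M}{n-i}}{\binom{N}{n}},$$

computed as a log-space tail sum (stable to $N \sim 10^5$), where $N$ is
the background (all genes with annotation, taken from the gene-set file),
$M$ the term size, $n$ the candidate count and $m$ the overlap. Terms with
$m = 0$ are excluded from the testing family; the remaining p-values are
BH-adjusted ("Q values", cutoff 0.05 inclusive) — BH is the conventional
reading of an unnamed "correction for multiple tests" that reports Q
values. The rich factor is $m/M$.

Marker validation regresses the trait on allele dosage: genotypes are coded
0/1/2 copies of the alternate allele — by default the *minor* allele at the
marker, since validated markers of this design are typically rare
homozygote effects; the counted allele is overridable — and tested with the
Pearson correlation (two-sided t, $n-2$ df). Degenerate inputs (constant
dosage or trait) raise errors rather than NaN. No multiplicity correction
is applied by default across the handful of validation markers, matching
raw `p < 0.05` usage; a BH flag exists.

Trait-side grouping uses the cohort conventions: low group 0–0.5 ng/mL
(inclusive), high group > 1 ng/mL (strict), and the two bulks are the top
and bottom `k = 3` animals by milk value with ties broken by ascending
animal id.

## The synthetic world

`sim_config()` states the simulated world; its defaults *are* the test
conditions and are not tuned per test:

* two chromosomes of 10 Mb with 10,000 SNPs each at uniformly random
  positions;
* one causal locus (chr1, center 5 Mb, half-width 1 Mb): inside it, the
  expected pool frequencies interpolate **linearly** from the shared
  background to core values 0.85 (high) / 0.15 (low) — the simplest
  monotone linkage-decay shape that produces a peaked ED track;
* background alternate frequency Uniform(0.2, 0.8) per site, shared by both
  pools, so the 95% wild-pool filter removes only a known tail;
* per-pool depth Poisson(30) — an overdispersion-free baseline matching
  ~30X resequencing; alternate reads Binomial(depth, p);
* miscalls at rate 0.001 per read, redistributed uniformly over the three
  other bases (symmetric in the four-base ED geometry);
* a 103-animal cohort with Hardy–Weinberg dosages at the causal marker
  (allele frequency 0.25, so dosage-2 animals exist in a cohort of this
  size), milk trait = 0.8 + 4.0·dosage + N(0, 0.1) ng/mL truncated at zero
  — dosage-2 animals sit ~5-fold above the non-carrier baseline, the
  validated-marker contrast scale of this study design; the blood trait
  follows the same dosage effect at half scale with its own noise,
  mimicking the weaker blood/milk agreement of real cohorts.

A consequence of representing counts through VCF allele depths: the writer
emits every non-reference base carrying reads as an ALT allele, so a site
with a single miscalled read becomes triallelic and is removed by the
biallelic filter (~5–10% of sites at these settings). This is
self-consistent — `n_alleles` counts distinct observed alleles — and is
precisely the situation the "non-secondary allele" filter exists for.

What the generator does **not** emulate: read-level artifacts (mapping
error, strand bias, base-quality structure), indels, overdispersed depth
(a negative-binomial hook is left in the config), LD structure beyond the
single linear-decay causal block, relatedness among animals, and any
correlation between the background SNPs and the trait. A green recovery
test therefore establishes that the statistics and plumbing are correct on
data satisfying the model's own assumptions — not that the pipeline is
robust to real-data pathologies.

## Numerical choices

* ED and ED⁴ are plain vectorized arithmetic; equality tests against the
  independent term-by-term oracle hold to 1e−12.
* `loess` with `surface = "interpolate"` (the default) is used even for
  large chromosomes; on exactly polynomial input of matching degree it
  reproduces the polynomial to machine precision, and against a directly
  solved single-point tricube WLS it agrees to well under the test
  tolerances. Chromosomes with fewer than `degree + 2` sites fall back to
  their mean with a warning; spans smaller than the minimum workable
  window are silently enlarged to `(degree + 2)/n`.
* All threshold/cut comparisons are strict (`>`) except the two inclusive
  boundaries the rules state (95% fixation, purity 0.8/0.2, Q ≤ 0.05).
* Region membership excludes gap-bridged below-threshold SNPs, so the
  "all members above threshold" invariant holds for any `max_gap_snps`.
* Determinism: every stochastic step is seeded from one integer seed;
  phenotypes, annotations, gene sets and genotype tables use fixed offsets
  (+1…+4) of the same seed so stages can be regenerated independently.

## Known limitations

**The median+3SD threshold is crossed on signal-free genomes.** Under the
null (no causal locus), the smoothed ED⁴ track is a non-negative,
right-skewed, strongly autocorrelated process. The fraction of sites above
its own median+3SD is about 0.4–1.3% in simulation (a Gaussian track would
give 0.13%), and with 20,000 sites *some* excursion exceeds the threshold
in nearly every null genome — so at least one (small, low-peak) region is
called in roughly 9 of 10 signal-free simulations. This is a property of
the thresholding rule, not of the implementation: the threshold is
computed from the same track it is applied to, and 3 SDs is not an
extreme-value bound. Practical consequences: region calls on real data
should be ranked by peak fitted value (the planted-signal tests recover
the causal region as the *top* region in 10/10 seeds with zero non-causal
SNPs inside regions), and a genuinely null genome will still yield a
handful of marginal regions. Raising `threshold_k`, requiring
`min_region_snps` > 1, or permutation-calibrating the threshold would
control this, but the package keeps the stated rule as its default.

**Other limitations.** The wild-pool fixation filter uses the low bulk
only (as specified); swapping bulk labels changes which near-fixed sites
survive. The enrichment background comes from the gene-set file, so genes
absent from every term silently shrink the universe. The Pearson
validation test assumes additivity; a recessive effect at low allele
frequency loses power under dosage coding (carrier coding is available).
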