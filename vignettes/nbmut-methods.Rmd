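---
title: "Methods: somatic spectrum, driver and germline burden analysis with nbmut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic spectrum, driver and germline burden analysis with nbmut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbmut)
```

`nbmut` implements the computational analysis that sits downstream of
tumor-normal variant calling in exome studies of clinically aggressive
neuroblastoma: filtering raw calls to a high-confidence somatic set,
characterizing the mutation spectrum and its signature composition,
prioritizing candidate driver genes from per-mutation pathogenicity
scores, testing pathways for enrichment of pathogenic mutations, and
testing cancer-predisposition genes for a germline rare-variant burden
against control cohorts. This vignette documents the statistical model
behind each stage, the tunable parameters and their defaults, the
numerical choices, and what the bundled synthetic-cohort generator does
and does not emulate.

## Somatic filtering

Variant callers emit raw calls that mix true somatic events with germline
leakage and sequencing artifacts. `filter_somatic_variants()` applies a
cascade of six rules in a fixed order — minimum tumor and normal depth,
minimum alt-supporting tumor reads, minimum tumor VAF, maximum normal
VAF, dbSNP membership, and functional class — and attributes every
rejected call to the *first* rule it failed, so rejection audits are
reproducible and sum exactly to the number of calls removed.

The default thresholds (tumor depth ≥ 14, normal depth ≥ 8, ≥ 4 alt
reads, tumor VAF ≥ 0.10, normal VAF ≤ 0.05, dbSNP excluded) approximate
common VarScan2-era tumor-normal practice; the exact thresholds of any
given study are rarely portable, so every one is a named argument of
`filter_config()`. "Non-silent" throughout the package means missense,
nonsense, splice-site, frameshift and in-frame indel — silent and
noncoding calls never contribute to driver or carrier statistics.
Filtering is idempotent, and relaxing any one threshold can only grow the
retained set; both properties are enforced by tests.

`classify_subgroup()` encodes the clinical stratification used for
reporting: `hr_event3` is a high-risk patient with any adverse event
(progression, relapse, death) within 36 months of diagnosis, boundary
inclusive; all other samples map directly to their risk group.

## Mutation spectrum and signatures

Single-nucleotide variants are classified by substitution type and
flanking bases into the standard 96 trinucleotide classes. Mutations
reported on the purine strand are reverse-complemented so every class has
a pyrimidine (C or T) reference base; the 192 strand-resolved
possibilities collapse two-to-one onto the 96 classes (verified by
exhaustive enumeration in the tests). Bin order is the COSMIC
lexicographic order — substitution class major, then 5′ base, then 3′
base — so spectra interoperate with published signature tables.

Signature exposures are fitted by non-negative least squares: with `f`
the frequency-normalized spectrum and `P` the 96 × k reference profile
matrix, `decompose_signatures()` minimizes ‖f − Pw‖₂ over w ≥ 0
(via `pracma::lsqnonneg`) and reports the weights renormalized to sum
to 1, i.e. the percentage contribution of each mutational process. NNLS
was chosen because it is the standard attribution method when the study's
own fitting procedure is unreported, and because it is verifiable against
a brute-force grid search over the exposure simplex — the test suite
checks agreement at a 10⁻³ grid step. The residual 2-norm is reported so
a poor fit is visible; it can never exceed the best single-signature fit.

Cross-dataset spectrum comparison uses cosine similarity on
frequency-normalized spectra, the field's usual profile-similarity
statistic.

The two bundled reference profiles (`example_signatures()`) are
deterministic *synthetic* stand-ins: a C>T profile peaked at NpCpG
(emulating spontaneous deamination of 5-methylcytosine, the ubiquitous
age-related process) and a broad C>A profile with TpCpT emphasis
(emulating the process reported as characteristic of neuroblastoma). They
are not reproductions of any published signature matrix; analyses of real
data should load the appropriate published profiles with
`read_signature_matrix()`.

## Driver-gene prioritization

Per-mutation pathogenicity p-values (CHASM-style, scoring the
probability that a missense change increases tumor fitness, and
VEST-style, scoring functional impact) are **inputs**: the package does
not re-implement these classifiers. `gene_level_p()` aggregates a gene's
mutation p-values either by Fisher's combination (−2Σlog p ~ χ²₂ₖ; the
default, matching the convention of the CRAVAT tool family) or by a
Bonferroni-corrected minimum p, offered for sensitivity analysis.
Gene-level false discovery rates are Benjamini–Hochberg step-up
(`bh_fdr()`, a validated wrapper over `stats::p.adjust`), and a gene is
called significant only under the dual gate **CHASM FDR < 0.25 and VEST
FDR < 0.10** — both thresholds exposed as arguments. Carrier frequency is
the number of distinct mutated samples over the assayed total, reported
additionally rounded to one decimal percent, the convention for printed
frequencies (4 of 99 prints as 4.0%, 14 of 99 as 14.1%).

Mutation p-values of exactly zero are clamped to 10⁻³⁰⁰ with a warning
(log-space safety); a gene none of whose mutations carry a usable score
is excluded with a warning rather than silently scored.

## Pathway enrichment

Mutated genes are ranked by −log₁₀ of the CHASM-style gene p-value
(ties broken lexicographically, so rankings are reproducible), and
preranked GSEA is run against user-supplied gene sets (GMT).
`enrichment_score()` is the classic weighted Kolmogorov–Smirnov running
sum: hits increment by |score|^w normalized over hits (w = 1 by default,
the "weighted" statistic; w = 0 gives the unweighted KS), misses
decrement by 1/(N − N_hits), and the enrichment score is the extremum by
absolute value.

Because the ranking is a single mutation-derived list, phenotype
permutation is impossible; the null is **gene-label permutation** (set
membership assigned to random list positions, scores fixed). The nominal
p-value compares the observed score against same-sign permutation scores
with an add-one estimator, so it is never zero, is bounded below by
1/(n_perm + 1), and is uniform under the null — the test suite checks
calibration by a Kolmogorov–Smirnov test over 500 null sets. NES divides
the observed score by the mean same-sign permutation score, and FDR
follows the canonical pooled-NES procedure (all sets' permutation NES
pooled per sign). With all-positive or all-negative permutation nulls the
affected side's NES is reported as `NA` rather than fabricated.

`pathway_carrier_summary()` reports the pathway-level carrier count,
frequency, mutation count, and the mutual-exclusivity fraction — the
share of carrier samples with exactly one mutated pathway gene.

## Germline rare-variant burden

Candidate germline variants are filtered to a curated
cancer-predisposition gene list, stripped of common polymorphisms via the
dbSNP flag, and kept only when the VEST-style p-value is *strictly* below
0.10 (a value exactly at the threshold is rejected). Per-gene carrier
counts are then tested against each control cohort with a two-sided
Fisher's exact test and against all cohorts pooled.

Two numerical choices matter here:

* **Two-sidedness by the minimum-likelihood rule.** The p-value sums all
  hypergeometric point probabilities over the fixed-margin support that do
  not exceed the observed table's probability (relative tolerance
  1 + 10⁻⁷), evaluated in log space. This is the only two-sided rule
  consistent with published per-cohort values such as 0.116 for a table
  whose one-sided tail is ≈ 0.078. The implementation is validated
  against both `stats::fisher.test` and an independent
  binomial-coefficient enumeration oracle to 10⁻⁹ over random tables with
  margins up to 1,000.
* **Pooling, not p-value combination.** The combined test sums control
  with/without counts across cohorts and runs one exact test against the
  pooled 2×2 table. Pooling reproduces published combined values (e.g.
  0.0004 and 0.0078) that Fisher's method on the three per-cohort
  p-values does not.

`fold_enrichment()` is the case carrier frequency over the pooled-control
carrier frequency, with a pseudocount of 1 added to the control carriers
only when no control carries a variant (otherwise the ratio is
undefined). The published fold column is not exactly recoverable from the
printed counts under any single pseudocount scheme, so the bundled
fixture (`table1_counts()`) carries the printed values as data
(`printed_fold`) while the function computes the transparent ratio.

A gene can reach a small pooled p-value on the strength of one control
cohort alone. `top_burden_genes()` therefore selects candidates the way
the published analysis did: every per-cohort p-value strictly below a
suggestive 0.10 (any cut between the largest qualifying value, 0.058, and
the smallest non-qualifying one, 0.106, selects the same genes on the
bundled table), ordered by combined p. On the bundled counts this yields
BARD1, AXIN2, CHEK2 — whereas raw combined-p ordering would rank MC1R
third despite its unconvincing per-cohort evidence (p = 0.298 and 0.116
in two of three cohorts).

## The synthetic cohort generator

All inputs the pipeline consumes can be simulated
(`simulate_somatic_variants()`, `simulate_pathogenicity_scores()`,
`simulate_carrier_tables()`), so every stage is testable without access
to restricted sequencing archives. The generator emulates a small
aggressive-neuroblastoma exome study; its defaults are fixed study
conditions, not tuning knobs:

* 17 tumor-normal pairs; per-sample mutation counts ~ Poisson(17);
* trinucleotide context classes drawn from a 0.532/0.468 mixture of the
  C>T-deamination-like and C>A-like synthetic profiles, reported on a
  random strand so canonicalization is exercised;
* tumor VAF ~ Beta(8, 12) — clonal mutations in tumors of roughly 75%
  purity — at ~110× depth; normal alt reads ~ Binomial(depth, 0.002);
* passenger pathogenicity p-values ~ Uniform(0, 1); planted driver genes
  draw from Beta(1, 50), concentrated near zero;
* germline carrier counts ~ Binomial(cohort size, per-cohort frequency),
  with one planted burden gene (case frequency 0.077 vs 0.003 in
  controls) among equal-frequency genes.

Determinism is structural: a single integer seed plus a stable polynomial
hash of each sample id (or gene name) derives independent RNG substreams,
so output is byte-identical across runs and the first k samples of a
larger cohort equal a k-sample cohort — properties the tests assert. The
generator's RNG use never leaks into the caller's session state.

What the simulation does *not* model: genomic positions are uniform
placeholders (no chromatin- or replication-timing covariates), there is
no subclonal architecture, no copy-number or structural variation, no
correlation between pathogenicity score and VAF, and contexts are drawn
as classes rather than extracted from a reference genome. Passing tests
therefore demonstrate the correctness and calibration of the statistical
machinery under the stated generative model, not robustness to every
artifact of real sequencing data.

## Problem sizes and reproducibility

The test-suite and acceptance checks use problem sizes chosen to make
sampling error negligible relative to each tolerance: 50,000 context
draws for exposure recovery (±0.02), 500 null sets × 200 permutations
for GSEA calibration and 1,000 permutations for planted-set detection,
1,000 random 2×2 tables with margins up to 1,000 for the exact-test
oracle, and a 99-sample cohort for end-to-end planted-structure recovery.
`scripts/acceptance.R` reruns the headline computations from scratch with
any seed and writes the resulting numbers as JSON.

## Known limitations

* CHASM/VEST scores are consumed, never computed; studies without such
  scores cannot use the driver or germline stages as-is.
* Indels are carried through filtering and counted for carriers, but only
  SNVs enter the 96-context spectrum (indels have no substitution
  context).
* The GSEA FDR is the canonical pooled-NES estimate; with very few gene
  sets it is coarse, and it is not monotone in the nominal p-value by
  construction.
* Per-gene assayed case totals may legitimately differ (a gene covered by
  two platforms has more assayed cases); `burden_report()` warns rather
  than errors, and the warning is expected on the bundled table.
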