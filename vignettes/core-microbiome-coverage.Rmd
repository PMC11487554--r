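---
title: "Core-microbiome extraction, biobank coverage, and clinical association: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core-microbiome extraction, biobank coverage, and clinical association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coremicro)
```

## The problem

Culturomics projects isolate and deposit bacterial strains from a host
cohort, then ask how well that culture collection represents the cohort's
metagenomes and which taxa matter clinically. `coremicro` implements the
analytical chain around those questions on two governing per-taxon axes:

* **mean relative abundance** (mean RA, percent): the arithmetic mean of a
  taxon's compositional share over *all* samples, zeros included;
* **prevalence / frequency of occurrence** (FO, percent): the fraction of
  samples in which the taxon is detected above a detection floor.

Everything downstream — abundance strata, the core definition, coverage
stratification — is a thresholding of these two statistics.

## Model and definitions

An abundance table is compositional: each sample column is closed to
100 %. `normalize_to_relative()` performs the closure and refuses all-zero
columns (they carry no compositional information; silently producing `NaN`
would poison every downstream mean). Closure is idempotent, and genus
aggregation (summing member species) conserves per-sample totals.

Strata, on cohort-mean abundance, are **nested**: *high* means mean
RA ≥ 1 %, *medium-above* means ≥ 0.2 % (and therefore contains *high*),
*low* is the rest. Nesting matters for coverage denominators: the
medium-above selector of `stratified_coverage()` includes the high
stratum, which is the only reading under which published stratum counts of
the form "59 medium-above containing 25–26 high" are coherent.

The **core microbiome** is the intersection of two inclusive gates:
dominant (mean RA ≥ `medium_cut`, default 0.2 %) and common
(FO ≥ `prevalence_cut`, default 80 %). Sources in this literature
alternate between `≥` and `>` at these boundaries; we standardize on
inclusive `≥` everywhere — the Results-style wording rather than
figure-legend wording — and expose every threshold in `strata_config()` so
the choice is visible and reversible. The ranked core list orders by mean
RA descending with an alphabetical tie-break, for determinism.

Mean RA includes zeros. Averaging only over samples where a taxon occurs
would inflate rare, sporadic taxa across the dominance gate and make the
two axes redundant. Strata are computed on cohort means, not per sample:
a per-sample alternative exists but produces sample-dependent strata,
which the coverage denominators cannot use.

The detection floor defaults to 0 (strictly positive abundance counts as
present) because the input contract is an already-thresholded profiler
table; metagenomic noise floors vary by pipeline, so the floor is
configurable rather than fixed. Prevalence is monotonically non-increasing
in the floor.

## Name matching and coverage

Matching cultured species against metagenomic taxon names is string-based:
case-folded, whitespace-collapsed, underscores mapped to spaces, trailing
"sp."-style qualifiers dropped. Genus abbreviations are *not* expanded —
expanding "Blt." to "Blautia" correctly requires a curated list we do not
have, and a wrong expansion is worse than a missed match. Synonyms are an
explicit, user-extensible equivalence relation (`synonym_map()`, closed
symmetrically and transitively via union–find); the default map carries the
single reassignment most relevant here, *Phocaeicola vulgatus* =
*Bacteroides vulgatus*. No external taxonomy service is consulted:
matching is reproducible offline by construction.

Coverage percentages are reported at one decimal, rounded
**half-away-from-zero in exact integer arithmetic** (`round1()`): the
convention that reproduces the full family of internally consistent
published count-ratio figures (55/59 → 93.2, 25/26 → 96.2, 145/280 → 51.8,
81/132 → 61.4, 135/480 → 28.1, 58/86 → 67.4, 18/20 → 90.0). Two published
figures are arithmetically inconsistent with their own counts
(32/33 rounds to 97.0, not 96.9; 61/101 to 60.4, not 59.4); the package
reports what the counts give and documents the discrepancy rather than
imitating it.

`mass_coverage()` — the share of total abundance mass carried by cultured
taxa — is a deliberate, labelled approximation of sequence-level
(read-mapping) coverage. It requires no reads or genomes, but it credits a
whole taxon's mass to a single cultured representative, so it should never
be quoted as a read-mapping result.

## Rank statistics

**Spearman.** rho is the Pearson correlation of mid-ranks (average ranks
on ties). For `n_used ≤ 10` the two-sided p-value is exact: the package
enumerates all `n!` assignments of one rank vector (blocking on the first
position so at most `(n−1)!` rows are materialized at once) and counts
assignments whose centred rank product is at least as extreme as observed.
This handles ties correctly, where the classical Edgeworth/AS89 p-values do
not. Above `n = 10` (3.6 M permutations is the practical limit in R) the
usual t approximation on `n − 2` degrees of freedom is used. Pairs with a
missing value in either member are deleted pairwise, and at least four
complete pairs are required. Because the statistic is rank-based, strictly
monotone transforms of either variable — including log transforms of
abundances — leave (rho, p) unchanged; correlations are therefore computed
on raw relative abundances.

**Wilcoxon rank-sum.** The statistic is the mid-rank sum of group A. When
`choose(n_a + n_b, n_a) ≤ 1e5` the null is enumerated exhaustively over all
group labelings of the pooled mid-ranks: exact, and valid under ties. The
cap, rather than a pure group-size rule, is the package's design choice: a
"small" group of 8 against a cohort of 1000 still implies ~10^19 labelings,
while the cap admits every balanced design up to 8 vs 8 (C(16,8) = 12870)
and many unbalanced ones. Beyond the cap, the normal approximation with
tie correction and a 0.5 continuity correction is used; for tie-free
groups of 5–8 per arm the two routes agree within 0.02 (measured), while
3–4 per arm always take the exact path anyway. Two-sided p is the null
probability of a rank-sum deviation at least as large as observed.
Direction is reported by median difference.

**Stars and multiplicity.** Stars follow the strict figure-legend bins
(`p < 0.05/0.01/0.001/0.0001` → `*` to `****`; `p = 0.05` gets no star).
The association matrix is uncorrected by default — matching how such
matrices are typically reported — with Benjamini–Hochberg q-values as an
explicit opt-in; BH never yields `q < p` and preserves the p-ordering.

## The synthetic cohort generator

`simulate_cohort()` draws a zero-inflated log-normal community: taxon *i*
is present in a sample with probability π_i; when present its latent
abundance is LogNormal(μ_i, σ_i); columns are closed to 100 %. This is the
minimal model exhibiting the two governing axes independently — occurrence
(→ prevalence) and latent scale (→ mean RA) — and is *not* a claim about
the true generative process of gut metagenomes. In particular it has no
taxon–taxon correlation beyond closure, no overdispersion structure, no
sequencing noise, and samples are exchangeable. A green recovery test
therefore establishes that the estimators read back the planted
parameters under the stated model, not that they are robust to real-data
pathologies.

Default stated world (150 taxa; cohorts of 96 and 1153, the two-cohort
design being emulated; σ = 1 throughout):

* **10 planted core taxa**: π = 0.95, latent mass 30 → expected closed
  mean RA ≈ 5 %, far above the 0.2 % gate; expected FO 95 % against the
  80 % gate. With n = 96, both margins are many binomial/log-normal
  standard errors wide, which is what "planted" should mean.
* **5 abundant-but-infrequent taxa**: π = 0.4, mass 100 — dominant yet not
  common, so core extraction must reject them on prevalence alone.
* **10 cohort-differential taxa**: π = 0.9 in both cohorts, mass 0.4
  (common but never dominant), and cohort B's latent abundance multiplied
  by `differential_fold = 0.25`. High occurrence is required for a rank
  test on whole columns to see an abundance fold at all: at low π the
  test is dominated by occurrence sampling noise, which the fold does not
  shift. A 4-fold depletion of a common commensal is a realistic strong
  effect.
* **135 background taxa**: π evenly spaced in [0.05, 0.5], mass 0.8 →
  expected mean RA ≈ 0.05 %, a 4-fold margin below the dominance cut.
* **3 planted clinical correlations** on rank scores (so Spearman's
  monotone invariance makes the slope interpretable): ESR = 20 + 40·score
  + N(0, 8) (mm/h scale), CRP = 5 + 25·score + N(0, 5) (mg/L),
  IL-10 = 6 − 3·score + N(0, 1) (pg/mL). `age` (N(55, 12) years) and
  `anti_CCP` (log-normal, U/mL) are always generated independently of
  every taxon and serve as built-in negative controls.
* **Roster**: 60 % of taxa, plus 20 cultured-only novel species that the
  metagenome never detects (exercising the undetected-cultured
  complement).

One global seed feeds four derived per-artifact streams (cohort A, cohort
B, clinical, roster), so adding an artifact never perturbs earlier ones and
identical spec + seed gives byte-identical TSV output. The truth record
stores planted *parameters* only — never computed flags — so recovery
checks cannot be tautological.

## Numerical and degenerate-input choices

* Closure tolerance 1e-9 (relative); `round1()` uses integer arithmetic
  scaled by 10, with no floating-point rounding step.
* Empty strata report `percent = NULL` rather than 0 or NaN.
* An all-zero sample column, an empty name, an unknown taxon, fewer than 4
  complete pairs, or zero rank variance each raise a typed error naming
  the offender; nothing degrades silently.
* p-values from normal/t approximations are clamped to ≥ 1e-300 so the
  (0, 1] contract and star annotation stay valid at machine extremes.
* In the astronomically unlikely event that a simulated sample contains no
  taxon at all, the most prevalent taxon is seeded at unit latent mass
  rather than failing the closure invariant.

## Limitations

* Coverage is name-based; a cultured strain "covers" a taxon regardless of
  strain-level divergence, and matching quality is bounded by the synonym
  map supplied.
* `mass_coverage()` approximates, and must not be quoted as, sequence-level
  coverage.
* The simulator omits compositional correlation structure and batch
  effects; calibration results transfer to real data only to the extent
  the rank statistics are distribution-free (exact under exchangeability).
* Core extraction at genus rank is computed on the genus-aggregated table,
  not by rolling up species-level core flags; the two can differ and the
  former is the documented behaviour.
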