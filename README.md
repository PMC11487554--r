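# coremicro

Cohort-level gut-microbiome profiling for culturomics studies: given a
taxa × sample relative-abundance table, a cultured strain biobank roster,
and per-sample clinical metadata, `coremicro` answers three questions that
recur whenever a culture collection is built from a patient cohort:

1. **Which taxa form the core microbiome?** A taxon is *dominant* when its
   mean relative abundance over all samples is ≥ 0.2 %, *common* when its
   prevalence (frequency of occurrence, FO) is ≥ 80 % of samples, and
   *core* when both hold — the dual-threshold definition
   `core(i) ⇔ mean RA(i) ≥ c_a ∧ FO(i) ≥ c_p`, with both gates inclusive
   and configurable.
2. **How completely does the biobank cover the metagenome?** Stratified
   count coverage (taxa with mean RA ≥ 0.2 % are *medium-above*, ≥ 1 %
   *high*; strata are nested), the cultured-but-undetected complement,
   abundance-mass coverage, and cross-biobank unique species — all with
   synonym-aware species-name matching (e.g. *Phocaeicola vulgatus* =
   *Bacteroides vulgatus*).
3. **Which core taxa track clinical indices?** Spearman rank correlation
   (exact permutation p for n ≤ 10, t approximation above) per
   (taxon, index) pair, Wilcoxon rank-sum comparison between cohorts
   (exhaustive labeling enumeration when feasible, tie-corrected normal
   approximation otherwise), the `*`/`**`/`***`/`****` star convention
   (p < 0.05 / 0.01 / 0.001 / 0.0001, strict), and optional
   Benjamini–Hochberg correction.

A seeded zero-inflated log-normal simulator (`synthetic_spec()` /
`simulate_cohort()`) generates two-cohort studies (disease n = 96,
reference n = 1153 by default) with planted core taxa, planted
cohort-differential taxa and planted monotone clinical correlations, so the
whole chain is testable without any external download; `truth_check()`
measures recovery of every planted effect.

## Worked example

```r
library(coremicro)

## deterministic worked example: 480 detected species, 280-species biobank
ex <- coverage_example()
prof <- taxon_profiles(ex$species_table)
stratified_coverage(prof, ex$roster, stratum = "medium_above")
#> coverage [species rank, medium_above stratum]: 55/59 (93.2%)
stratified_coverage(prof, ex$roster, stratum = "high")
#> coverage [species rank, high stratum]: 25/26 (96.2%)
undetected_cultured(ex$roster, rownames(ex$species_table))$percent
#> [1] 51.8   # 145 of 280 cultured species never detected

## synthetic two-cohort study, end to end
sim <- simulate_cohort(synthetic_spec(n_samples_B = 200, seed = 42))
core <- extract_core(sim$table_A)
core
#> core_result (species rank): 15 dominant, 20 common, 10 core of 150 taxa
#>   top core: Genus009 species009, Genus008 species008, Genus006 species006, ...
assoc <- associate_all(sim$table_A, sim$clinical, taxa = core)
head(assoc[order(assoc$p_value), c("taxon", "index", "rho", "p_value", "star")], 3)
#>                taxon index        rho      p_value star
#>  Genus002 species002   CRP  0.8613172 2.158306e-29 ****
#>  Genus001 species001   ESR  0.8209085 1.336081e-24 ****
#>  Genus003 species003 IL_10 -0.7328504 2.111642e-17 ****
truth_check(sim)
#> core_recovered 1, core_exact TRUE, differential_detected 1, assoc_detected 1
```

The coverage lines read "covered/total (one-decimal percent)": of the 59
species at mean RA ≥ 0.2 %, 55 have a cultured representative. The
association rows show that the three planted monotone clinical effects
(ESR +, CRP +, IL-10 −) are recovered with the correct sign, and
`truth_check()` confirms exact recovery of all planted core,
differential and association effects.

## Command line

```sh
Rscript inst/scripts/coremicro-cli.R simulate --seed 1 --out-dir sim/
Rscript inst/scripts/coremicro-cli.R core --table sim/cohortA.tsv --k 5 --out core.tsv
Rscript inst/scripts/coremicro-cli.R coverage --table sim/cohortA.tsv --roster sim/roster.csv --out cov.json
Rscript inst/scripts/coremicro-cli.R associate --table sim/cohortA.tsv --clinical sim/clinical.tsv --out assoc.tsv
```

File formats: abundance TSV with a `#rank=species|genus` pragma and a
`taxon` first column (percent units); roster CSV with
`strain_id,species,genus,family,phylum,novel,deposits`; clinical TSV with a
sample-ID first column, numeric index columns and an optional `cohort`
column; synonym CSV with `name_a,name_b`.
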