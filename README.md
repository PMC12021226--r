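# rbcldiet

Diet analysis from fecal DNA metabarcoding of a short chloroplast *rbcL*
barcode region, built around a curated local reference database.

## The problem

Identifying what a small herbivore or omnivore eats from its feces is done by
amplifying a short plant barcode (here a ~262 bp *rbcL* fragment) from fecal
DNA, sequencing it deeply, and matching the resulting amplicon sequence
variants (ASVs) against reference sequences. Two things make this hard in
practice:

* **Reference curation.** Public sequences are self-reported and sometimes
  misidentified; trap bait (e.g. barley and walnut) leaves DNA that must not
  be counted as diet; and congeneric plants often share identical barcode
  sequences, so a match frequently cannot be resolved to species.
* **Read-level noise.** Sequencing errors, two-parent chimeras and ambient
  contamination produce spurious ASVs that must be filtered before counting.

`rbcldiet` implements the complete workflow as tested, reusable R functions:

1. **Reference database** (`build_database`, `classify_resolution`,
   `flag_bait_confounded`): trim pool sequences to the barcode region
   between primer anchors, deduplicate into unique entries with merged
   source-species sets, drop blacklisted accessions, classify each entry as
   species-specific / genus-shared / family-shared / unassignable, and
   exclude taxa indistinguishable from bait.
2. **ASV processing** (`dereplicate`, `remove_chimeras`,
   `filter_low_frequency`, `rarefy_table`, `rarefaction_curve`): exact
   dereplication, removal of ASVs that decompose exactly into a prefix and a
   suffix of two more abundant parents, per-sample exclusion of ASVs below
   1.0% of the sample's reads (strict), and seeded rarefaction to a common
   depth (default 1,000 reads).
3. **Taxonomic assignment** (`assign_asv`, `assign_table`,
   `lowest_common_rank`): global-alignment percent identity against the
   local database first, falling back to an external pool below the 98%
   gate; exact ties resolve to the lowest common ancestor of the tied
   species; bait matches and ecologically implausible out-of-area matches
   are excluded with recorded reasons.
4. **Diet summaries** (`build_diet_table`, `frequency_of_occurrence`,
   `resolution_summary`, `growth_form_summary`, `taxa_per_sample`): a
   sample-by-taxon presence table and the standard frequency-of-occurrence
   (FO) statistics, per season and overall.
5. **Community statistics** (`dissimilarity`, `nmds`, `permanova`,
   `shannon_re_curve`, `coverage_estimate`, `steel_dwass`): Bray–Curtis and
   Jaccard indices, Kruskal stress-1 NMDS, one-factor PerMANOVA,
   coverage-based rarefaction/extrapolation of Hill-1 diversity
   (exp Shannon) with bootstrap CIs, and Steel–Dwass all-pairs tests —
   all implemented in the package (vegan is used only as an independent
   cross-check in the tests).
6. **Synthetic data** (`sim_config`, `generate_flora`, `generate_samples`):
   a seeded generator with controlled within-genus/within-family sequence
   divergence, multinomial seasonal diet profiles, substitution errors,
   chimeras, bait and contaminant reads — with full ground truth, so every
   stage is testable without downloads.

The package ships a machine-readable transcription of the published diet
table of the motivating field study (72 plant taxa, 43 families, 100 fecal
samples; `load_table1()`), used to validate the summary statistics.

## Worked example

```r
library(rbcldiet)
cfg <- sim_config(seed = 42)          # 24 samples, 2000 reads, default noise
fl  <- generate_flora(cfg)
sim <- generate_samples(fl)
dbs <- sim_databases(fl)
out <- run_pipeline(sim$reads, sim$metadata, dbs$local, dbs$fallback,
                    fl$flora, pipeline_config(seed = 42))
print(out$rarefied)
#> ASV table [rarefied]: 24 samples x 11 ASVs
#>   reads: total 24000, per-sample median 1000
print(out$assignments)
#> ASV assignments: 11 ASVs; local tier 11 (100.0%)
#>                status count percent
#>              assigned     9    81.8
#>         excluded_bait     2    18.2
#>  excluded_implausible     0     0.0
#>            unassigned     0     0.0
```

Eleven ASVs survive filtering: nine diet taxa and two bait sequences, which
are recognized and excluded. Frequency of occurrence recovers the simulated
profiles (five core taxa in every sample, one season-specific taxon in a
quarter of them):

```r
head(frequency_of_occurrence(out$diet)[, c("label", "rank", "overall", "overall_pct")])
#>                label    rank overall overall_pct
#> 1 Genus01a species01 species      24         100
#> 2 Genus01a species02 species      24         100
#> 3 Genus01a species03 species      24         100
#> 4 Genus01b species01 species      24         100
#> 5 Genus01b species02 species      24         100
#> 6 Genus01b species03 species       6          25
```

Seasonal structure in read abundances is detected by PerMANOVA on the
Bray–Curtis index:

```r
rel <- out$rarefied$counts / rowSums(out$rarefied$counts)
d <- dissimilarity(rel, "bray_curtis")
permanova(d, out$diet$samples$season, permutations = 999, seed = 42)
#> PerMANOVA: F = 43.608 (df 3, 20), R2 = 0.867, p = 0.0010 (999 permutations)
```

The season-specific taxa drive 87% of the abundance variation, and no
permutation of the labels reaches the observed F, so p sits at the
1/(permutations + 1) floor.

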