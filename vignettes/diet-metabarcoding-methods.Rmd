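---
title: "Methods: diet metabarcoding with a curated local rbcL database"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diet metabarcoding with a curated local rbcL database}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcldiet)
```

## The analysis in one paragraph

Fecal samples yield merged amplicon reads of a ~262 bp chloroplast *rbcL*
fragment. Reads are dereplicated into exact amplicon sequence variants
(ASVs), cleaned of two-parent chimeras and of per-sample low-frequency
variants, and rarefied to a common depth. Each surviving ASV is matched
against a curated local reference database built from the study area's
flora; matches at or above a 98% global-alignment identity gate are
accepted, ties are resolved to the lowest common ancestor (LCA) of the tied
species, and ASVs failing locally are retried against an external sequence
pool subject to ecological-plausibility and bait filters. The resulting
sample-by-taxon presence table supports frequency-of-occurrence summaries
and community statistics: Bray–Curtis/Jaccard dissimilarity, NMDS,
PerMANOVA, coverage-based rarefaction/extrapolation of Shannon diversity,
and Steel–Dwass all-pairs comparisons of per-sample taxon richness.

## Reference database curation

`build_database()` trims pool sequences to the barcode region (when primer
anchors are supplied, each anchor is located by a brute-force Hamming scan
tolerating up to 2 mismatches — deliberately simple and fully testable,
rather than alignment-based trimming), deduplicates identical trimmed
sequences into unique entries with merged source-species sets, and drops
accessions named in a user-supplied blacklist. Misidentification detection
itself (e.g. tree-based checks of public accessions) is treated as curation
*input*, not computation: the blacklist records its outcome.

Each unique entry is classified by its source-species set: one species →
`species_specific`; several species in one genus → `genus_shared`; one
family → `family_shared`; several families → `unassignable`. The class
percentages are reported to one decimal over the unique-entry count.

**Bait confound rule.** Bait species (trap bait such as barley and walnut)
can leave DNA in feces. An in-area species whose *every* unique sequence is
also carried by a bait species is indistinguishable from bait and is
excluded together with the bait species. A species that retains at least
one bait-free sequence stays in: this generalizes the published
single-instance rule ("exclude what cannot be told apart from bait") to the
distinguishability criterion, which is this package's design choice; the
retained-when-distinguishable branch is exercised in the tests.

Species with no usable sequence are reported as uncovered, never silently
dropped. The package reports its own coverage accounting and does not
attempt to reproduce the motivating study's exact species bookkeeping,
whose published totals are not fully arithmetic in the text.

## ASV processing

The stage order is fixed: `dereplicate` → `remove_chimeras` →
`filter_low_frequency` → `rarefy_table`. No stage creates a new ASV, and
each stage logs per-sample read accounting.

* **Dereplication** is exact: a learned error model is intentionally not
  fitted. The synthetic error rate (default 1e-3 per base) is low enough
  that true variants dominate and error reads, which scatter over many
  distinct single-substitution variants, fall below the low-frequency
  threshold. This mirrors the workflow's reliance on the 1% filter for
  contamination control.
* **Chimera removal** targets two-parent bimeras: an ASV is removed iff two
  same-length parents exist in the same sample, each at ≥ 2× its abundance,
  and a split point k where the ASV equals one parent over 1..k and the
  other over k+1..end, both exactly. The 2× multiplier follows the default
  spirit of the standard denoising tools; the upstream description names no
  parameters, so the multiplier is exposed as `min_fold`.
* **Low-frequency filter**: a cell is zeroed iff its count is *strictly*
  below 1.0% of the sample's total (a count at exactly 1.0% is retained),
  applied per sample, matching the quoted definition of the rule.
* **Rarefaction** subsamples exactly `depth` reads (default 1,000) per
  sample, uniformly without replacement; a seed is required, and samples
  below the depth are dropped with a warning. The source workflow does not
  state how sub-depth samples were handled (all of its samples passed);
  dropping with a warning is this package's policy.
* **Rarefaction curves** use the exact hypergeometric expectation
  E[S_m] = Σ_i [1 − C(n−n_i, m)/C(n, m)], computed on the log-choose
  scale, not Monte Carlo. The tests verify that Monte-Carlo rarefaction
  means converge to this closed form.

## Taxonomic assignment

Percent identity is global Needleman–Wunsch alignment (match +1, mismatch
−1, linear gap −2 per position, end gaps penalized; engine: Biostrings),
with identity = matching columns / alignment columns × 100. Because the
simulator is substitution-only over a fixed-length region, identity reduces
to Hamming identity there, which the test suite exploits as an independent
oracle.

Decision flow per ASV: best local-tier identity ≥ 98% → resolve; otherwise
try the fallback tier; otherwise `unassigned`. Boundary and tie policies,
where the source material is ambiguous, are fixed as follows:

* **Gate boundary.** The upstream description says both "more than 98%"
  (pass) and "less than 98%" (fail); exactly 98.0% is treated as a pass
  (≥), and the gate is configurable.
* **Tie set.** Entries within 1e-9 of the best identity are tied (exact
  ties only); heuristic near-ties (bit-score style) are not emulated. The
  tie set's source species union feeds the LCA; shuffling database order
  never changes an assignment (tested).
* **Exclusions.** Bait and bait-confounded species are removed from the
  candidate set first; if nothing remains the ASV is `excluded_bait`. On
  the fallback tier, species not flagged as in-area and not on the planted
  allow-list are removed next; if nothing remains, `excluded_implausible`.
  The allow-list makes ecological judgement an explicit input (e.g. planted
  ornamentals counted as food) while the filter mechanics stay computed.
* A surviving tie set spanning multiple families yields no assignment.

Distinct ASVs resolving to the same taxon are collapsed only at the diet
table, preserving per-ASV provenance. Family-rank taxa with identical names
but different tie sets receive numbered labels ("Fagaceae-1", "Fagaceae-2")
ordered by decreasing overall occurrence — the published tables use such
labels without defining the numbering; frequency ordering is this package's
rule.

## Summaries and the packaged reference table

Frequency of occurrence divides per-taxon detection counts by the number of
samples per season and overall. Percentages print to one decimal using
half-up rounding (6.25 → 6.3), the convention of the published tables,
rather than R's round-half-even. Seasons bin by collection month: Mar–May
spring, Jun–Aug summer, Sep–Nov autumn, Dec–Feb winter; seasonal sample
sizes of the packaged table (22/35/32/11 of 100) are taken from the study's
reported captures, not recomputed.

`load_table1()` ships the transcribed reference diet table (72 taxa, 43
families, 50 woody) and validates on load that every row's overall count
equals the sum of its seasonal counts. The tests further verify that every
printed percentage is recomputable from its count and seasonal n.

## Community statistics

All statistics are implemented in the package; vegan and base R's exact
rank tests serve only as independent cross-checks in the test suite.

* **Dissimilarity.** Bray–Curtis on relative read abundances,
  Σ|x−y| / Σ(x+y); Jaccard on presence/absence, 1 − |A∩B| / |A∪B|.
* **NMDS.** Kruskal stress-1 minimized by iterative majorization (Guttman
  transform) alternated with monotone regression of configuration distances
  on the dissimilarity order. Ties in the dissimilarities follow Kruskal's
  primary approach: within a tie block the fitted values are ordered by the
  current configuration distances before the pool-adjacent-violators pass,
  so ties are never forced equal. Default 20 starts (classical scaling
  first, then random), convergence at 1e-6 stress change, deterministic
  given the seed. A stress above 0.2 flags an unreliable configuration, the
  conventional rule of thumb; the package does not implement the
  visualization-time outlier removal used in the motivating study's
  figures, whose criterion was never defined — a documented gap.
* **PerMANOVA.** SS_total = Σ_{i<j} d²_ij / N; within-group sums analogously
  per group; pseudo-F = (SS_among/(g−1)) / (SS_within/(N−g)); p-value with
  the +1 correction, never exactly zero. The type-I error rate is verified
  against the binomial 99% band over 200 null simulations.
* **Coverage and diversity.** Sample coverage uses the singleton/doubleton
  plug-in Ĉ = 1 − (f1/n)·(n−1)f1/((n−1)f1 + 2f2). The
  rarefaction/extrapolation curve reports the Hill number of order 1
  (exp Shannon; q is configurable but 1 is the default and the only value
  used here). Interpolation uses the exact expected entropy of a
  without-replacement subsample — by linearity of expectation this equals
  the enumeration mean over all subsamples, which the tests assert to
  1e-12. Extrapolation is anchored at the observed point and approaches an
  asymptote as 1/size: H(n+m*) = H∞ − (H∞ − H(n))·n/(n+m*), with H∞ the
  observed entropy plus a Miller–Madow-style correction (Ŝ_Chao1 − 1)/(2n).
  The exact extrapolation family used by the reference implementation in
  the literature is not specified in the source material; this anchored
  1/size form is the package's documented choice, verified against the
  brute-force subsample oracle on the interpolation side where an exact
  answer exists. Confidence intervals are percentile bootstrap (default
  1,000 replicates) resampling reads multinomially from the observed
  relative abundances; the unseen-species bootstrap adjustment is
  deliberately omitted — a documented simplification that narrows CIs
  slightly for very incomplete samples.
* **Steel–Dwass.** For each group pair, the rank sum on the pooled pair
  with midranks, standardized with the tie-corrected variance and referred
  to the studentized-range distribution with k = number of groups. At k = 2
  its p-values are verified to order identically to the exact Wilcoxon
  test.

## The synthetic-data generator

The generator exists so that every downstream stage can be validated
against known truth. Its defaults describe the study conditions the package
is tested under: a 262 bp region; 24 samples cycling through four seasons
at 2,000 reads each; per-base substitution error 1e-3; 2% chimeras, 5%
bait reads, 1% contaminants. The flora default (4 families × 3 genera × 3
species) is deliberately small; divergence defaults (13 substitutions
within genus, 30 within family) make congeners species-resolvable (identity
249/262 ≈ 95.0%, below the 98% gate) while `within_genus_div = 0`
constructs genus-ambiguous databases on demand.

Divergence semantics: each non-reference sequence differs from its
genus/family reference by *exactly* the configured number of substitutions,
applied on position blocks disjoint within the parent, so identity
arithmetic in the tests is exact. Pairs of two non-reference congeners may
differ by up to twice the configured distance.

Seasonal diet profiles default to five core species (weights 0.30/0.22/
0.18/0.12/0.08) shared by all seasons plus one season-specific species at
0.10 — chosen so every profile taxon clears the 1% filter by a wide margin
while seasonal turnover exists for the community statistics to detect.
Chimeras join a prefix and suffix of two diet reads of the same sample at a
uniform breakpoint (matching per-sample bimera-removal semantics); the
error model is substitution-only (no indels), keeping identity arithmetic
exact over the fixed-length region; FASTQ qualities are constant
placeholders (Q37).

What passing tests on this generator do **not** show: realistic platform
error profiles (quality-dependent, indel-bearing), PCR amplification bias,
index hopping, paired-end merge artifacts, or the taxonomic breadth of a
real flora (hundreds of species with irregular shared-haplotype structure).
Results on synthetic data demonstrate the correctness of the computations,
not field-level recall.

## Problem sizes and reproducibility

The test suite and the acceptance script run the full pipeline at 24
samples × 2,000 reads (≈1 minute), the PerMANOVA calibration at 200 null
datasets × 999 permutations, the LCA oracle over all 6,195 subsets of size
≤ 4 of a 20-species flora, and Monte-Carlo cross-checks at 1,000
replicates — sizes chosen to exercise every code path while keeping a full
run comfortably interactive. Every stochastic stage takes an explicit
integer seed and restores the caller's RNG state; identical seeds produce
byte-identical outputs end to end, including written FASTA/FASTQ.

## Known limitations

* Identity search is exhaustive alignment against every database entry
  (with an exact-match fast path); fine at curated-database scale, not a
  BLAST replacement for millions of references.
* The fallback tier models the public repository as an offline FASTA pool;
  live retrieval is out of scope.
* PerMANOVA is one-factor only, as the analysis requires.
* Extrapolated diversity beyond ~2n, and its bootstrap CIs, inherit the
  simplifications noted above and should be read qualitatively.
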