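---
title: "Comparative evolution of MSL complex binding sites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative evolution of MSL complex binding sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mslevo)
```

## The biological problem

The MSL (male-specific lethal) complex — MSL1, MSL2, MSL3, MOF and MLE plus
the roX RNAs — mediates dosage compensation in *Drosophila* by upregulating
the single male X roughly two-fold. MSL2 binds the X almost exclusively, but
MOF and MSL1 also occupy thousands of autosomal sites where they likely act
outside dosage compensation. `mslevo` implements a comparative pipeline for
binding sites of these proteins in two species: which sites are shared,
which are lineage-specific gains, whether dosage-compensation (DC) and
non-DC sites differ in their signatures of adaptive evolution, whether
transposable elements (TEs) supplied new sites, and whether nearby genes
diverged in expression.

## Interval conventions and the three overlap criteria

All coordinates are 0-based, half-open (the BED convention); readers convert
on ingest and writers convert back. Three distinct overlap criteria recur in
this analysis and are kept explicit throughout (`satisfies()`):

* **reciprocal-half** — the common region is larger than half of the region
  covered by *each* site (strict `>`); used to call a MOF/MSL1 site DC
  (overlapping MSL2) versus non-DC.
* **either-half** — the common region is larger than half of *either* peak
  (strict `>`); used when merging adjacent peaks (`merge_peaks()`), a single
  sorted left-to-right pass in which merging is transitive.
* **one-sided at-least-half** — at least half (non-strict `>=`) of a site's
  region, projected into the partner species, overlaps a region bound by the
  same protein there; used for conservation calls.

The wording differs between "larger than half" and "at least half" in the
source procedures, so the strictness is per-rule and configurable; for odd
lengths the half-length is kept as an exact rational (`len/2`) compared
against the integer overlap, avoiding off-by-one asymmetry. A fourth
criterion, **center-within**, asks only whether the center/summit of one
feature lies inside the other (half-open) and is the default for
cis-regulatory element overlap.

## Cross-species projection

Orthology between the two coordinate systems is a set of one-to-one
(reciprocal-best) alignment blocks, non-overlapping on both sides. The
native format is a 7-column block TSV; a converter from UCSC chain files is
provided (`chain_to_ortholog_map()`), but block semantics — no per-block
indels — are the contract, because the analysis only needs interval-level
orthology. `project_interval()` intersects a query with the blocks, maps
each piece proportionally (strand-aware) and returns the minimal spanning
interval on one destination chromosome. Where pieces land on several
chromosomes the one carrying the largest projected length wins, ties broken
lexicographically — a documented choice; reciprocal-best chains rarely split
a 300-bp site. Fractional projected coordinates are floored/ceiled outward
so a non-empty piece never collapses to zero length.

## Turnover and conservation

For each bound region we search the highest linear fold-enrichment (FE)
inside the region in its own species and inside the orthologous region in
the other species, the latter extended by half its length on each side
(`extend_interval()`, factor 0.5 per side). A site is **absent** in the
partner when the orthologous signal is reduced 10-fold or more — on linear
FE, `other <= own/10`, boundary inclusive per the literal "or more". A peak
with zero own signal makes absence vacuous and is flagged and called
present. **Conservation** instead projects the focal site into the partner's
coordinates and applies the one-sided at-least-half rule against the union
of same-protein peaks there; unmappable sites are counted species-specific
but reported separately so no information is lost. The half-length
extension applies only to the presence/absence signal search, not the
conservation overlap, as the procedures describe. The direction (project
focal into partner) is the default and configurable by swapping arguments
with the inverted map.

## The extended McDonald–Kreitman framework

For a class of sites (e.g. "MOF non-DC autosomal") we tabulate, from
ingroup allele counts and one outgroup allele per site
(`classify_variant()`, `tabulate_site_classes()`):

* `D` — divergent sites: fixed in the ingroup and different from the
  outgroup (sites polymorphic in the ingroup are never D, keeping D and P
  disjoint);
* `P` — polymorphic sites; `P_nosingleton` excludes variants whose minor
  allele occurs exactly once in the sample (singletons are enriched for
  sequencing error and weakly deleterious variants);
* `L` — the class length in bp.

Sites without an outgroup allele are unusable; sites with more than two
ingroup alleles are counted once as polymorphic and flagged. Four-fold
degenerate third codon positions (`fourfold_sites()`, strand-aware, derived
from the standard genetic code) serve as the neutral control, and X-linked
controls are paired with X-linked site classes, autosomal controls with
autosomal classes, because the X and the autosomes experience different
evolutionary forces.

The fraction of adaptive fixations is the standard extended-MK estimator

$$\alpha = 1 - \frac{D_{neutral}\,P_{selected}}{D_{selected}\,P_{neutral}},$$

with singleton-excluded P on both sides (the with-singleton column is
available via a flag). Alpha is at most 1 and can be negative when
segregating weakly deleterious variation inflates P relative to D.
Significance comes from a two-sided Fisher's exact test on the 2×2
divergence/polymorphism table; per-gene MK tests on
non-synonymous/synonymous counts are corrected with Benjamini–Hochberg
(`gene_mk()`). The package ships the published per-class count table
(`msl_mk_counts()`) as a worked input: every printed D/P ratio and alpha
value reproduces from those counts to 3 decimal places, which is exactly
what `scripts/acceptance.R` recomputes.

## TE annotation cleaning and family enrichment

Raw repeat hits are cleaned in four steps (`clean_te_annotation()`): drop
hits overlapping microsatellites; union-merge overlapping hits of the same
family; resolve cross-family overlaps by prioritising the longest insertion
and iteratively truncating the common region from shorter ones (when
truncation splits an insertion, the longest surviving fragment is kept —
a documented choice preserving the longest-first principle); drop anything
under 100 bp. After cleaning, insertions of different families never
overlap, which the tests assert.

A binding site is TE-derived under one of two selectable rules: at least
half the binding region overlaps a single insertion (`half_overlap`,
default) or the summit falls inside an insertion (`center_in_te`). The two
rules appear in different parts of the source analysis; reports always name
the rule used. Family enrichment is the log2 odds ratio

$$LOR = \log_2 \frac{n_{family}/L_{family}}{N_{genome}/G},$$

with enrichment at `LOR >= 1.5` (roughly a 3-fold density excess). Genome
size and family lengths are computed from the annotation, never hard-coded.
Motif occurrences in consensus sequences (`motif_count()`) are exact,
overlapping matches on both strands, deduplicated per start position — a
deliberate simplification that counts occurrences without a
position-weight-matrix significance model.

## Expression divergence

TPM values are averaged across replicates per species and sex; genes are
grouped by whether an unconserved non-DC site, a conserved non-DC site, or
no site overlaps the strand-aware window of 2 kb upstream plus the gene
body (any overlap of at least 1 bp — the grouping is about presence, not
overlap fraction), with TE presence tracked independently. Divergence of a
group is `1 - rho` (Spearman, average ranks for ties) between the two
species' mean-TPM vectors, with a gene-level bootstrap (default 1,000
draws) for its sampling distribution; groups under 3 genes give `NA`.
Group comparisons use a two-sided Mann–Whitney U test on the bootstrap
distributions. Bootstrap draws are resamples rather than independent
observations, so these p-values describe the separation of the bootstrap
distributions; the package mirrors this procedure rather than endorsing it.
Z-normalisation of expression changes uses the sample (n−1) standard
deviation, a documented convention. Whether the bootstrap should resample
genes or replicates was open; genes are resampled, consistent with the
group-level statistic.

## The synthetic-data generator

`sim_config()` fixes the study conditions under which the pipeline is
exercised: two species with five 1-Mb chromosomes (the first acting as the
X), ortholog blocks of 20 kb covering 90% of each genome, 2,000 peaks of
width 300 bp with log-normal fold enrichments clipped to at least 12 (so a
background-only ortholog at FE 1 is an unambiguous >10-fold reduction), a
10% species-specific gain fraction, 97% of MSL2 peaks on the X, neutral
divergent/polymorphic densities of 0.162/0.107 per bp with 20% singletons
(matching the scale of the published four-fold counts), a selected-class
polymorphism density of 0.02 per bp, and a TE landscape of 10 families in
which one family carries 8× the background site density. Expression noise
standard deviations (1.2 / 0.55 / 0.15 log units for unconserved-BS+ /
BS− / conserved-BS+ genes) order the planted divergence the way the
comparative analysis observes it. One master seed drives a named-substream
scheme, so adding a generator never perturbs the others and every output is
bit-reproducible.

The generator plants truth the estimators must recover, and the test suite
does so at these sizes: variant-count recovery of alpha in
{−0.5, 0, 0.5, 0.9} over 100 replicates at 1-Mb class lengths (mean within
±0.05); exact recovery of planted gain/DC labels; TE enrichment over 20
replicates (planted family at LOR 3 within ±0.3, and the only family over
1.5); and the divergence ordering with Mann–Whitney separation in at least
95% of 100 replicates at 500 genes per group. What the generator does *not*
emulate — read-level noise, indels, coalescent linkage, demography,
alignment error — bounds what these tests show about real data: they
validate the estimators and bookkeeping, not robustness to upstream
artefacts.

## Numerical and degenerate-input choices

* Peak merging sorts by (chrom, start, end), remaining ties by input order:
  deterministic output regardless of input order.
* `D/P = Inf` when `D > 0, P = 0`; `NA` when both are 0; alpha is `NA`
  whenever any of the four counts is 0; Fisher on an all-zero table is `NA`.
* Counts are held as doubles: the alpha cross-products exceed 32-bit
  integer range at genome scale.
* Singleton status is evaluated after dropping samples with missing calls;
  a two-allele site with minor count exactly 1 is a singleton.
* Unknown chromosome names class as "other" with a warning; the 4th
  chromosome is excluded from the autosome class.

## Known limitations

Peak calling, read mapping, variant calling, motif discovery with a
significance model, GO enrichment and whole-genome alignment construction
are all upstream of this package; it consumes their outputs. The genome-
scale published counts (thousands of sites per protein) require those raw
data and are not reproducible here — the package instead proves its
arithmetic on the published count table and its estimators on synthetic
data with known truth. Cis-element annotations must share one coordinate
system with the peaks; lift-over is out of scope and validated only by
chromosome-name intersection.
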