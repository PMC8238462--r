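# mslevo

Comparative analysis of MSL dosage-compensation-complex binding-site
evolution between two *Drosophila* species.

The MSL complex (MSL1, MSL2, MSL3, MOF, MLE plus the roX RNAs) upregulates
the single male X roughly two-fold. MSL2 targets the X almost exclusively,
but MOF and MSL1 also bind thousands of autosomal sites with likely
dosage-compensation-independent functions. `mslevo` is for evolutionary
genomicists who want to ask, from peak calls, fold-enrichment tracks, an
ortholog map, repeat annotations, population variants and expression
tables: which binding sites turned over between species, which are
dosage-compensation (DC) sites versus non-DC sites, how strong the
signature of positive selection is in each class, whether transposable
elements supplied new sites, and whether nearby genes diverged in
expression.

At its core sits the extended McDonald–Kreitman test. For a class of sites
with divergent count *D* (fixed differences against an outgroup) and
polymorphic count *P* (singletons excluded), compared with four-fold
degenerate sites as the neutral control, the fraction of adaptive
fixations is

    alpha = 1 - (D_neutral * P_selected) / (D_selected * P_neutral)

with a two-sided Fisher's exact test on the 2×2 (D, P) table. Around it the
package implements the field's interval rules (reciprocal-half,
either-half, one-sided at-least-half, center-within), peak merging,
interval projection through reciprocal-best ortholog blocks, the 10-fold
signal-reduction rule for site absence, TE-annotation cleaning with
longest-first truncation and log2 odds-ratio family enrichment,
cis-regulatory overlap, and expression divergence as `1 − ρ` (Spearman)
with a gene-level bootstrap. A fully seeded synthetic-data generator
(`sim_config()`, `simulate_*()`, `write_dataset()`) emulates every input
with known ground truth.

## Worked example

Alpha for autosomal MOF non-DC sites in *D. melanogaster* from the
published site-class counts shipped with the package:

```r
library(mslevo)
tab  <- msl_mk_counts()
sel  <- tab[tab$species == "mel" & tab$protein == "MOF" &
            tab$chrom_class == "A" & tab$site_type == "Non-DC", ]
neut <- tab[tab$species == "mel" & tab$protein == "MOF" &
            tab$chrom_class == "A" & tab$site_type == "4-fold", ]
sel$label <- "MOF non-DC (autosomes)"; neut$label <- "4-fold (autosomes)"
summary(mk_test(sel, neut))
#> 2x2 divergence/polymorphism table (singleton-excluded P):
#>                             D      P
#> MOF non-DC (autosomes)  23903   1285
#> 4-fold (autosomes)     458286 243823
#>
#> Extended McDonald-Kreitman test
#>   selected: MOF non-DC (autosomes)  D/P = 18.602
#>   neutral:  4-fold (autosomes)  D/P = 1.88
#>   alpha (fraction of adaptive fixations): 0.899
#>   Fisher's exact (two-sided) p: <2e-16
```

The D/P ratio of 18.6 against a neutral 1.88 means almost 90% of the fixed
differences in these sites are attributable to positive selection.

Cross-species turnover on synthetic data with a planted 10% gain fraction:

```r
cfg <- sim_config(seed = 1, n_peaks = c(MOF = 400, MSL1 = 0, MSL2 = 0),
                  dc_fraction = 0)
g     <- simulate_genomes(cfg)
ps    <- simulate_peaks_and_signal(cfg, g)
calls <- call_turnover(ps$peaks_a, ps$track_a, g$map, ps$track_b,
                       g$chrom_lengths_b)
table(calls$status)
#>  absent_in_other present_in_other
#>               36              364
sum(!ps$truth$conserved)
#> [1] 36
```

All 36 planted species-specific gains are recovered, with no false
absences. `run_pipeline()` orchestrates the full stage sequence from a YAML
configuration (see the methods vignette), and
`inst/scripts/msl-pipeline.R` wraps `simulate` / `validate` / `run` for the
shell.

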