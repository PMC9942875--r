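# bescan

Analysis toolkit for **CRISPR base-editing mutagenesis screens** — for
groups who tile a gene with cytidine- or adenine-base-editor guides,
select under a phenotype (e.g. IFN-γ sensitivity), and need to go from
raw guide counts and sequencing-verification tables to per-variant
functional calls.

`bescan` covers the full in-silico side of such a screen:

* **Library design** — enumerate tiling guides against a gene model
  (protospacer 1–20, PAM 21–23; IUPAC PAM patterns), profile each guide's
  editability (window targets, GC context, poly-T tracts, uniqueness in
  the input), and select stop-codon control guides.
* **Outcome prediction** — for each guide, the editable window positions
  give `k + [k ≥ 2]` predicted alleles (every single edit plus the joint
  edit of all window targets); each allele is applied to the genome,
  re-spliced, re-translated and assigned a single consequence under the
  priority order *stop gain > start loss > splice variant > missense >
  UTR > synonymous*. Amino-acid mutagenesis coverage is reported per
  editor and for editor unions.
* **Screen statistics** — QC filters (zero-in-control, minimum reads,
  plasmid over-representation), reads-per-million normalization
  (`rpm = reads/total × 1e6 + 1`), log2 fold changes, DrugZ-style
  empirical-Bayes guide z-scores (control centring, abundance-windowed
  robust sd, monotone in abundance), element aggregation
  (`normZ = Σz/√n`, normal p, BH FDR) and LOF / GOF / SOF / neutral
  classification from a proliferation + FACS assay pair with
  benchmark-derived thresholds.
* **Genotype verification** — amplicon VAF profiles (1% absolute filter,
  editing-window focus, synonymous co-edits), single-cell guide
  assignment via a two-component skew-t mixture fitted by EM on log
  normalized UMI counts (cells kept iff P(≥1 guide) ≥ 0.99 and
  P(≥2) ≤ 0.01), ploidy-aware zygosity calls (triploid default: AF > 60%
  → homozygous `1/1/1`), consensus edits (≥ 3 cells and ≥ 25% of a
  guide's cells) and false-negative / misassignment rate estimation.
* **Synthetic data** — seeded generators for every input: a toy locus
  and tiling library with planted LOF/GOF/SOF effects, negative-binomial
  screen counts with plasmid/T0/control/IFN-γ/FACS arm structure,
  skew-t cell × guide UMI matrices with doublets, and amplicon variant
  tables with window-peaked editing and a het/homo zygosity mix.

See the methods vignette (`vignettes/bescan-methods.Rmd`) for the models,
parameter defaults and design decisions.

## Worked example

Simulate a screen end to end and classify the planted variants:

```r
library(bescan)

cfg <- sim_config(seed = 42)
sim <- simulate_locus_and_library(cfg)   # contig, gene models, library, truth
table(sim$library$category)
#>                intergenic             non_targeting    stop_control_essential
#>                        15                        30                         4
#> stop_control_nonessential                 targeting
#>                         4                       100

cm <- simulate_screen_counts(sim$truth, cfg)
cm
#> CountMatrix: 153 guides x 9 samples (plasmid, T0, control, IFNg, FACS_sorted)

qc       <- qc_filter(cm, min_reads = NULL)
controls <- sim$truth$guide_id[sim$truth$category %in%
              c("non_targeting", "intergenic", "stop_control_nonessential")]
mapping  <- na.omit(sim$truth[, c("guide_id", "element")])
pro <- run_screen(qc$counts, "IFNg",        "control", controls, mapping)
fac <- run_screen(qc$counts, "FACS_sorted", "control", controls, mapping)

# thresholds from benchmark guides of known effect (a validation cohort)
el <- unique(na.omit(sim$truth[, c("element", "class")]))
bl <- sim$truth$guide_id[sim$truth$element %in% head(el$element[el$class == "LOF"], 3)]
bg <- sim$truth$guide_id[sim$truth$element %in% head(el$element[el$class == "GOF"], 2)]
zp <- setNames(pro$guide_z_mean$z, pro$guide_z_mean$guide_id)
zf <- setNames(fac$guide_z_mean$z, fac$guide_z_mean$guide_id)
calls <- classify_variants(pro$element_scores, fac$element_scores,
                           list(prolif = zp[bl], facs = zf[bl]),
                           list(prolif = zp[bg]))
table(merge(calls, el)[, c("class", "call")])
#>          call
#> class     GOF LOF neutral SOF
#>   GOF       3   0       0   0
#>   LOF       0   6       0   0
#>   neutral   0   0      13   0
#>   SOF       0   0       0   3
```

Every planted class is recovered: elements enriched under IFN-γ selection
*and* in the FACS sort are loss-of-function (`LOF`); elements enriched
only in proliferation are separation-of-function (`SOF`); depleted
elements are gain-of-function (`GOF` — the FACS sort for non-responders
cannot recover these, so no FACS support is required). The strongest
calls, with element-level z-scores and FDR:

```r
#>    element z_prolif     z_facs          fdr call
#> 21      E5 5.362375 16.3226867 2.053374e-06  LOF
#> 1       E1 4.842284  0.1904474 1.346373e-05  SOF
#> 16     E23 4.770341 15.7831425 1.346373e-05  LOF
#> 15     E22 4.738393 15.1753035 1.346373e-05  LOF
#> 9      E17 4.444612 15.2858994 4.402530e-05  LOF
```

The SOF signature is visible directly: `E1` scores z ≈ 4.8 in
proliferation but z ≈ 0.2 in the FACS assay.

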