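---
title: "Methods: base-editing screen design, scoring and genotype verification"
author: "bescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: base-editing screen design, scoring and genotype verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bescan)
```

## Scope

`bescan` implements the informatics of a base-editing mutagenesis screen:
designing a tiling guide library over a gene model, predicting the edited
alleles each guide can install and their protein consequences, turning
guide count matrices into enrichment statistics and functional calls, and
verifying genotypes from amplicon and single-cell DNA sequencing. A
synthetic-data module generates inputs with the statistical structure each
stage assumes, so the whole pipeline can be exercised and tested without
any external download.

## Coordinates and gene models

Internally every genomic coordinate is 0-based half-open; emitted variant
tables are 1-based, following VCF convention. A `GeneModel` is one
transcript: sorted non-overlapping exons, a genomic CDS span and a strand.
At load time (when sequences are available) the spliced, strand-oriented
CDS must have positive length divisible by 3 and begin with ATG; a
`permissive` flag downgrades these errors to warnings for deliberately
broken fixtures. Gene models are read from a small JSON dialect (the
canonical fixture format) or from GTF/GFF3 exon/CDS features via
`rtracklayer`; multi-isoform selection is the user's responsibility
upstream — one model per gene.

`locate()` assigns each position a single site category: `CDS` (with the
offset into the spliced CDS and the codon index), the two UTRs split by
the CDS span and strand, `splice_region`, `intron` or `intergenic`. The
splice region is the 2 intronic bases flanking each exon — the canonical
GT/AG dinucleotides. Annotation pipelines differ in how far their "splice"
categories reach, and no single window is canonical, so the width is a
parameter (`splice_window`) rather than a constant; 2 is the minimal
defensible default.

## Guides and editors

The protospacer occupies positions 1–20 with the PAM at 21–23. (Some
descriptions number the PAM 20–23; that is inconsistent with a 20-nt
protospacer and we treat it as a typo.) An `EditorConfig` holds the
source/product base, the activity window and the PAM pattern; presets
cover BE3-NGG and BE3.9max-NGN (C→T, lenient window 4–9), YE1-BE4max-NGN
(C→T, 5–7; the engineered YE1 deaminase has a narrower window) and
ABE8e-NGN (A→G, 4–9).

`enumerate_guides()` scans both strands for 20-mers adjacent to a matching
PAM. Genome-wide uniqueness scoring needs a genome index; at desk scale we
instead count exact protospacer matches over both strands of the supplied
contigs (`unique_in_input`). A guide's editability profile flags:

* `no_target` — no source base in the window;
* `exclusively_gc_context` — every window cytosine is immediately
  preceded 5' by G on the protospacer strand, the dinucleotide context
  APOBEC deaminases disfavour (defined for cytidine editors only);
* `polyT` — a TTTT tract, a potential U6 transcription terminator.

These flags matter twice: as library QC, and as principled excuses when a
guide later fails to produce detectable edits (see error rates below).

## Predicted outcomes and consequences

For a guide with editable window positions $\{p_1,\dots,p_k\}$ the outcome
space is each single edit alone plus, when $k \ge 2$, the joint edit of
all $k$ positions — $k + [k\ge2]$ alleles. Bystander editing makes the
all-positions allele the dominant multi-edit product, and intermediate
combinations are deliberately not enumerated by default
(`combinatorial = TRUE` enumerates all $2^k - 1$ subsets for small $k$).

`annotate_outcome()` applies the variants to a genome copy, re-splices,
re-translates, and labels every edited position via `locate()`: edits in
the annotated start codon are `start_lost`; other CDS edits become
`stop_gained`, `missense` or `synonymous` from the codon-level diff;
intronic edits within the splice window are `splice_variant`. The
outcome's single consequence is the maximum under the priority order

> stop gain > start loss > splice variant > missense > UTR > synonymous,

with two extensions forced by completeness: `intron` (a non-splice
intronic edit) ranks below `synonymous`, and `intergenic` below that.
When an outcome overlaps several genes, annotation runs per gene and the
reported consequence is the maximum across genes, ties broken by gene id
order.

`aa_coverage()` reports the fraction of protein residues (terminal stop
excluded) touched by at least one non-synonymous predicted outcome, per
editor and for editor unions; a splice outcome credits the codon nearest
the affected boundary. Coverage on the synthetic locus illustrates the
machinery; reproducing a specific gene's published coverage requires that
study's exact filtered guide sets and reference annotation.

## Screen statistics

Counts are filtered in a fixed order, each removal logged with its rule:
guides with 0 reads in any control/reference sample; guides with fewer
than 100 reads in any sample (the minimum-count rule; we read this as a
guide-level rule because dropping whole samples would break the paired
replicate design); guides with more than 50,000 plasmid reads
(over-representation); optionally guides whose control counts differ more
than 3-fold between replicate experiments.

Normalization is reads-per-million with a pseudocount:
$\mathrm{rpm} = \mathrm{reads}/\mathrm{total} \times 10^6 + 1$, so
$\sum(\mathrm{rpm}-1) = 10^6$ per sample exactly, and
$\mathrm{L2FC} = \log_2(\mathrm{rpm_{treated}}/\mathrm{rpm_{reference}})$.

Guide z-scores follow the DrugZ idea of an empirical-Bayes noise
estimate: fold changes are centred on the mean of the control guides
(non-targeting, intergenic, non-essential stop controls; at least 20
required), then each guide's standard deviation is estimated from a
sliding window of 800 guides ranked by reference abundance (clipped to
the library size) and forced monotone non-increasing in abundance, so
sparsely counted guides never receive a smaller sd than well-counted
ones. Within the window we use the normal-consistent scaled MAD rather
than the plain sd: a tiling library's strongest hits would otherwise
inflate the noise estimate of every guide at similar abundance. On
homoscedastic data the two estimators agree (a property test holds the
median implied sd within 5% of the pooled sd at n = 2,000).

Element scores (per gene, or per predicted amino-acid position) are
$\mathrm{normZ} = \sum z_i/\sqrt{n}$ with a two-sided normal p-value and
Benjamini–Hochberg FDR across the run's elements. Replicates are averaged
at the guide-z level before aggregation.

### LOF / GOF / SOF classification

The two-assay design drives the calls: positive selection with IFN-γ in a
proliferation screen enriches loss-of-function (LOF) and
separation-of-function (SOF) guides and depletes gain-of-function (GOF)
guides, while the FACS screen — sorting cells that fail to induce MHC-I /
PD-L1 — can only recover LOF. Thresholds come from benchmark *guide* sets
of known effect (a validation cohort): the LOF threshold is the 5th
percentile of the benchmark-LOF guide |z| in the proliferation assay, the
GOF threshold likewise from benchmark-GOF guides, the FACS support
threshold from benchmark-LOF guide |z| in the FACS assay. An element is
LOF when proliferation-enriched beyond threshold with FACS support, SOF
when proliferation-significant but below the FACS threshold, GOF when
depleted beyond the GOF threshold (no FACS requirement, since a sort for
non-responders cannot recover GOF), else neutral. Setting element-level
calls against guide-level benchmark thresholds is deliberate: element
normZ concentrates as $\sqrt{n}$, so genuine multi-guide elements clear a
guide-derived threshold with margin, which keeps recall stable without
loosening the quantile.

## Genotype verification

**Amplicon profiles.** VAF = alt/total reads; entries below 1% are removed
(an absolute filter). Per guide we report VAF by protospacer position, the
fraction of edit observations inside the editor window, and — when
consequence labels are present — how often a non-synonymous window edit
co-occurs with a synonymous edit in the same sample.

**Guide-to-cell assignment.** Guide UMI counts are normalized by the
cell's total UMI count and log-transformed (pseudocount 0.5 keeps zero
counts finite), and one pooled two-component skew-t mixture (Azzalini
parameterization) is fitted over all cell × guide entries. The EM is
generalized: exact E-step and weight update, and a warm-started
Nelder–Mead maximization of each component's responsibility-weighted
log-likelihood, which guarantees a monotone observed log-likelihood
(asserted in tests at every iteration). Initialization is quantile-based
— entries above the 95th percentile seed the "present" component —
and convergence is $|\Delta\ell| < 10^{-6}(1+|\ell|)$ within 500
iterations. Per-entry posteriors give, per cell, P(≥1 guide) and
P(≥2 guides) under cross-guide independence (Poisson–binomial); a cell is
assigned its maximum-posterior guide iff P(≥1) ≥ 0.99 and P(≥2) ≤ 0.01.
Whether the original analysis pooled entries or fitted per guide, and with
how many components, is undocumented; the pooled two-component fit is the
minimal model consistent with the description and is our design choice.

**Zygosity.** For the default triploid setting an allele fraction above
0.60 (two or three of three alleles) is a high-confidence homozygous call
(penetrance `1/1/1`), a nonzero fraction at or below it heterozygous
(`0/1/1`), zero wild type. The threshold is configurable per ploidy, and
calls are monotone in AF by construction.

**Consensus edits.** A guide is reported only with ≥ 3 uniquely assigned
cells; an edit is retained iff seen in ≥ 3 cells *and* ≥ 25% of the
guide's cells. Known germline SNPs should be removed upstream via a
position blocklist before consensus calling.

**Error rates.** Guides with no detected edits are first excused by their
editability flags (no target, exclusively GC context, poly-T); the
false-negative rate is the remaining undetected count divided by the
*detected* count, as a percentage. The denominator is deliberately the
detected count — of the plausible readings of the verification worked
example (87 detected, 37 undetected, 12 excused) only this one reproduces
its printed 28.7%. The control misassignment rate is the fraction of
non-targeting control guides assigned a target-gene edit (worked example:
1/39 = 2.6%).

## The synthetic-data generators

All generators are deterministic given a seed (per-generator streams are
derived from the master seed) and their outputs pass the corresponding
module's input validation.

* **Locus and library** — one plus-strand target gene (default: 900-nt
  CDS over 3 exons, canonical GT/AG introns, 60/90-nt UTRs) plus two
  small auxiliary genes enriched in CAA/CAG/CGA codons so stop-codon
  controls exist. Tiling guides are grouped positionally into elements of
  4 (a proxy for amino-acid positions); 6 LOF, 3 GOF and 3 SOF elements
  are planted by default with ±2.0 log2-unit effects, leaving most
  elements neutral as in a real tiling screen. Controls: 30 non-targeting
  20-mers absent from the contig, 15 intergenic guides from the padding,
  and stop controls from the auxiliary genes (the "essential" gene's
  controls carry a −2.0 log2 dropout in every post-T0 arm).
* **Screen counts** — guide abundance is log-normal around the
  sequencing depth (default 500×, sdlog 0.5, a typical well-powered
  screen); counts are negative-binomial with dispersion 0.1. Arms:
  plasmid, and per replicate T0, control, IFN-γ (expected counts ×
  $2^{\mathrm{effect}}$) and FACS. The FACS sort is modelled as binomial
  capture — LOF guides captured at 0.8, everything else at 0.02, then
  resequenced to depth — matching the selection logic of sorting
  non-responder cells rather than its physics, so only LOF enriches
  there.
* **UMI matrices** — each cell carries one guide (two at the 5% doublet
  rate); log UMI fractions come from the "present" skew-t component
  (location −1.2, scale 0.3, df 6, skewness −1) or the background
  (−7, 0.5, 5, +1.5), i.e. ≈ 11 background scales of separation —
  emulating the clean bimodality of real guide-UMI data — and are
  converted to counts against log-normal per-cell totals (~8,000).
* **Amplicon calls** — per observation the edited position set is drawn
  from the outcome support (all window positions jointly with rate 0.3,
  else one position weighted by a profile peaked inside the window:
  0.35 vs 0.01 outside); per-cell allele counts are binomial around the
  allele fraction implied by a drawn zygosity (default 50/50 het/homo at
  ploidy 3, depth 200).

What the generators do **not** emulate: PCR/sequencing error and read
structure (counts are drawn directly), guide-efficiency sequence context,
copy-number effects, ambient-UMI correlation structure, and clustered
real-genome features (repeats, homopolymers beyond chance). Passing tests
therefore certify the statistical machinery — calibration, recovery,
thresholds — not performance on any particular real dataset.

## Numerical choices and degenerate inputs

* Ambiguity codes never count as editable bases and translate to `X`.
* Ties in consequence across genes break by gene id order; the skew-t
  components are ordered by location, "present" being the upper one.
* Regions shorter than 23 nt yield an empty guide table, not an error;
  an all-guides-removed QC filter is fatal.
* `eb_zscore` refuses to run with fewer than 20 control guides, naming
  the threshold; zero-total samples are fatal in normalization.
* EM non-convergence flags the fit and excludes all cells from
  assignment rather than returning doubtful posteriors.
* Zero-depth variant observations are skipped with a warning.

## Problem sizes used in tests

The test-suite simulations use 1,000–2,200 guides per screen (225–500
elements of 4 guides), 3 seeds for calibration properties, 500 cells × 20
guides for assignment, 5,000 entries for mixture recovery and ~2,000
edited cells for zygosity recovery — sizes chosen so each property is
measured with useful precision while the suite stays quick.

## Known limitations

Editing-efficiency prediction, bystander-probability modelling and indel
byproducts are out of scope: outcomes are possibilities, not
probabilities, so the absence of a significant score never demonstrates
that a residue is dispensable (the ~29% false-negative worked example
makes the same point from data). Promoter-targeting guides are supported
as plain intervals with no regulatory-effect model. Uniqueness is
exact-match within supplied sequences, not genome-wide. Variant calling
from reads is upstream of this package; it consumes variant tables.
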