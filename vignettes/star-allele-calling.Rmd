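---
title: "Copy-number-aware star-allele calling: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number-aware star-allele calling: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxstar)
library(dplyr)
```

## The problem

Pharmacogenes are genotyped as *star alleles*: named haplotype patterns
defined by SNVs, small indels, and — for a difficult minority of genes —
structural variants (SVs): whole-gene deletions (CYP2D6\*5, GSTT1\*0),
duplications (CYP2A6\*1x2), higher-order multiplications (CYP2E1\*7x3), and
gene–pseudogene hybrids (CYP2D6\*36+\*10, a CYP2D6/CYP2D7 fusion carried in
tandem with \*10). A sample's *diplotype* (the ordered pair of star alleles)
is then translated to a CPIC phenotype such as *poor metabolizer*, which is
what prescribing guidance consumes.

`pgxstar` implements the full calling chain for targeted-capture or WGS
inputs: variant tables and per-base depth in, diplotypes and phenotypes out,
plus the concordance machinery used to validate one call set against
another. Because its inputs are tabular throughout (sites-by-samples variant
records, positions-by-samples depth, per-sample calls), the package is
organized tidyverse-style: data frames in, tibbles out, `autoplot()` for the
evidence plots, `tidy()`/`glance()` for fitted classifiers.

## Copy-number model

Read depth at position $p$ in sample $s$ is modeled as proportional to
library size, position-specific capture efficiency, and local copy number:
$E[d(s,p)] = \tfrac{1}{2}\,\mu \cdot \ell_s \cdot e_p \cdot c(s,p)$.
Two normalizations remove the nuisance factors:

1. **Intra-sample** (control gene): $\mathrm{cn_{raw}}(s,p) = 2\,d(s,p) /
   m_s$, where $m_s$ is the sample's median depth over a control locus with
   negligible copy-number polymorphism. VDR is the default control: it is
   long (63.5 kb) and rarely deleted or duplicated. The median (rather than
   the mean) is robust to focal CNVs inside the control. This step cancels
   $\ell_s$ exactly, which is why profiles are invariant to rescaling a
   sample's whole depth row (tested at tolerance 1e-9).
2. **Inter-sample** (cohort reference): targeted capture leaves $e_p$ in
   the ratio, so each position's cohort reference — the *median* of
   $\mathrm{cn_{raw}}$ over a designated sample set — is rescaled to 2.
   The reference set is either all samples or, critically, only samples
   known to carry no SV in the gene. For genes where deletion carriers are
   the cohort majority (GSTT1 deletion allele frequencies put carriers near
   75–78% of subjects), the all-sample median sits on a deleted copy state
   and the normalization inverts the evidence: diploid samples read as
   duplicated. The no-SV mode is therefore the default in the recovery
   studies for GSTT1-like genes, mirroring how such panels are run in
   practice. Whether the reference is per-position or per-gene aggregate
   was an open choice; per-position is used (and recorded in the profile's
   provenance attributes) because it also cancels capture-efficiency shape,
   not just scale.

Positions with zero depth in more than half the cohort are masked as
capture dropouts before normalization — this prevents division by a
near-zero reference but means a cohort that is majority homozygous-deleted
masks the entire gene; the deterministic deletion-cohort fixtures used in
tests keep homozygous carriers at 25% for this reason. Copy numbers are
reported unrounded; integerization happens only inside SV classification,
preserving the fractional evidence needed downstream.

## SV classification

Profiles are averaged in fixed 500 bp bins over the gene plus (when
modeled) pseudogene span, giving a short near-piecewise-constant feature
vector; masked positions are excluded and empty bins imputed from flanking
bins. A one-vs-rest SVM over these features assigns one of the gene's
registered diplotype-level classes (e.g. CYP2D6: normal, del_het, del_hom,
dup, and the three cataloged hybrid configurations).

Two design points deserve justification:

* **Kernel.** The classifier uses the RBF kernel. A linear kernel looks
  tempting (the features are plateaus), but one-vs-rest with linear
  machines provably fails here: copy-number classes are *ordered along a
  line* (gene-level CN 0, 1, 2, 3, 4), and no single hyperplane can
  separate an interior plateau (heterozygous deletion at 1) from the union
  of its neighbors (0 and 2). We observed exactly this as ~0.87 training
  accuracy with del_het/normal confusion before switching; with RBF, class
  boundaries are bounded regions and training accuracy is 1.0 with
  held-out accuracy ≥ 0.99.
* **Indeterminate escape.** A sample is refused (Indeterminate) when no
  machine claims it (top one-vs-rest decision value < 0) *or* its
  standardized distance to the winning class centroid exceeds that class's
  calibration threshold (the 99.5th percentile of the class's own training
  distances, times 1.5). Calibration is per class because count noise
  scales with the copy level: a four-copy hybrid class has intrinsically
  wider bins than the diploid class, and a pooled threshold either
  over-rejects high-CN classes or under-rejects novelty near the diploid
  class. Per-feature spreads are floored at 0.15 CN to absorb cross-cohort
  normalization wobble and degenerate noise-free features. Novel SVs —
  e.g. a partial deletion matching no registered template — land outside
  every calibrated region and fall to Indeterminate rather than being
  forced into the nearest class; the same applies to hybrid patterns not
  enumerated in the per-gene registry.

Training data come from the simulator's class recipes (below): no labeled
real cohort ships with the package. Models are deterministic given a seed.

## Phasing and allele matching

Statistical population phasing against an external reference panel is out
of scope; the package consumes pre-phased VCFs (`passthrough` mode) or runs
a deterministic catalog-guided phaser (`match` mode). Match mode places
homozygous-alternate variants on both copies and searches the $2^{k-1}$
phase configurations of the $k$ heterozygous variants, choosing by a
two-term objective: first minimize the number of variants *not explained*
by each copy's best catalog allele, then maximize the size of the largest
fully-matched allele. The first term forces variants defining two distinct
single-variant alleles into trans (a cis placement leaves one of them
unexplained by the copy's best match); the second forces jointly-defining
variants into cis (both placements explain everything, but cis matches the
larger combination allele). Ties break on enumeration order, so results
are reproducible; above 12 heterozygous sites a greedy seed replaces the
exhaustive search. This phaser is intentionally simple — incorrect phasing
is a known discordance mode for catalog-based pipelines, so the phasing
mode is recorded in every call's provenance.

Matching itself is subset matching: a candidate allele's entire defining
set must lie on the haplotype; candidates rank most-specific first (largest
defining set, so UGT1A1 \*80+\*28 outranks \*80 and \*28 on a haplotype
carrying both variants), then function-altering before unknown-function,
then lexically. An empty candidate list yields the reference allele.
SV-tagged alleles are never asserted from variants alone.

## Integrating copy number and allele fractions

The assignment rules per SV class kind:

* *del_het*: remaining variants are hemizygous (homozygous-looking), so
  they are matched as a single copy and the second slot takes the gene's
  deletion allele (\*5, \*0, \*2, \*S1 per catalog); *del_hom* assigns the
  deletion allele twice.
* *dup*/*mult* (total-copy plateau 3 or 4): the extra copies are attributed
  through heterozygous-site allele fractions. A copy carrying $c$ of $T$
  total copies shows alt fraction $c/T$; the copy split $(c_1, c_2)$,
  $c_1 + c_2 = T$, minimizing the mean absolute deviation between observed
  het fractions and expected fractions is selected. Sites attributable to
  one copy (its matched allele's defining variants) pin that copy;
  fractionally informative but phase-arbitrary sites (haplotype-private
  passenger variants) constrain the split through the better-fitting copy.
  This is the 1:3 vs 2:2 logic separating \*7/\*7x3 (sites at 0.25/0.75)
  from \*7x2/\*7x2 (sites at 0.5). When the haplotypes carry the *same*
  base allele, its own defining sites sit at fraction 1 and are
  uninformative — the discrimination necessarily lives on sites private to
  one physical chromosome, which is why the simulator plants them (below).
  If the best split's residual exceeds the tolerance (0.12, roughly three
  binomial standard deviations at 100x and conservative at 250x), the call
  is Indeterminate with a reason; with no het evidence at all, the extra
  copies go to the reference-most allele and the call is flagged
  low-confidence.
* *hyb*: the registered hybrid allele name replaces the copy carrying its
  embedded conventional allele (\*10 inside \*36+\*10, \*4 inside
  \*68+\*4); hybrids contributing no observable variants (CYP2B6\*29, whose
  gene-derived 5' is missing) replace the reference-most copy.

Canonical diplotype ordering follows the printed convention: numeric cores
ascending (\*36x2+\*10 orders by 36, hence "\*36x2+\*10/\*41"), copy
suffixes after their base, reference-first then lexical for non-numeric
names.

## Phenotype translation

Nine genes have a genotype-phenotype table: CYP2C9, CYP2D6, and DPYD use
activity scores (reference allele 1, decreased 0.5 or 0.25, none 0; an
`xN` suffix multiplies by N; the diplotype score is the sum), mapped
through per-gene bins stored as data (CYP2D6: 0 poor; (0,1] intermediate;
(1,2.25] normal; >2.25 ultrarapid — the CPIC 2020 convention, consistent
with the worked scores 2/1/0). The other six use unordered
function-pair maps, also stored as data (CYP2B6 decreased+no_function →
poor metabolizer reproduces the \*6/\*8 example; SLCO1B1 reports
transporter function labels). Any allele of unknown/uncertain/unassigned
function forces Indeterminate — e.g. CYP2D6 \*29/\*106, because \*106 has
no assigned function. Genes outside the nine return a "no phenotype table"
result in batch mode rather than an error, since panels genotype more genes
than they phenotype. Function assignments beyond the in-text worked
examples follow current CPIC releases and ship as an editable TSV; bins
and maps are versioned data, swappable without code change.

## The synthetic-data generator

The generator defines the study conditions for every simulation result in
the package:

* **Depth**: negative-binomial counts with mean
  $\mu \cdot \ell_s \cdot e_p \cdot c(s,p)/2$; defaults $\mu = 250$x
  (the deep-coverage regime the panel targets), dispersion 0.1 (per-base
  CV ≈ 0.33 at 250x, typical of capture data), mean-one log-normal library
  factors (sdlog 0.2) and capture efficiencies (sdlog 0.2), control locus
  simulated copy-neutral. Dispersion 0 gives the deterministic mean —
  used for exactness tests.
* **Copy tracks**: per-haplotype piecewise-constant templates over the
  gene + pseudogene span; hybrids place a single breakpoint at a fixed
  fraction of the span, with the converted segment's reads accruing to the
  pseudogene (so a \*36+\*10 carrier shows the step up in the gene 5' and
  the mirrored step in the pseudogene tail). Templates are registered per
  class and verified by averaging simulated profiles.
* **Allelic depths**: at each defining-variant site, alt reads are binomial
  with success probability carrying-copies / total-copies at that position,
  total reads taken from the simulated depth. Each sample also receives
  two haplotype-private passenger heterozygous variants (emulating
  suballele variation). These are what make same-base-allele copy
  configurations identifiable: for a \*7/\*7x3 carrier the \*7-defining
  sites are carried by all four copies (fraction 1), and the 1:3 signature
  appears on the passengers at 0.25/0.75.
* **Mixtures**: per-gene default diplotype mixtures are fixed once, shaped
  on diverse-cohort reports (deletion alleles common for GSTT1/GSTM1/
  UGT2B17, hybrid and duplication configurations present for CYP2D6 and
  CYP2E1).
* Position grids sample each locus at a fixed stride (25–300 bp, ~200
  positions per locus) rather than every base — the package's resolution
  choice for desk-scale cohorts; per-base input is accepted unchanged.

What the simulator does *not* emulate — GC-dependent coverage waves,
alignment artifacts from CYP2D7 homology at the read level, index
hopping, reference bias in allelic depths — bounds what passing recovery
tests show: they validate the normalization, classification, phasing, and
integration logic under the stated noise model, not robustness to every
real-world artifact.

## Study sizes and numerical choices

The recovery studies run at the sizes the validation design calls for:
10 seeded replicate carriers for each of the 19 SV-defined catalog alleles
at 250x (class recall), and 200-sample cohorts for CYP2D6, CYP2E1, GSTT1,
and UGT2B17 (exact-diplotype recovery, ≥ 99% required, with the CYP2E1
copy-split subset required at 100%). Training uses 30 simulated examples
per class. Degenerate inputs are handled explicitly: empty variant tables
yield homozygous-reference diplotypes; zero control statistics exclude the
sample with a warning; empty feature bins impute from neighbors; an empty
no-SV set is an error rather than a silent fallback.

## Known limitations

* Suballeles (\*2A vs \*2B) are not resolved beyond catalog contents, and
  novel alleles are not nominated — unmatched configurations end at the
  reference allele or Indeterminate.
* Breakpoints are template-level; no base-pair resolution or split-read
  evidence.
* The shipped allele-definition positions are synthetic (illustrative
  hg19-like coordinates) except those printed in primary literature; the
  loaders accept externally curated tables for production use.
* The deterministic phaser is catalog-guided, not population-statistical;
  long-range phasing errors seen with panel data are out of its reach.
* HLA genes are catalog entries only; HLA typing requires dedicated
  methods.
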