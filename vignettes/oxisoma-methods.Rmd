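---
title: "Paired-tissue somatic SNV calling and oxidative spectrum analysis with oxisoma"
author: "oxisoma authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired-tissue somatic SNV calling with oxisoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxisoma)
```

# The model

`oxisoma` detects somatic single-nucleotide variants by contrasting two
tissues of one individual at the pileup level. Its unit of evidence is the
`PileupCounts` object: per site, the read count of each base split into
four cells — (forward strand, F1R2), (forward, F2R1), (reverse, F1R2),
(reverse, F2R1) — plus per-allele mean base quality and per-site mean
mapping quality. Keeping strand *and* read-pair orientation is the point:
oxidative damage to guanine (8-oxo-dG) acquired during DNA shearing
produces variant support confined to a single read-pair orientation, and
the orientation-bias filter needs those cells to see it.

## Genotypes and the somatic p-value

Each tissue is genotyped from its variant allele frequency (VAF) against
fixed thresholds: `hom_alt` at VAF ≥ 0.90, `het` at VAF ≥ 0.10, `hom_ref`
below, `no_call` when depth < 8 or the mean mapping quality of the site
(< 40) or the mean base quality of the evaluated allele (< 20) fails. Both
VAF boundaries are closed at the lower edge — a VAF of exactly 0.10 is a
heterozygote — a convention we fixed because the thresholds are stated
without open/closed edges anywhere we could check.

The alternate allele is the best-supported non-reference base of the
*combined* tissue counts, so both tissues are genotyped against the same
allele; ties break deterministically in A<C<G<T order. If a second
non-reference allele also reaches the heterozygote threshold in either
tissue the site is declared `Undetermined`: the analysis is strictly
biallelic.

The somatic evidence is a one-sided Fisher exact test on the 2×2 table of
(ref, var) read counts of the two tissues, i.e. the hypergeometric tail
probability of tables at least as extreme as observed in the direction of
the tissue with the higher VAF (the VarScan2 convention; the tool defines
the test but not the sidedness, so the direction rule is ours and is
exercised by the tissue-swap tests). Statuses then follow:

* **Somatic** — genotypes differ (neither `no_call`) and p < 0.05;
* **Germline** — equal non-reference genotypes, and in *each* tissue the
  var/ref split rejects a homozygous-reference error model;
* **Reference** — both `hom_ref`;
* **Undetermined** — everything else.

The germline confidence clause deserves a note. The source criterion —
"confidently called as same genotype (p < 0.05)" — does not say what the
p-value is computed against. We interpret it as *confidence that the
variant is real in both tissues*: a one-sided Fisher test of the observed
(ref, var) counts against the expected counts of a hom-ref error model
(default error rate 0.01), rejecting at the somatic threshold. The choice
is isolated in `germlineConfident()` and the error rate is a parameter, so
alternative readings are one function swap away.

`minVarReads` (default 0) exists because variant-read support is sometimes
reported descriptively (most deeply sequenced studies find nearly all
somatic candidates carry ≥ 4 variant reads); it is an optional gate, not a
default filter.

## Artifact filters

Three post-calling filters, all order-independent and accumulated as flags
rather than destructive removal:

* **strand_bias** — more than 90 % of variant-supporting reads on one
  strand. Computed on variant reads only, not total depth: the filter
  targets artifactual variant support, and a deeply covered site with
  balanced reference reads can still carry one-strand variant support.
  The threshold is configurable and strict (exactly 90 % passes).
* **orientation_bias** — *all* variant reads in one read-pair orientation
  (F1R2 or F2R1). Deliberately all-or-nothing, as the rule is stated; a
  single read in the other orientation passes. This makes the filter very
  sharp against pure artifacts and essentially harmless for true variants
  at depth 100, where ~40 variant reads land in one orientation with
  probability 2^-39.
* **identity_region** — the site lies in a region ≥ 87 % identical to
  another genomic region. Real analyses should supply a curated BED;
  `buildIdentityMask()` is a convenience for synthetic references that
  slides a window (default 100 bp) over the genome and compares it,
  ungapped, against every non-overlapping offset via a cumulative-sum
  match count. It is O(L²) and exact — practical to ~50 kb, which is the
  scale of the simulated genomes here — and is verified against an
  exhaustive all-pairs window comparison.

In the paired setting the two read-bias filters are evaluated on the summed
variant evidence of both tissues; for a somatic call the non-carrier tissue
contributes essentially nothing, and for germline calls pooling only
increases power.

## Spectrum, zygosity and context

Substitutions collapse to six strand-symmetric classes (`G:C>T:A` pools
G>T and C>A, etc.). A `SpectrumTable` holds counts and proportions for a
call subset; enrichment is the per-class difference of proportions
(somatic − germline), which sums to zero by construction.

Zygosity reporting uses thresholds distinct from calling, applied to read
fractions at reporting time: het above 10 % VAF, hom below 5 %, and the
gap [5 %, 10 %] *indeterminate* — the source rules are silent about that
interval, so we exclude rather than guess, and report the indeterminate
count separately.

Context operations re-orient each G:C>T:A event to a fixed strand: the
purine (G) strand for the 3′-base analysis (C>A events read the complement
of the 5′ neighbour), because the repair-efficiency literature states the
3′-adenine effect relative to the oxidized G; and the pyrimidine (C) strand
for the CCG-motif check (G>T events count when their plus-strand context is
CGG), matching how the shearing-artifact motif is written. The underlined
base in the motif's source is lost in typesetting; we adopt the middle-C
convention and note it as an assumption. Both orientations are covered by
reverse-complement tests.

## Annotation and enrichment

The codon annotator rebuilds the codon containing each CDS variant in
transcription order (reverse-complementing for minus-strand genes) and
translates with the standard genetic code: `synonymous`, `nonsynonymous`,
`stopgain` (stop-loss is reported as nonsynonymous), `UTR` inside a gene
span but outside CDS, `noncoding` elsewhere; overlapping genes report the
most severe effect. Correctness is established against an independent
whole-transcript re-translation oracle over random gene models on both
strands.

Gene-set analysis is hypergeometric over-representation with
Benjamini–Hochberg adjustment, the standard equivalent when the input is an
unranked gene list (a ranked, permutation-based method would need a
per-gene statistic that a small somatic call set does not provide). The
long-gene test is the same tail probability with "long" defined on genomic
span — not summed CDS — with a 100 kb default threshold, since that is how
gene length is used in the double-strand-break literature the question
comes from. The background universe is always an explicit argument:
whether it should be all genes or captured genes is a study-design choice
we refuse to default.

## Validation rule

A call is validated on the amplicon platform when (i) the carrier tissue
(higher validation VAF) has ≥ 100 variant reads — we require the carrier
only, with `bothTissues = TRUE` available, since the source rule does not
say which tissue the support applies to; (ii) the two tissues' VAFs differ
≥ 2-fold, where a zero VAF in one tissue passes if the other is positive
and a 0/0 tie fails (the zero case is undefined at the source; a tie
carries no evidence of a difference); and (iii) the same tissue carries the
higher VAF on both platforms — stated as the criterion of accordance, so it
is an explicit conjunct. The rule is monotone in reads and fold change and
invariant under a consistent tissue-label swap.

# The simulator

`simulatePair()` operates at the pileup level: it samples read *counts*,
not reads. Alignment, capture bias and per-read quality modelling are out
of scope — every statistic the pipeline computes is a function of the
counts, so count-level sampling exercises all of it.

Defaults are the study conditions: mean depth 100× (Poisson per site);
germline class weights 0.36 `A:T>G:C`, 0.38 `G:C>A:T`, remainder split
evenly; somatic weights 0.87 `G:C>T:A`; somatic heterozygotes in tissue 1
with probability 0.85 (inside the reported 70–100 % range); sequencing
error 10⁻³ per read. Germline sites are identical in both tissues
(heterozygote fraction 2/3, the exome-typical het:hom ratio; het VAF
Beta(50,50), hom 0.99). Somatic VAF is Beta with configurable mean,
default 0.35 — deep re-sequencing of somatic heterozygotes tends to show
sub-0.5 fractions, consistent with subclonal mosaicism — and concentration
50; the true tissue VAF distribution is unknown, so this is a free
parameter, never asserted as biological truth. The acceptance checks use
mean 0.4 where the recovery condition is stated at that VAF.

Two deliberate idealisations, both load-bearing for interpretation:

* **Artifact sites are pure.** All variant reads at an artifact site carry
  one orientation *and error reads never land on the artifact allele*. At
  depth 100 a stray error read in the other orientation would otherwise
  defeat the all-or-nothing rule at ~2 % of sites. Real 8-oxo-dG artifacts
  are approximately, not exactly, single-orientation; the near-100 % flag
  rate measured here is a property of the rule on its idealised target,
  not a field sensitivity estimate.
* **Injected variants avoid the duplicated decoy region.** The decoy exists
  to exercise the identity mask; placing truth variants inside it would
  conflate mask behaviour with recovery metrics.

Consequently, passing recovery tests demonstrate that the implementation
applies its rules correctly under the generative model it assumes; they do
not demonstrate sensitivity/precision on real exomes, where mapping error,
capture bias, contamination and clonal structure all intrude.

Gene models tile the simulated genome with 600–6,000 bp genes (1–3 CDS
exons, frame-consistent); at this scale no gene crosses the 100 kb
"long-gene" threshold, so simulated enrichment runs use a 2 kb threshold —
a scale choice, stated here once; `longGeneTest()` keeps 100 kb as its
default. One built-in gene set collects the longest ~30 % of genes, so
uniformly placed variants hit it more often — the length-driven
over-representation the long-gene analysis looks for emerges naturally.

Determinism: `simulateReference()` seeds at `seed`, `simulatePair()` at
`seed + 1`, validation at caller-chosen offsets; all downstream stages are
deterministic, so a fixed config yields byte-identical files, which the
manifest's md5 checksums make checkable.

# Numerical and scale choices

* The Fisher tail is computed by `phyper()`; tests compare it against a
  brute-force enumeration of all 2×2 tables with margins ≤ 30 at 10⁻⁹.
  p-values are clamped into (0, 1] — the test is exact, so 0 cannot occur.
* Problem sizes in tests and the acceptance script: 50 kb genomes with
  5,000 germline / 200 somatic / 100 artifact sites for recovery and
  spectrum checks, 10,000 sites for null calibration, 1,000 random
  variants for the annotation oracle. These sizes make the binomial
  confidence intervals used in the recovery checks meaningful while a full
  run stays in the minutes range.
* Spectrum proportions of an empty subset are `NaN` with `total = 0`
  rather than an error, so pipelines can carry empty strata; enrichment on
  an empty table *is* an error, since the difference is undefined.
* Mean base qualities of absent alleles are `NA` in memory and `"NA"` in
  the TSV; quality gates treat missing means as passing (no evidence
  against the call), which matters only at zero-coverage alleles.

# Known limitations

* Biallelic SNVs only: indels and tri-allelic sites are out of scope by
  design (`Undetermined`).
* The identity mask builder is an exact O(L²) self-comparison, not a
  segmental-duplication caller; use a curated BED beyond ~50 kb.
* The simulator does not model exome capture, read-level errors, mapping
  artifacts or clonal substructure (one Beta VAF per somatic site).
* `compareCallsets()` is a generic overlap summary; no second caller is
  re-implemented.
* The pipeline is single-threaded by contract; outputs never depend on
  scheduling.
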