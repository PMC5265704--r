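# oxisoma

Somatic single-nucleotide variants — mutations present in only a subset of an
individual's cells — can be detected by comparing deep sequencing data from
two tissues of the same person: a site where the tissues carry different
genotypes is somatic, a site where both carry the same non-reference genotype
is germline. In neuron-rich brain tissue this contrast is particularly
interesting because oxidative stress converts guanine to 8-oxo-dG, which
mispairs with adenine and leaves a recognisable fingerprint: an excess of
G:C>T:A transversions. The same chemistry, however, also operates *in vitro*
during DNA shearing, so real oxidative mutations must be separated from
library-preparation artifacts.

`oxisoma` is an R package for this paired-tissue design. It implements:

* **Somatic calling** in the VarScan2 style. Per-tissue genotypes come from
  variant-allele-frequency (VAF) thresholds — heterozygote at VAF ≥ 0.10,
  homozygote at VAF ≥ 0.90, minimum coverage 8, base quality ≥ 20, mapping
  quality ≥ 40 — and each site gets a **somatic p-value**: the one-sided
  Fisher exact probability of the paired 2×2 ref/var read-count table,

  $$p = \sum_{k \ge v_2} \frac{\binom{n_2}{k}\binom{n_1}{V-k}}{\binom{N}{V}},$$

  one-sided toward the variant-richer tissue. A site is *Somatic* when the
  tissues' genotypes differ and p < 0.05, *Germline* when both tissues share
  a confidently supported non-reference genotype.
* **Artifact filters**: removal of calls with > 90 % of variant reads on one
  strand; of calls whose variant reads all share one read-pair orientation
  (F1R2 or F2R1 — the 8-oxo-dG shearing signature); and of sites inside
  regions ≥ 87 % identical to another genomic region (user BED or built by
  ungapped self-comparison).
* **Spectrum analyses**: six-class substitution spectra, somatic-vs-germline
  enrichment (difference of class proportions), tissue-resolved zygosity of
  heterozygous calls (het > 10 % VAF, hom < 5 %), the 3′-base context of
  mutated guanines, and the CCG-motif fraction of G:C>T:A calls.
* **Annotation and enrichment**: a minimal codon-effect annotator
  (synonymous / non-synonymous / stop-gain via transcript rebuild and the
  standard genetic code), a long-gene hypergeometric test, and gene-set
  over-representation with Benjamini–Hochberg correction.
* **Amplicon validation rule**: a discovery call is validated when the deep
  validation platform shows ≥ 100 variant reads in the carrier tissue, a
  ≥ 2-fold VAF difference between tissues, and the same tissue carrying the
  higher VAF on both platforms.
* **A pileup-level simulator** that generates paired-tissue data with known
  ground truth (germline/somatic/artifact origin, class, zygosity, VAF) so
  that every stage is testable offline, plus `runPipeline()` to orchestrate
  the whole analysis with a reproducibility manifest.

## Worked example

```r
library(oxisoma)

cfg <- simulationConfig(seed = 42, genomeLength = 20000, nGermline = 1000,
                        nSomatic = 50, nArtifact = 20)
refSim <- simulateReference(cfg)
pair   <- simulatePair(cfg, refSim)

calls <- classifyPairs(pair$t1, pair$t2)          # study-default thresholds
mask  <- buildIdentityMask(refSim$reference)      # 87 % self-identity mask
calls <- applyArtifactFilters(calls, pair$t1, pair$t2, mask = mask)
calls
#> PairedCalls with 20000 sites
#>   status: Reference=18930  Germline=1000  Somatic=70  Undetermined=0
#>   filtered: 4322 site(s) carry artifact flags
```

70 sites are called Somatic before filtering: the 50 injected somatic sites
plus the 20 single-orientation artifacts, which the orientation filter then
flags (most of the other flagged sites are reference positions whose one or
two error reads trivially share an orientation — flags only matter for
variant calls).

```r
som  <- mutationSpectrum(calls, "Somatic")
som
#> SpectrumTable (somatic), n = 50
#>            A:T>G:C G:C>A:T G:C>T:A A:T>T:A A:T>C:G G:C>C:G
#> count            0       0   46.00    2.00    2.00       0
#> proportion       0       0    0.92    0.04    0.04       0

germ <- mutationSpectrum(calls, "Germline")
round(spectrumEnrichment(som, germ), 3)
#> A:T>G:C G:C>A:T G:C>T:A A:T>T:A A:T>C:G G:C>C:G
#>  -0.355  -0.390   0.862  -0.028  -0.016  -0.072
```

The somatic subset is dominated by G:C>T:A transversions (enrichment +0.86
over the transition-rich germline spectrum), and the heterozygous variant
alleles sit almost exclusively in tissue 1:

```r
zygosityByTissue(calls)          # >10% / <5% reporting thresholds
#> $hetT1 41   $hetT2 5   $indeterminate 0   $fractionHetT1 0.891

nS <- length(keptCalls(calls, "Somatic"))
nG <- length(keptCalls(calls, "Germline"))
somaticPercentage(nS, nS + nG)
#> 4.77    # percent of variant sites that are somatic
```

A thin command-line wrapper with subcommands `simulate`, `call`, `filter`,
`spectrum`, `annotate`, `validate` and `run` is installed at
`inst/scripts/oxisoma`.

## Pileup TSV dialect

Classic `samtools mpileup` text cannot represent read-pair orientation, which
the oxidative-artifact filter needs, so pileups are exchanged as a TSV with
header

```
chrom  pos  ref  A  C  G  T  meanBQ_A  meanBQ_C  meanBQ_G  meanBQ_T  meanMQ
```

where each base column holds the comma-joined quadruple
`fwdF1R2,fwdF2R1,revF1R2,revF2R1` of read counts, `meanBQ_*` are per-allele
mean phred base qualities (`NA` when the allele has no reads) and `meanMQ`
is the site's mean mapping quality. Positions are 1-based; BED masks use the
usual 0-based half-open convention on disk; gene models use the GFF-lite
TSV documented in `?readGeneModels`.

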