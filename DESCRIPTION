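Package: oxisoma
Title: Paired-Tissue Somatic SNV Calling and Oxidative Mutational Spectrum
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects somatic single-nucleotide variants between two tissues of
    the same individual from pileup-level read counts, using a VarScan2-style
    one-sided Fisher exact somatic p-value, variant-allele-frequency genotype
    thresholds, and post-calling artifact filters for strand bias, read-pair
    orientation bias (the F1R2/F2R1 signature of oxidative 8-oxo-dG damage),
    and self-similar genomic regions. Downstream analyses cover six-class
    substitution spectra, somatic-versus-germline enrichment, tissue-resolved
    zygosity of heterozygous calls, 3'-base and CCG-motif sequence context,
    a minimal codon-effect annotator with gene-length and gene-set
    over-representation tests, and an amplicon re-sequencing validation rule.
    A pileup-level simulator with recorded ground truth makes every stage
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    fgsea,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SomaticMutation, VariantDetection, Sequencing, Software
Collate: 
    'oxisoma-package.R'
    'AllGenerics.R'
    'CallingParams-class.R'
    'PairedCalls-class.R'
    'PileupCounts-class.R'
    'SpectrumTable-class.R'
    'annotation.R'
    'calling.R'
    'filters.R'
    'io.R'
    'validation.R'
    'spectrum.R'
    'simulate.R'
    'pipeline.R'
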