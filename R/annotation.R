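#' @include PairedCalls-class.R
NULL

.EFFECT_SEVERITY <- c(stopgain = 1L, nonsynonymous = 2L, synonymous = 3L,
                      UTR = 4L, noncoding = 5L)

# ordered CDS positions of a gene in transcription order (genomic, 1-based)
.cdsPositions <- function(segs, strand) {
  pos <- unlist(lapply(seq_len(nrow(segs)), function(i)
    seq.int(segs$start[i], segs$end[i])))
  if (strand == "-") rev(pos) else pos
}

#' Annotate the coding effect of variant calls
#'
#' Minimal codon-effect annotation against GFF-lite gene models: for a
#' variant inside a CDS the codon is rebuilt in transcription order
#' (reverse-complemented for minus-strand genes) and translated with the
#' standard genetic code. Effects: `synonymous`, `nonsynonymous`,
#' `stopgain`, `UTR` (inside a gene span but outside CDS), `noncoding`
#' (outside all genes). A variant hitting several genes reports the most
#' severe effect (stopgain > nonsynonymous > synonymous > UTR > noncoding).
#'
#' @param calls a [PairedCalls-class] object or data.frame with `chrom`,
#'   `pos`, `ref`, `alt`.
#' @param geneModels gene models from [readGeneModels()].
#' @param reference reference sequence (`DNAString`/`DNAStringSet`/character).
#' @return a `data.frame` with one row per input variant: `chrom`, `pos`,
#'   `ref`, `alt`, `gene_id`, `effect`, `refAA`, `altAA`, `codonPos`.
#' @export
annotateEffects <- function(calls, geneModels, reference) {
  if (is(calls, "PairedCalls")) calls <- as.data.frame(calls)
  s <- .refToChar(reference)
  n <- nrow(calls)
  out <- data.frame(chrom = calls$chrom, pos = calls$pos, ref = calls$ref,
                    alt = calls$alt, gene_id = NA_character_,
                    effect = "noncoding", refAA = NA_character_,
                    altAA = NA_character_, codonPos = NA_integer_,
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  spans <- attr(geneModels, "geneSpans")
  if (is.null(spans)) stop("geneModels must carry a geneSpans attribute")
  cds <- geneModels[geneModels$feature == "CDS", , drop = FALSE]
  grVar <- GRanges(calls$chrom, IRanges(calls$pos, calls$pos))
  grGene <- GRanges(spans$chrom, IRanges(spans$start, spans$end))
  ov <- findOverlaps(grVar, grGene)
  if (!length(ov)) return(out)

  # per-gene CDS machinery, built lazily once per gene
  geneCache <- new.env(parent = emptyenv())
  geneInfo <- function(g) {
    if (!is.null(geneCache[[g]])) return(geneCache[[g]])
    segs <- cds[cds$gene_id == g, , drop = FALSE]
    strand <- spans$strand[spans$gene_id == g][1]
    info <- if (nrow(segs) == 0) list(pos = integer(), strand = strand)
    else {
      p <- .cdsPositions(segs[order(segs$start), , drop = FALSE], strand)
      if (length(p) %% 3L != 0L)
        stop("CDS length not divisible by 3 for gene: ", g)
      bases <- substring(s, p, p)
      if (strand == "-") bases <- .COMPLEMENT[bases]
      list(pos = p, strand = strand, bases = bases)
    }
    geneCache[[g]] <- info
    info
  }

  code <- Biostrings::GENETIC_CODE
  for (h in seq_along(ov)) {
    i <- S4Vectors::queryHits(ov)[h]
    gi <- S4Vectors::subjectHits(ov)[h]
    g <- spans$gene_id[gi]
    if (is.na(calls$alt[i])) next
    info <- geneInfo(g)
    cdsIdx <- match(calls$pos[i], info$pos)
    if (is.na(cdsIdx)) {
      eff <- "UTR"; refAA <- NA_character_; altAA <- NA_character_
      cp <- NA_integer_
    } else {
      cp <- ((cdsIdx - 1L) %% 3L) + 1L
      codonStart <- cdsIdx - cp + 1L
      refCodon <- info$bases[codonStart:(codonStart + 2L)]
      altCodon <- refCodon
      altCodon[cp] <- if (info$strand == "-")
        .COMPLEMENT[[calls$alt[i]]] else calls$alt[i]
      refAA <- code[[paste(refCodon, collapse = "")]]
      altAA <- code[[paste(altCodon, collapse = "")]]
      eff <- if (refAA == altAA) "synonymous"
             else if (altAA == "*") "stopgain"
             else "nonsynonymous"
    }
    if (.EFFECT_SEVERITY[[eff]] < .EFFECT_SEVERITY[[out$effect[i]]]) {
      out$effect[i] <- eff
      out$gene_id[i] <- g
      out$refAA[i] <- refAA
      out$altAA[i] <- altAA
      out$codonPos[i] <- cp
    }
  }
  out
}

#' Synonymous / non-synonymous summary
#'
#' Fraction of coding variants that change the protein
#' (nonsynonymous + stopgain) versus synonymous, over coding sites only.
#'
#' @param effects data.frame from [annotateEffects()].
#' @return list with `nCoding`, `nNonsynonymous`, `nSynonymous`,
#'   `fractionNonsynonymous` (NA, flagged, when no coding site).
#' @export
synNonsynSummary <- function(effects) {
  coding <- effects$effect %in% c("synonymous", "nonsynonymous", "stopgain")
  nC <- sum(coding)
  nNS <- sum(effects$effect %in% c("nonsynonymous", "stopgain"))
  list(nCoding = nC, nNonsynonymous = nNS, nSynonymous = nC - nNS,
       fractionNonsynonymous = if (nC > 0) nNS / nC else NA_real_)
}

# one-sided hypergeometric over-representation p-value
.hyperP <- function(k, n, K, N) {
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Long-gene over-representation test
#'
#' One-sided hypergeometric test for an excess of long genes (genomic span
#' above `lengthThreshold`) among the foreground genes relative to the
#' background universe.
#'
#' @param fgGenes data.frame with `gene_id` and `length` (bp), or character
#'   gene ids looked up in `bgGenes`.
#' @param bgGenes data.frame with `gene_id` and `length` for the universe
#'   (must contain the foreground).
#' @param lengthThreshold genes strictly longer are "long" (default 1e5 bp).
#' @return list with `k`, `n`, `K`, `N`, `fractionFgLong`,
#'   `fractionBgLong`, `pValue`.
#' @export
longGeneTest <- function(fgGenes, bgGenes, lengthThreshold = 1e5) {
  if (is.character(fgGenes))
    fgGenes <- bgGenes[bgGenes$gene_id %in% fgGenes, , drop = FALSE]
  if (!all(c("gene_id", "length") %in% colnames(bgGenes)))
    stop("bgGenes needs columns gene_id and length")
  N <- nrow(bgGenes)
  n <- nrow(fgGenes)
  if (n == 0 || N == 0) stop("empty gene list")
  K <- sum(bgGenes$length > lengthThreshold)
  k <- sum(fgGenes$length > lengthThreshold)
  list(k = k, n = n, K = K, N = N,
       fractionFgLong = k / n, fractionBgLong = K / N,
       pValue = .hyperP(k, n, K, N))
}

#' Gene-set over-representation analysis
#'
#' Hypergeometric test of a foreground gene list against each gene set,
#' with Benjamini-Hochberg adjustment across sets. Sets are intersected
#' with the universe; the foreground must be a subset of the universe.
#'
#' @param fgGenes character vector of foreground gene ids.
#' @param geneSets named list of character vectors (see [readGmt()]).
#' @param universe character vector, the background gene universe.
#' @return data.frame sorted by ascending p-value with columns `set`, `k`,
#'   `n`, `K`, `N`, `pValue`, `padj`.
#' @export
overrepresentation <- function(fgGenes, geneSets, universe) {
  fgGenes <- unique(fgGenes)
  universe <- unique(universe)
  if (!all(fgGenes %in% universe))
    stop("foreground genes must be a subset of the universe")
  N <- length(universe)
  n <- length(fgGenes)
  rows <- lapply(names(geneSets), function(nm) {
    set <- intersect(geneSets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(fgGenes, set))
    data.frame(set = nm, k = k, n = n, K = K, N = N,
               pValue = if (K > 0) .hyperP(k, n, K, N) else 1,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$padj <- p.adjust(res$pValue, method = "BH")
  res <- res[order(res$pValue, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}
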