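#' @include PileupCounts-class.R PairedCalls-class.R
NULL

# Pileup TSV dialect
# ------------------
# One row per site. Columns:
#   chrom  pos  ref  A  C  G  T  meanBQ_A  meanBQ_C  meanBQ_G  meanBQ_T  meanMQ
# where each of A,C,G,T is a comma-joined quadruple
# "fwdF1R2,fwdF2R1,revF1R2,revF2R1" of non-negative integer read counts.
# Mean base qualities are per-allele phred means ("NA" where the allele has
# no reads); meanMQ is the per-site mean mapping quality. This dialect exists
# because classic samtools mpileup text cannot represent read-pair
# orientation (F1R2/F2R1), which the oxidative-artifact filter needs.

.PILEUP_HEADER <- c("chrom", "pos", "ref", "A", "C", "G", "T",
                    "meanBQ_A", "meanBQ_C", "meanBQ_G", "meanBQ_T", "meanMQ")

#' Read a pileup table
#'
#' Reads the package's pileup TSV dialect (documented in the README and in
#' the source of this function): per-site, per-tissue read counts for each
#' base split by strand and read-pair orientation.
#'
#' @param path path to a tab-separated pileup file with header row.
#' @return a [PileupCounts-class] object, one element per input row, order
#'   preserved.
#' @export
readPileupTable <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                  check.names = FALSE)
  if (!identical(colnames(d), .PILEUP_HEADER))
    stop("pileup header mismatch; expected: ",
         paste(.PILEUP_HEADER, collapse = " "))
  n <- nrow(d)
  counts <- matrix(0L, n, 16L, dimnames = list(NULL, .COUNT_COLS))
  if (n > 0) {
    pos <- suppressWarnings(as.integer(d$pos))
    bad <- which(is.na(pos) | pos < 1L)
    if (length(bad))
      stop("invalid pos at line ", bad[1] + 1L, " (1-based positions required)")
    ref <- toupper(d$ref)
    bad <- which(!ref %in% .BASES)
    if (length(bad))
      stop("unknown ref base at line ", bad[1] + 1L)
    for (b in seq_len(4L)) {
      parts <- strsplit(d[[.BASES[b]]], ",", fixed = TRUE)
      len <- lengths(parts)
      bad <- which(len != 4L)
      if (length(bad))
        stop("malformed count quadruple at line ", bad[1] + 1L,
             " (column ", .BASES[b], ")")
      vals <- suppressWarnings(as.integer(unlist(parts)))
      if (anyNA(vals))
        stop("non-integer count in column ", .BASES[b], " at line ",
             which(is.na(matrix(vals, ncol = 4L, byrow = TRUE)),
                   arr.ind = TRUE)[1, 1] + 1L)
      if (any(vals < 0L))
        stop("negative count in column ", .BASES[b], " at line ",
             which(matrix(vals < 0L, ncol = 4L, byrow = TRUE),
                   arr.ind = TRUE)[1, 1] + 1L)
      counts[, (b - 1L) * 4L + 1:4] <- matrix(vals, ncol = 4L, byrow = TRUE)
    }
    bq <- sapply(paste0("meanBQ_", .BASES), function(cn)
      suppressWarnings(as.numeric(d[[cn]])))
    if (is.null(dim(bq))) bq <- matrix(bq, nrow = 1L)
    mq <- suppressWarnings(as.numeric(d$meanMQ))
    PileupCounts(d$chrom, pos, ref, counts, baseQual = bq, mapQual = mq)
  } else {
    PileupCounts(character(), integer(), character(), counts,
                 baseQual = matrix(numeric(), 0L, 4L), mapQual = numeric())
  }
}

#' Write a pileup table
#'
#' Inverse of [readPileupTable()]; integer counts and coordinates round-trip
#' exactly.
#'
#' @param x a [PileupCounts-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePileupTable <- function(x, path) {
  n <- length(x)
  quad <- function(b) {
    off <- (b - 1L) * 4L
    paste(x@counts[, off + 1L], x@counts[, off + 2L],
          x@counts[, off + 3L], x@counts[, off + 4L], sep = ",")
  }
  d <- data.frame(chrom = x@chrom, pos = x@pos, ref = x@ref,
                  A = quad(1L), C = quad(2L), G = quad(3L), T = quad(4L),
                  stringsAsFactors = FALSE)
  for (b in seq_len(4L))
    d[[paste0("meanBQ_", .BASES[b])]] <- x@baseQual[, b]
  d$meanMQ <- x@mapQual
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

#' Write paired calls to VCF 4.2
#'
#' Emits one data line per call with INFO keys `SOMATIC_P`, `STATUS`,
#' `VAF_T1`, `VAF_T2`; the FILTER column carries the artifact-filter flags
#' (`PASS` when unflagged). Sites with no alternate allele are written with
#' ALT `.`.
#'
#' @param calls a [PairedCalls-class] object, sorted by (chrom, pos).
#' @param path output path.
#' @param referenceName optional reference name for the header.
#' @return `path`, invisibly.
#' @export
writeCallsVcf <- function(calls, path, referenceName = NULL) {
  d <- calls@data
  o <- order(d$chrom, d$pos)
  if (!identical(o, seq_len(nrow(d))))
    stop("calls must be sorted by (chrom, pos)")
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=oxisoma-%s", as.character(packageVersion("oxisoma"))),
    if (!is.null(referenceName)) sprintf("##reference=%s", referenceName),
    '##INFO=<ID=SOMATIC_P,Number=1,Type=Float,Description="One-sided Fisher exact somatic p-value">',
    '##INFO=<ID=STATUS,Number=1,Type=String,Description="Reference, Germline, Somatic or Undetermined">',
    '##INFO=<ID=VAF_T1,Number=1,Type=Float,Description="Variant allele frequency in tissue 1">',
    '##INFO=<ID=VAF_T2,Number=1,Type=Float,Description="Variant allele frequency in tissue 2">',
    '##FILTER=<ID=strand_bias,Description="More than the allowed fraction of variant reads on one strand">',
    '##FILTER=<ID=orientation_bias,Description="All variant reads share one read-pair orientation (F1R2 or F2R1)">',
    '##FILTER=<ID=identity_region,Description="Site falls in a region highly similar to another genomic region">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  lines <- hdr
  if (nrow(d) > 0) {
    alt <- ifelse(is.na(d$alt), ".", d$alt)
    filt <- ifelse(d$filters == "", "PASS", d$filters)
    info <- sprintf("SOMATIC_P=%s;STATUS=%s;VAF_T1=%s;VAF_T2=%s",
                    sprintf("%.6g", d$somaticP), d$status,
                    sprintf("%.4f", d$vaf1), sprintf("%.4f", d$vaf2))
    lines <- c(lines, paste(d$chrom, d$pos, ".", d$ref, alt, ".",
                            filt, info, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line — name, description, then tab-separated
#' member gene ids. Duplicate members within a set are de-duplicated.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors of member gene ids.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(setNames(list(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1], " has fewer than 3 fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional descriptions (recycled; default `"na"`).
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path, descriptions = "na") {
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GFF-lite table
#'
#' GFF-lite is a minimal tab format with header
#' `gene_id chrom strand feature start end` and one row per feature;
#' `feature` is `gene` (span) or `CDS` (coding segment), coordinates 1-based
#' inclusive. A gene without an explicit `gene` row gets the span of its CDS
#' segments. CDS total length must be divisible by 3.
#'
#' @param path path to a GFF-lite file.
#' @return a `data.frame` with columns `gene_id`, `chrom`, `strand`,
#'   `feature`, `start`, `end` (CDS rows sorted by genomic start), carrying a
#'   `geneSpans` attribute data.frame (`gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `length`).
#' @export
readGeneModels <- function(path) {
  d <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "feature", "start", "end")
  if (!all(need %in% colnames(d)))
    stop("GFF-lite header must contain: ", paste(need, collapse = " "))
  if (any(!d$strand %in% c("+", "-")))
    stop("strand must be + or -")
  if (any(d$start > d$end)) stop("start > end in gene model")
  if (any(!d$feature %in% c("gene", "CDS")))
    stop("feature must be 'gene' or 'CDS'")
  cds <- d[d$feature == "CDS", , drop = FALSE]
  cds <- cds[order(cds$gene_id, cds$start), , drop = FALSE]
  cdsLen <- tapply(cds$end - cds$start + 1L, cds$gene_id, sum)
  badLen <- names(cdsLen)[cdsLen %% 3L != 0L]
  if (length(badLen))
    stop("CDS length not divisible by 3 for gene: ", badLen[1])
  spans <- d[d$feature == "gene", need, drop = FALSE]
  noSpan <- setdiff(unique(d$gene_id), spans$gene_id)
  if (length(noSpan)) {
    extra <- do.call(rbind, lapply(noSpan, function(g) {
      rows <- cds[cds$gene_id == g, , drop = FALSE]
      data.frame(gene_id = g, chrom = rows$chrom[1], strand = rows$strand[1],
                 feature = "gene", start = min(rows$start),
                 end = max(rows$end), stringsAsFactors = FALSE)
    }))
    spans <- rbind(spans, extra)
  }
  spans$length <- spans$end - spans$start + 1L
  spans$feature <- NULL
  res <- d[order(d$gene_id, d$feature != "gene", d$start), need]
  rownames(res) <- NULL
  attr(res, "geneSpans") <- spans[order(spans$gene_id), , drop = FALSE]
  res
}

#' Write gene models to a GFF-lite table
#'
#' @param models data.frame as returned by [readGeneModels()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(models, path) {
  write.table(models[, c("gene_id", "chrom", "strand", "feature",
                         "start", "end")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an identity-region mask from BED
#'
#' BED intervals (0-based half-open on disk) become a 1-based `GRanges`
#' in memory; overlapping intervals keep union semantics via [reduce()].
#'
#' @param path path to a BED file.
#' @return a `GRanges` mask.
#' @export
readRegionMask <- function(path) {
  reduce(rtracklayer::import(path, format = "BED"))
}

#' Write an identity-region mask to BED
#'
#' @param mask a `GRanges`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRegionMask <- function(mask, path) {
  rtracklayer::export(mask, path, format = "BED")
  invisible(path)
}

#' Read a reference sequence from FASTA
#'
#' @param path FASTA path.
#' @return a named `DNAStringSet` (uppercased).
#' @export
readReference <- function(path) {
  x <- readDNAStringSet(path)
  if (length(x) < 1L) stop("empty reference FASTA")
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write a reference sequence to FASTA
#'
#' @param ref a `DNAStringSet` (or `DNAString`, written as `ref`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReference <- function(ref, path) {
  if (is(ref, "DNAString")) {
    ref <- DNAStringSet(ref)
    names(ref) <- "ref"
  }
  writeXStringSet(ref, path)
  invisible(path)
}
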