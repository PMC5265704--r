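# Fixture builders shared across test files. Everything is constructed in
# code; nothing is read from stored binary data.

# Build a single-site (or multi-site) PileupCounts from per-allele totals.
# counts: named list / vector per site, e.g. list(G = 60, T = 40).
# Cell-level control via a 16-vector named by oxisoma's canonical columns.
makeSite <- function(ref, counts, pos = 100L, chrom = "chr1",
                     baseQual = NULL, mapQual = 60) {
  cells <- c("fwd_F1R2", "fwd_F2R1", "rev_F1R2", "rev_F2R1")
  bases <- c("A", "C", "G", "T")
  cols <- as.vector(t(outer(bases, cells, paste, sep = "_")))
  full <- matrix(0L, 1L, 16L, dimnames = list(NULL, cols))
  for (nm in names(counts)) {
    v <- counts[[nm]]
    if (nm %in% bases) {
      # spread an allele total evenly over its 4 cells
      q <- as.integer(v) %/% 4L; r <- as.integer(v) %% 4L
      b <- match(nm, bases)
      for (cell in 1:4)
        full[1, (b - 1L) * 4L + cell] <- q + as.integer(r >= cell)
    } else {
      full[1, nm] <- as.integer(v)
    }
  }
  PileupCounts(chrom, pos, ref, full, baseQual = baseQual, mapQual = mapQual)
}

# Stack several single-site PileupCounts into one object.
bindSites <- function(...) {
  xs <- list(...)
  PileupCounts(
    chrom = unlist(lapply(xs, siteChrom)),
    pos = unlist(lapply(xs, sitePos)),
    ref = unlist(lapply(xs, siteRef)),
    counts = do.call(rbind, lapply(xs, function(x) x@counts)),
    baseQual = do.call(rbind, lapply(xs, function(x) x@baseQual)),
    mapQual = unlist(lapply(xs, function(x) x@mapQual)))
}

# A tiny two-gene reference + GFF-lite models for annotation tests:
# gene PLUS1 (+ strand) and MINUS1 (- strand), each one CDS exon.
makeToyGenome <- function() {
  # 120 bp; CDS of PLUS1 = 11..40 (30 bp), CDS of MINUS1 = 71..100 (30 bp)
  set.seed(99)
  bases <- sample(c("A", "C", "G", "T"), 120, replace = TRUE)
  # make PLUS1 CDS begin ATG and avoid internal stops by construction:
  # write explicit codons
  plusCodons <- c("ATG", "GCT", "GAG", "TGG", "AAA", "CCC", "GGG", "TTT",
                  "CAT", "TAA")
  bases[11:40] <- strsplit(paste(plusCodons, collapse = ""), "")[[1]]
  # MINUS1: transcript codons read on the minus strand
  minusCodons <- c("ATG", "GAA", "TGC", "CTG", "ACA", "CCA", "GTT", "GCA",
                   "CGT", "TGA")
  txSeq <- strsplit(paste(minusCodons, collapse = ""), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases[71:100] <- rev(comp[txSeq])
  refChar <- paste(bases, collapse = "")
  models <- data.frame(
    gene_id = c("PLUS1", "PLUS1", "MINUS1", "MINUS1"),
    chrom = "chr1",
    strand = c("+", "+", "-", "-"),
    feature = c("gene", "CDS", "gene", "CDS"),
    start = c(5L, 11L, 65L, 71L),
    end = c(50L, 40L, 110L, 100L),
    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".gffl")
  oxisoma::writeGeneModels(models, f)
  gm <- oxisoma::readGeneModels(f)
  unlink(f)
  list(refChar = refChar, models = gm)
}

# Random toy gene models over a random reference, for the annotation oracle
# property test. Returns refChar + models with nGenes alternating strands.
makeRandomGenome <- function(L = 3000, nGenes = 6, seed = 1) {
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  rows <- list()
  cursor <- 21L
  for (g in seq_len(nGenes)) {
    span <- sample(200:400, 1)
    if (cursor + span > L - 20L) break
    nEx <- sample(1:3, 1)
    exLen <- (sample(10:40, nEx, replace = TRUE) %/% 3L) * 3L
    gaps <- sample(5:30, nEx, replace = TRUE)
    exStart <- cursor + 10L + cumsum(c(0L, (exLen + gaps)[-nEx]))
    exEnd <- exStart + exLen - 1L
    keep <- exEnd <= cursor + span - 10L
    exStart <- exStart[keep]; exEnd <- exEnd[keep]
    if (!length(exStart)) { cursor <- cursor + span + 20L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = sprintf("G%02d", g), chrom = "chr1",
      strand = if (g %% 2 == 0) "-" else "+",
      feature = c("gene", rep("CDS", length(exStart))),
      start = c(cursor, exStart), end = c(cursor + span - 1L, exEnd),
      stringsAsFactors = FALSE)
    cursor <- cursor + span + sample(20:60, 1)
  }
  models <- do.call(rbind, rows)
  f <- tempfile(fileext = ".gffl")
  oxisoma::writeGeneModels(models, f)
  gm <- oxisoma::readGeneModels(f)
  unlink(f)
  list(refChar = paste(bases, collapse = ""), models = gm)
}

# The 14-record amplicon validation fixture mirroring the reported
# structure: 10 records satisfy the conjunctive rule, 4 fail one conjunct
# each (reads / fold / direction / fold-tie).
makeValidationFixture <- function() {
  rec <- function(site, d1, d2, v1, v2, r1, r2)
    data.frame(site = site, t1_disc_vaf = d1, t2_disc_vaf = d2,
               t1_val_vaf = v1, t2_val_vaf = v2,
               t1_val_varreads = r1, t2_val_varreads = r2,
               stringsAsFactors = FALSE)
  passing <- do.call(rbind, lapply(1:10, function(i)
    rec(sprintf("chr1:%d", 1000 + i),
        d1 = 0.40, d2 = 0.02,
        v1 = 0.30, v2 = 0.10, r1 = 150 + i, r2 = 50)))
  failing <- rbind(
    rec("chr1:2001", 0.40, 0.02, 0.30, 0.10, 90, 40),    # < 100 reads
    rec("chr1:2002", 0.40, 0.02, 0.15, 0.10, 200, 120),  # fold 1.5 < 2
    rec("chr1:2003", 0.40, 0.02, 0.10, 0.30, 150, 400),  # direction flipped
    rec("chr1:2004", 0.40, 0.02, 0.00, 0.00, 0, 0))      # both zero
  rbind(passing, failing)
}
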