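#' @include AllGenerics.R
NULL

#' PileupCounts: per-site, per-tissue read evidence
#'
#' The atom of the pipeline: for each genomic site, read counts for each of
#' the four bases split into four cells — (forward strand, F1R2),
#' (forward, F2R1), (reverse, F1R2), (reverse, F2R1) — plus per-allele mean
#' base quality and a per-site mean mapping quality. Coordinates are 1-based.
#'
#' @slot chrom character, chromosome per site.
#' @slot pos integer, 1-based position per site.
#' @slot ref character, reference base per site (A/C/G/T).
#' @slot counts integer matrix, n x 16, columns `A_fwd_F1R2` ... `T_rev_F2R1`.
#' @slot baseQual numeric matrix, n x 4, mean phred base quality per allele
#'   (`NA` where the allele has no reads).
#' @slot mapQual numeric, per-site mean phred mapping quality.
#'
#' @param x a `PileupCounts` object.
#' @name PileupCounts-class
#' @aliases PileupCounts
#' @export
setClass("PileupCounts",
  representation(
    chrom = "character",
    pos = "integer",
    ref = "character",
    counts = "matrix",
    baseQual = "matrix",
    mapQual = "numeric"
  )
)

setValidity("PileupCounts", function(object) {
  n <- length(object@pos)
  msgs <- character()
  if (length(object@chrom) != n || length(object@ref) != n ||
      nrow(object@counts) != n || nrow(object@baseQual) != n ||
      length(object@mapQual) != n)
    msgs <- c(msgs, "slot lengths disagree")
  if (ncol(object@counts) != 16L ||
      !identical(colnames(object@counts), .COUNT_COLS))
    msgs <- c(msgs, "counts must have the 16 canonical columns")
  if (ncol(object@baseQual) != 4L)
    msgs <- c(msgs, "baseQual must have 4 columns (A,C,G,T)")
  if (n > 0) {
    if (any(object@pos < 1L)) msgs <- c(msgs, "pos must be >= 1 (1-based)")
    if (any(!object@ref %in% .BASES))
      msgs <- c(msgs, "ref base must be one of A,C,G,T")
    if (any(object@counts < 0L)) msgs <- c(msgs, "counts must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PileupCounts object
#'
#' @param chrom,pos,ref site coordinates and reference base (recycled to the
#'   number of sites).
#' @param counts n x 16 count matrix (columns `A_fwd_F1R2` ...), or an n x 4
#'   per-allele depth matrix which is then split evenly-as-possible across
#'   cells (convenience for fixtures).
#' @param baseQual n x 4 mean base-quality matrix; defaults to 35 where the
#'   allele has reads.
#' @param mapQual per-site mean mapping quality; default 60.
#' @return a [PileupCounts-class] object.
#' @export
PileupCounts <- function(chrom, pos, ref, counts,
                         baseQual = NULL, mapQual = NULL) {
  n <- max(length(pos), nrow(counts))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.integer(pos), n)
  ref <- rep_len(toupper(as.character(ref)), n)
  counts <- as.matrix(counts)
  if (ncol(counts) == 4L) {
    # per-allele totals: spread deterministically over the 4 cells
    full <- matrix(0L, n, 16L, dimnames = list(NULL, .COUNT_COLS))
    for (b in seq_len(4L)) {
      tot <- as.integer(counts[, b])
      q <- tot %/% 4L
      r <- tot %% 4L
      for (cell in seq_len(4L))
        full[, (b - 1L) * 4L + cell] <- q + as.integer(r >= cell)
    }
    counts <- full
  }
  storage.mode(counts) <- "integer"
  colnames(counts) <- .COUNT_COLS
  if (is.null(baseQual)) {
    ad <- .alleleDepthFromCounts(counts)
    baseQual <- matrix(ifelse(ad > 0, 35, NA_real_), n, 4L)
  }
  baseQual <- as.matrix(baseQual)
  colnames(baseQual) <- .BASES
  if (is.null(mapQual)) mapQual <- rep(60, n)
  new("PileupCounts", chrom = chrom, pos = pos, ref = ref,
      counts = counts, baseQual = baseQual, mapQual = as.numeric(mapQual))
}

.alleleDepthFromCounts <- function(counts) {
  ad <- sapply(seq_len(4L), function(b)
    rowSums(counts[, (b - 1L) * 4L + 1:4, drop = FALSE]))
  if (is.null(dim(ad))) ad <- matrix(ad, nrow = 1L)
  colnames(ad) <- .BASES
  ad
}

#' @rdname PileupCounts-class
#' @export
setMethod("siteChrom", "PileupCounts", function(x) x@chrom)

#' @rdname PileupCounts-class
#' @export
setMethod("sitePos", "PileupCounts", function(x) x@pos)

#' @rdname PileupCounts-class
#' @export
setMethod("siteRef", "PileupCounts", function(x) x@ref)

#' @rdname PileupCounts-class
#' @export
setMethod("siteDepth", "PileupCounts", function(x) rowSums(x@counts))

#' @rdname PileupCounts-class
#' @export
setMethod("alleleDepth", "PileupCounts",
          function(x) .alleleDepthFromCounts(x@counts))

#' @rdname PileupCounts-class
#' @export
setMethod("length", "PileupCounts", function(x) length(x@pos))

#' @rdname PileupCounts-class
#' @param i index vector for subsetting.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PileupCounts", function(x, i, j, ..., drop = FALSE) {
  new("PileupCounts",
      chrom = x@chrom[i], pos = x@pos[i], ref = x@ref[i],
      counts = x@counts[i, , drop = FALSE],
      baseQual = x@baseQual[i, , drop = FALSE],
      mapQual = x@mapQual[i])
})

#' @rdname PileupCounts-class
#' @param object a `PileupCounts` object.
#' @export
setMethod("show", "PileupCounts", function(object) {
  n <- length(object)
  cat("PileupCounts with", n, "sites\n")
  if (n > 0) {
    d <- siteDepth(object)
    cat("  chrom:", paste(unique(object@chrom), collapse = ","),
        " pos:", min(object@pos), "-", max(object@pos), "\n")
    cat("  depth: mean", round(mean(d), 1), " range",
        min(d), "-", max(d), "\n")
  }
  invisible(NULL)
})

# per-allele counts in a given cell dimension
.strandCounts <- function(x, base) {
  b <- match(base, .BASES)
  off <- (b - 1L) * 4L
  cbind(fwd = x@counts[cbind(seq_along(b), off + 1L)] +
              x@counts[cbind(seq_along(b), off + 2L)],
        rev = x@counts[cbind(seq_along(b), off + 3L)] +
              x@counts[cbind(seq_along(b), off + 4L)])
}

.orientationCounts <- function(x, base) {
  b <- match(base, .BASES)
  off <- (b - 1L) * 4L
  cbind(F1R2 = x@counts[cbind(seq_along(b), off + 1L)] +
               x@counts[cbind(seq_along(b), off + 3L)],
        F2R1 = x@counts[cbind(seq_along(b), off + 2L)] +
               x@counts[cbind(seq_along(b), off + 4L)])
}
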