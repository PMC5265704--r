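#' @include PileupCounts-class.R PairedCalls-class.R
NULL

#' Strand-bias filter
#'
#' A variant call fails when more than `maxStrandBias` of its
#' variant-supporting reads come from one strand (computed on variant reads
#' only, not total depth). Vectorised over sites.
#'
#' @param site a [PileupCounts-class] object.
#' @param altBase alternate allele per site.
#' @param maxStrandBias strict fraction threshold (default 0.90).
#' @return logical: `TRUE` = pass, `FALSE` = fail.
#' @export
strandBiasFilter <- function(site, altBase, maxStrandBias = 0.90) {
  sc <- .strandCounts(site, altBase)
  tot <- rowSums(sc)
  if (any(tot == 0))
    stop("strand-bias filter requires >= 1 variant-supporting read")
  pmax(sc[, "fwd"], sc[, "rev"]) / tot <= maxStrandBias
}

#' Read-pair orientation-bias filter
#'
#' A variant call fails when every variant-supporting read shares one
#' read-pair orientation (all F1R2, or all F2R1) — the hallmark of oxidative
#' 8-oxo-dG / DNA-shearing artifacts. All-or-nothing: a single read in the
#' other orientation passes the site.
#'
#' @param site a [PileupCounts-class] object.
#' @param altBase alternate allele per site.
#' @return logical: `TRUE` = pass, `FALSE` = fail.
#' @export
orientationBiasFilter <- function(site, altBase) {
  oc <- .orientationCounts(site, altBase)
  tot <- rowSums(oc)
  if (any(tot == 0))
    stop("orientation-bias filter requires >= 1 variant-supporting read")
  oc[, "F1R2"] > 0 & oc[, "F2R1"] > 0
}

#' Identity-region mask filter
#'
#' A site fails when its position intersects the mask (union semantics).
#'
#' @param chrom,pos site coordinates (1-based).
#' @param mask a `GRanges` mask (1-based in memory; see [readRegionMask()]).
#' @return logical: `TRUE` = pass (outside mask), `FALSE` = fail.
#' @export
identityMaskFilter <- function(chrom, pos, mask) {
  if (length(mask) == 0) return(rep(TRUE, length(pos)))
  gr <- GRanges(chrom, IRanges(pos, pos))
  countOverlaps(gr, mask) == 0L
}

#' Build an identity mask from a reference by ungapped self-comparison
#'
#' Slides a window over the reference and masks every window whose best
#' ungapped alignment to any other non-overlapping window (every offset
#' >= `window`) reaches `minIdentity`. Deterministic; O(L^2) in reference
#' length, intended for the synthetic references this package simulates —
#' real analyses normally supply a curated BED mask instead.
#'
#' @param reference a `DNAString`/`DNAStringSet` (first sequence used) or
#'   character.
#' @param window window size in bp (>= 20).
#' @param minIdentity identity fraction in (0, 1] (default 0.87).
#' @param chromName chromosome name for the returned ranges.
#' @return a reduced `GRanges` (1-based) of masked regions; empty when the
#'   reference is shorter than two windows.
#' @export
buildIdentityMask <- function(reference, window = 100L, minIdentity = 0.87,
                              chromName = "chr1") {
  stopifnot(window >= 20L, minIdentity > 0, minIdentity <= 1)
  s <- .refToChar(reference)
  x <- utf8ToInt(s)
  L <- length(x)
  if (L < 2L * window)
    return(GRanges())
  window <- as.integer(window)
  hit <- logical(L - window + 1L)       # window start positions
  for (d in seq.int(window, L - window)) {
    m <- x[seq_len(L - d)] == x[seq.int(1L + d, L)]
    nWin <- L - d - window + 1L
    if (nWin < 1L) break
    cs <- cumsum(m)
    ident <- (cs[seq.int(window, window + nWin - 1L)] -
              c(0, cs[seq_len(nWin - 1L)])) / window
    w <- which(ident >= minIdentity)
    if (length(w)) {
      hit[w] <- TRUE
      hit[w + d] <- TRUE
    }
  }
  starts <- which(hit)
  if (!length(starts)) return(GRanges())
  reduce(GRanges(chromName, IRanges(starts, starts + window - 1L)))
}

.refToChar <- function(reference) {
  if (is(reference, "DNAStringSet")) reference <- reference[[1]]
  toupper(as.character(reference))
}

#' Apply all artifact filters to paired calls
#'
#' Flags each variant call (any site with an alternate allele and at least
#' one variant-supporting read) that fails the strand-bias,
#' orientation-bias, or identity-region filter. Strand and orientation are
#' evaluated on the summed variant-read evidence of both tissues. Filters
#' are order-independent; flags accumulate in the `filters` column
#' (semicolon-joined, stable order `strand_bias;orientation_bias;
#' identity_region`).
#'
#' @param calls a [PairedCalls-class] object.
#' @param t1,t2 the two tissues' [PileupCounts-class] used for the calls.
#' @param mask optional `GRanges` identity mask.
#' @param maxStrandBias strand-bias threshold (default from the calls'
#'   [CallingParams-class]).
#' @return `calls` with the `filters` column populated.
#' @export
applyArtifactFilters <- function(calls, t1, t2, mask = NULL,
                                 maxStrandBias = NULL) {
  if (is.null(maxStrandBias)) maxStrandBias <- calls@params@maxStrandBias
  d <- calls@data
  n <- nrow(d)
  flags <- matrix(FALSE, n, 3,
                  dimnames = list(NULL, c("strand_bias", "orientation_bias",
                                          "identity_region")))
  hasVar <- !is.na(d$alt) & (d$varReads1 + d$varReads2) > 0
  if (any(hasVar)) {
    comb <- t1[hasVar]
    comb@counts <- comb@counts + t2[hasVar]@counts
    altB <- d$alt[hasVar]
    flags[hasVar, "strand_bias"] <-
      !strandBiasFilter(comb, altB, maxStrandBias)
    flags[hasVar, "orientation_bias"] <- !orientationBiasFilter(comb, altB)
  }
  if (!is.null(mask) && length(mask) > 0)
    flags[, "identity_region"] <- !identityMaskFilter(d$chrom, d$pos, mask)
  joined <- apply(flags, 1, function(f)
    paste(colnames(flags)[f], collapse = ";"))
  d$filters <- joined
  new("PairedCalls", data = d, params = calls@params)
}
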