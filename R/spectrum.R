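#' @include PairedCalls-class.R SpectrumTable-class.R
NULL

#' Collapse an SNV to its strand-symmetric substitution class
#'
#' Complementary changes map to the same class (C>A and G>T are both
#' `G:C>T:A`). Vectorised.
#'
#' @param refBase,altBase single reference / alternate bases.
#' @return character vector of classes (see [SUBSTITUTION_CLASSES]).
#' @export
collapseClass <- function(refBase, altBase) {
  refBase <- toupper(refBase); altBase <- toupper(altBase)
  if (any(!refBase %in% .BASES) || any(!altBase %in% .BASES))
    stop("bases must be A, C, G or T")
  if (any(refBase == altBase)) stop("ref and alt must differ")
  # orient to the purine (A or G) reference strand
  flip <- refBase %in% c("C", "T")
  r <- ifelse(flip, .COMPLEMENT[refBase], refBase)
  a <- ifelse(flip, .COMPLEMENT[altBase], altBase)
  key <- paste0(r, a)
  map <- c(AG = "A:T>G:C", GA = "G:C>A:T", GT = "G:C>T:A",
           AT = "A:T>T:A", AC = "A:T>C:G", GC = "G:C>C:G")
  unname(map[key])
}

#' Six-class substitution spectrum of a call subset
#'
#' @param calls a [PairedCalls-class] object.
#' @param status which status to tabulate (default `"Somatic"`); pass `NULL`
#'   to use all calls with an alternate allele.
#' @param label label stored in the result (defaults to the status,
#'   lower-cased).
#' @param keptOnly drop calls carrying artifact-filter flags (default TRUE).
#' @return a [SpectrumTable-class]; proportions are `NaN` (and `total` 0)
#'   for an empty subset.
#' @export
mutationSpectrum <- function(calls, status = "Somatic", label = NULL,
                             keptOnly = TRUE) {
  d <- calls@data
  keep <- !is.na(d$alt)
  if (!is.null(status)) keep <- keep & d$status %in% status
  if (keptOnly) keep <- keep & d$filters == ""
  d <- d[keep, , drop = FALSE]
  if (is.null(label))
    label <- if (is.null(status)) "all" else tolower(status[1])
  cls <- if (nrow(d)) collapseClass(d$ref, d$alt) else character()
  counts <- table(factor(cls, levels = SUBSTITUTION_CLASSES))
  counts <- setNames(as.numeric(counts), SUBSTITUTION_CLASSES)
  total <- sum(counts)
  props <- if (total > 0) counts / total else
    setNames(rep(NaN, 6), SUBSTITUTION_CLASSES)
  new("SpectrumTable", label = label, counts = counts,
      proportions = props, total = total)
}

#' Somatic-vs-germline spectrum enrichment
#'
#' Per-class difference of proportions, `somatic - germline`; positive
#' values mean the class is enriched among somatic calls. The six
#' differences sum to zero by construction.
#'
#' @param somatic,germline [SpectrumTable-class] objects from the same pair,
#'   both non-empty.
#' @return named numeric of length 6 in \[-1, 1\].
#' @export
spectrumEnrichment <- function(somatic, germline) {
  if (somatic@total == 0 || germline@total == 0)
    stop("enrichment requires non-empty somatic and germline spectra")
  somatic@proportions - germline@proportions
}

#' Tissue-resolved zygosity of somatic calls in one substitution class
#'
#' Uses the reporting thresholds, distinct from the calling thresholds: a
#' tissue with VAF > 0.10 is reported heterozygous, VAF < 0.05 homozygous
#' (reference); VAFs in \[0.05, 0.10\] are indeterminate. A site is
#' determinate when exactly one tissue is het and the other hom; the
#' reported fraction is het-in-tissue-1 over determinate sites.
#'
#' @param calls a [PairedCalls-class] object (somatic, unfiltered calls are
#'   selected internally).
#' @param class substitution class to restrict to (default `"G:C>T:A"`).
#' @param hetMin het threshold, strict (default 0.10).
#' @param homMax hom threshold, strict (default 0.05).
#' @return list with counts `hetT1`, `hetT2`, `indeterminate`, and
#'   `fractionHetT1` (NA when no determinate sites).
#' @export
zygosityByTissue <- function(calls, class = "G:C>T:A",
                             hetMin = 0.10, homMax = 0.05) {
  d <- calls@data
  keep <- d$status == "Somatic" & d$filters == "" & !is.na(d$alt)
  d <- d[keep, , drop = FALSE]
  if (nrow(d)) {
    cls <- collapseClass(d$ref, d$alt)
    d <- d[cls == class, , drop = FALSE]
  }
  zyg <- function(vaf) ifelse(vaf > hetMin, "het",
                       ifelse(vaf < homMax, "hom", "indet"))
  z1 <- zyg(d$vaf1); z2 <- zyg(d$vaf2)
  hetT1 <- sum(z1 == "het" & z2 == "hom")
  hetT2 <- sum(z2 == "het" & z1 == "hom")
  indet <- nrow(d) - hetT1 - hetT2
  list(hetT1 = hetT1, hetT2 = hetT2, indeterminate = indet,
       fractionHetT1 = if (hetT1 + hetT2 > 0) hetT1 / (hetT1 + hetT2)
                       else NA_real_)
}

# reference base at 1-based positions, as character vector
.refBaseAt <- function(reference, pos) {
  s <- .refToChar(reference)
  substring(s, pos, pos)
}

#' Distribution of the base 3' of the mutated G (G:C>T:A calls)
#'
#' Each event is re-oriented to the strand carrying the mutated G: for G>T
#' calls the 3' neighbour is the reference base at `pos + 1`; for C>A calls
#' the G sits on the minus strand and the 3' neighbour is the complement of
#' the base at `pos - 1`. Sites at the reference edge are excluded with a
#' warning.
#'
#' @param calls a [PairedCalls-class]; somatic unfiltered `G:C>T:A` calls
#'   are selected internally.
#' @param reference `DNAString`/`DNAStringSet`/character reference the calls
#'   were made against.
#' @return named numeric table of A/C/G/T counts at the +1 position.
#' @export
threePrimeContext <- function(calls, reference) {
  d <- .gctaSomatic(calls)
  s <- .refToChar(reference)
  L <- nchar(s)
  isG <- d$ref == "G"
  nbPos <- ifelse(isG, d$pos + 1L, d$pos - 1L)
  edge <- nbPos < 1L | nbPos > L
  if (any(edge)) {
    warning(sum(edge), " site(s) at the reference edge excluded")
    d <- d[!edge, , drop = FALSE]
    isG <- isG[!edge]; nbPos <- nbPos[!edge]
  }
  if (!nrow(d))
    return(setNames(rep(0, 4), .BASES))
  nb <- substring(s, nbPos, nbPos)
  nb[!isG] <- .COMPLEMENT[nb[!isG]]
  tab <- table(factor(nb, levels = .BASES))
  setNames(as.numeric(tab), .BASES)
}

#' Fraction of G:C>T:A calls whose mutated C sits mid-CCG
#'
#' Events are oriented to the pyrimidine (C) strand: a C>A call counts when
#' its plus-strand trinucleotide context is `CCG` (mutated base in the
#' middle); a G>T call counts when the plus-strand context is `CGG`, whose
#' minus-strand reading is `CCG`. Edge sites are excluded.
#'
#' @inheritParams threePrimeContext
#' @return list with `fraction`, `counted`, `evaluable`.
#' @export
ccgMotifFraction <- function(calls, reference) {
  d <- .gctaSomatic(calls)
  s <- .refToChar(reference)
  L <- nchar(s)
  edge <- d$pos < 2L | d$pos > L - 1L
  if (any(edge)) d <- d[!edge, , drop = FALSE]
  if (!nrow(d))
    return(list(fraction = NA_real_, counted = 0L, evaluable = 0L))
  tri <- substring(s, d$pos - 1L, d$pos + 1L)
  hitC <- d$ref == "C" & tri == "CCG"
  hitG <- d$ref == "G" & tri == "CGG"
  counted <- sum(hitC | hitG)
  list(fraction = counted / nrow(d), counted = counted,
       evaluable = nrow(d))
}

.gctaSomatic <- function(calls) {
  d <- as.data.frame(calls@data)
  keep <- d$status == "Somatic" & d$filters == "" & !is.na(d$alt)
  d <- d[keep, , drop = FALSE]
  if (nrow(d)) d <- d[collapseClass(d$ref, d$alt) == "G:C>T:A", ,
                      drop = FALSE]
  d
}
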