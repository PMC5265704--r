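#' @include PileupCounts-class.R PairedCalls-class.R
NULL

#' One-sided Fisher exact somatic p-value
#'
#' Probability, under the hypergeometric null of no allele-fraction
#' difference, of a 2x2 ref/var read-count table at least as extreme as the
#' observed one, one-sided toward the tissue with the higher variant allele
#' frequency (VarScan2 convention; ties resolve toward tissue 2). Vectorised
#' over sites.
#'
#' @param ref1,var1 reference / variant read counts in tissue 1.
#' @param ref2,var2 reference / variant read counts in tissue 2.
#' @return p-values in (0, 1].
#' @examples
#' fisherSomaticP(10, 0, 10, 0)   # identical tables -> 1
#' fisherSomaticP(10, 0, 0, 10)   # maximally different -> 1/choose(20,10)
#' @export
fisherSomaticP <- function(ref1, var1, ref2, var2) {
  n <- max(length(ref1), length(var1), length(ref2), length(var2))
  ref1 <- rep_len(ref1, n); var1 <- rep_len(var1, n)
  ref2 <- rep_len(ref2, n); var2 <- rep_len(var2, n)
  if (any(c(ref1, var1, ref2, var2) < 0))
    stop("read counts must be non-negative")
  n1 <- ref1 + var1
  n2 <- ref2 + var2
  if (any(n1 + n2 == 0))
    stop("both tissues have zero depth")
  V <- var1 + var2
  N <- n1 + n2
  vaf1 <- ifelse(n1 > 0, var1 / n1, 0)
  vaf2 <- ifelse(n2 > 0, var2 / n2, 0)
  # X = variant reads landing in tissue 2 | margins ~ Hypergeom(V, N-V, n2)
  toward2 <- vaf2 >= vaf1
  p <- numeric(n)
  if (any(toward2))
    p[toward2] <- phyper(var2[toward2] - 1, V[toward2],
                         N[toward2] - V[toward2], n2[toward2],
                         lower.tail = FALSE)
  if (any(!toward2))
    p[!toward2] <- phyper(var2[!toward2], V[!toward2],
                          N[!toward2] - V[!toward2], n2[!toward2],
                          lower.tail = TRUE)
  pmin(pmax(p, .Machine$double.xmin), 1)
}

# genotype from depth / variant support / quality gates; vectorised
.genotypeFromCounts <- function(depth, varReads, altBQ, refBQ, mapQual,
                                params) {
  vaf <- ifelse(depth > 0, varReads / depth, 0)
  gt <- ifelse(vaf >= params@minHomFreq, "hom_alt",
        ifelse(vaf >= params@minVarFreqHet, "het", "hom_ref"))
  # which allele's mean BQ gates the call: the variant allele when there is
  # variant support, otherwise the reference allele; missing means -> pass
  gateBQ <- ifelse(varReads > 0, altBQ, refBQ)
  noCall <- depth < params@minCoverage |
    (!is.na(mapQual) & mapQual < params@minMappingQuality) |
    (!is.na(gateBQ) & gateBQ < params@minBaseQuality)
  gt[noCall] <- "no_call"
  list(genotype = gt, vaf = vaf)
}

#' Call a per-tissue genotype at each site
#'
#' The alternate allele is the non-reference base with the highest read
#' count (ties broken in A<C<G<T order). VAF thresholds then assign the
#' genotype: VAF >= `minHomFreq` is `hom_alt`, VAF in
#' [`minVarFreqHet`, `minHomFreq`) is `het`, below `minVarFreqHet` is
#' `hom_ref`. Sites failing depth or quality gates are `no_call`.
#'
#' @param site a [PileupCounts-class] object (any number of sites).
#' @param params a [CallingParams-class].
#' @return a `DataFrame` with columns `genotype`, `altBase`, `vaf`, `depth`,
#'   `varReads`.
#' @export
callGenotype <- function(site, params = CallingParams()) {
  ad <- alleleDepth(site)
  refIdx <- match(site@ref, .BASES)
  nr <- ad
  nr[cbind(seq_len(nrow(nr)), refIdx)] <- -1L   # exclude ref from argmax
  altIdx <- max.col(nr, ties.method = "first")
  varReads <- ad[cbind(seq_len(nrow(ad)), altIdx)]
  altBase <- ifelse(varReads > 0, .BASES[altIdx], NA_character_)
  depth <- rowSums(ad)
  altBQ <- site@baseQual[cbind(seq_len(nrow(ad)), altIdx)]
  refBQ <- site@baseQual[cbind(seq_len(nrow(ad)), refIdx)]
  g <- .genotypeFromCounts(depth, varReads, altBQ, refBQ, site@mapQual,
                           params)
  DataFrame(genotype = g$genotype, altBase = altBase, vaf = g$vaf,
            depth = depth, varReads = varReads)
}

#' Confidence that an observed genotype is a real variant call
#'
#' Implements the "confidently called as same genotype (p < 0.05)" criterion
#' for germline sites: the tissue's variant/reference read split is compared
#' by a one-sided Fisher exact test against an expected homozygous-reference
#' error model (`germlineErrorRate` of the same depth); confidence means the
#' error model is rejected below `somaticPThreshold`.
#'
#' @param varReads,depth observed variant reads and total depth (vectorised).
#' @param params a [CallingParams-class].
#' @return logical vector.
#' @export
germlineConfident <- function(varReads, depth, params = CallingParams()) {
  expVar <- round(depth * params@germlineErrorRate)
  expRef <- depth - expVar
  ok <- depth > 0
  p <- rep(1, length(ok))
  if (any(ok))
    p[ok] <- fisherSomaticP(expRef[ok], expVar[ok],
                            (depth - varReads)[ok], varReads[ok])
  p < params@somaticPThreshold & varReads / pmax(depth, 1) >
    params@germlineErrorRate
}

#' Classify paired sites as Reference / Germline / Somatic / Undetermined
#'
#' For each site shared by the two tissues, chooses the best-supported
#' alternate allele from the combined counts, genotypes each tissue
#' ([callGenotype()] thresholds), computes the one-sided Fisher somatic
#' p-value on the paired ref/var table, and assigns a status:
#' \itemize{
#'   \item `Somatic` — differing genotypes (neither `no_call`) and somatic
#'     p-value below threshold;
#'   \item `Germline` — equal non-reference genotypes, confidently supported
#'     in both tissues ([germlineConfident()]);
#'   \item `Reference` — both `hom_ref`;
#'   \item `Undetermined` — anything else, including any `no_call` and
#'     sites where a second alternate allele reaches the heterozygote
#'     threshold (tri-allelic).
#' }
#'
#' @param t1,t2 [PileupCounts-class] objects for the two tissues, same sites
#'   in the same order.
#' @param params a [CallingParams-class].
#' @return a [PairedCalls-class] object.
#' @export
classifyPairs <- function(t1, t2, params = CallingParams()) {
  if (length(t1) != length(t2) ||
      !identical(t1@chrom, t2@chrom) || !identical(t1@pos, t2@pos) ||
      !identical(t1@ref, t2@ref))
    stop("tissue pileups must cover identical (chrom, pos, ref) sites")
  n <- length(t1)
  ad1 <- alleleDepth(t1)
  ad2 <- alleleDepth(t2)
  refIdx <- match(t1@ref, .BASES)
  idx <- cbind(seq_len(n), refIdx)
  comb <- ad1 + ad2
  nonref <- comb
  nonref[idx] <- -1L
  altIdx <- max.col(nonref, ties.method = "first")
  aidx <- cbind(seq_len(n), altIdx)
  altReads <- comb[aidx]
  alt <- ifelse(altReads > 0, .BASES[altIdx], NA_character_)

  depth1 <- rowSums(ad1); depth2 <- rowSums(ad2)
  var1 <- ad1[aidx]; var2 <- ad2[aidx]
  ref1 <- ad1[idx]; ref2 <- ad2[idx]

  g1 <- .genotypeFromCounts(depth1, var1, t1@baseQual[aidx],
                            t1@baseQual[idx], t1@mapQual, params)
  g2 <- .genotypeFromCounts(depth2, var2, t2@baseQual[aidx],
                            t2@baseQual[idx], t2@mapQual, params)

  # tri-allelic: another non-ref allele reaches the het threshold anywhere
  otherMax1 <- ad1; otherMax1[idx] <- 0L; otherMax1[aidx] <- 0L
  otherMax2 <- ad2; otherMax2[idx] <- 0L; otherMax2[aidx] <- 0L
  tri <- apply(otherMax1, 1, max) / pmax(depth1, 1) >= params@minVarFreqHet |
         apply(otherMax2, 1, max) / pmax(depth2, 1) >= params@minVarFreqHet

  somP <- rep(1, n)
  hasDepth <- (ref1 + var1 + ref2 + var2) > 0
  somP[hasDepth] <- fisherSomaticP(ref1[hasDepth], var1[hasDepth],
                                   ref2[hasDepth], var2[hasDepth])

  gt1 <- g1$genotype; gt2 <- g2$genotype
  status <- rep("Undetermined", n)
  callable <- gt1 != "no_call" & gt2 != "no_call" & !tri
  status[callable & gt1 == "hom_ref" & gt2 == "hom_ref"] <- "Reference"
  somatic <- callable & gt1 != gt2 & somP < params@somaticPThreshold
  if (params@minVarReads > 0L)
    somatic <- somatic & pmax(var1, var2) >= params@minVarReads
  status[somatic] <- "Somatic"
  germ <- callable & gt1 == gt2 & gt1 != "hom_ref" &
    germlineConfident(var1, depth1, params) &
    germlineConfident(var2, depth2, params)
  status[germ] <- "Germline"

  d <- DataFrame(chrom = t1@chrom, pos = t1@pos, ref = t1@ref, alt = alt,
                 gt1 = gt1, gt2 = gt2,
                 vaf1 = g1$vaf, vaf2 = g2$vaf,
                 depth1 = depth1, depth2 = depth2,
                 varReads1 = var1, varReads2 = var2,
                 somaticP = somP, status = status,
                 filters = rep("", n))
  new("PairedCalls", data = d, params = params)
}

#' Percentage of somatic variation
#'
#' `(number of somatic variations / number of total variations) x 100`,
#' where the total counts all sites whose genotype differs from the
#' reference in either tissue.
#'
#' @param nSomatic number of somatic sites.
#' @param nTotalVariant total number of variant sites (somatic + germline).
#' @return percentage in \[0, 100\].
#' @export
somaticPercentage <- function(nSomatic, nTotalVariant) {
  if (nTotalVariant == 0) stop("no variant sites: percentage undefined")
  if (nSomatic < 0 || nSomatic > nTotalVariant)
    stop("need 0 <= nSomatic <= nTotalVariant")
  100 * nSomatic / nTotalVariant
}

#' Compare two somatic call sets
#'
#' Caller-agnostic overlap of call sets keyed by `(chrom, pos, alt)`.
#'
#' @param callsA,callsB [PairedCalls-class] objects or data.frames with
#'   columns `chrom`, `pos`, `alt`.
#' @return list with `intersection`, `aOnly`, `bOnly` (counts) and
#'   `fractionAinB` = |A ∩ B| / |A|.
#' @export
compareCallsets <- function(callsA, callsB) {
  key <- function(x) {
    if (is(x, "PairedCalls")) x <- as.data.frame(x)
    unique(paste(x$chrom, x$pos, x$alt, sep = ":"))
  }
  a <- key(callsA); b <- key(callsB)
  inter <- length(intersect(a, b))
  list(intersection = inter,
       aOnly = length(a) - inter,
       bOnly = length(b) - inter,
       fractionAinB = if (length(a)) inter / length(a) else NA_real_)
}
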