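#' @include PileupCounts-class.R SpectrumTable-class.R
NULL

#' SimulationConfig: parameters of the paired-tissue pileup simulator
#'
#' Defaults emulate the paired-tissue exome study conditions: mean depth
#' 100x, a transition-rich germline spectrum (36 percent `A:T>G:C`, 38
#' percent `G:C>A:T`), a `G:C>T:A`-dominated somatic spectrum (87 percent),
#' somatic heterozygotes biased to tissue 1 (85 percent, inside the observed
#' 70-100 percent range), subclonal somatic VAFs (Beta, mean 0.35),
#' single-orientation artifact sites, and a duplicated decoy region.
#'
#' @slot seed integer; fixed seed implies byte-identical outputs.
#' @slot genomeLength genome size in bp (>= 5000).
#' @slot meanDepth mean sequencing depth (Poisson), default 100.
#' @slot nGermline,nSomatic,nArtifact counts of injected sites.
#' @slot germlineClassWeights,somaticClassWeights named 6-vectors over
#'   [SUBSTITUTION_CLASSES], each summing to 1.
#' @slot germlineHetFraction fraction of germline variants that are
#'   heterozygous (rest homozygous alt), default 2/3.
#' @slot somaticHetTissue1Prob probability the somatic het is in tissue 1.
#' @slot somaticVafMean,somaticVafConc Beta mean / concentration of the
#'   somatic VAF in the variant-carrying tissue.
#' @slot somaticOtherVaf variant-allele rate in the non-carrying tissue
#'   (default 0.005, i.e. at most background).
#' @slot errorRate per-read sequencing error rate (default 1e-3).
#' @slot artifactOrientation `"F1R2"` or `"F2R1"`: the single orientation
#'   carried by all artifact variant reads.
#' @slot duplicatedRegionLength,duplicatedRegionIdentity decoy duplication:
#'   length in bp (0 disables) and copy identity in (0, 1].
#' @slot nGenes number of gene models tiled onto the genome.
#' @slot nGeneSets number of random gene sets besides the built-in
#'   long-gene-biased set.
#'
#' @name SimulationConfig-class
#' @aliases SimulationConfig
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer",
    genomeLength = "integer",
    meanDepth = "numeric",
    nGermline = "integer",
    nSomatic = "integer",
    nArtifact = "integer",
    germlineClassWeights = "numeric",
    somaticClassWeights = "numeric",
    germlineHetFraction = "numeric",
    somaticHetTissue1Prob = "numeric",
    somaticVafMean = "numeric",
    somaticVafConc = "numeric",
    somaticOtherVaf = "numeric",
    errorRate = "numeric",
    artifactOrientation = "character",
    duplicatedRegionLength = "integer",
    duplicatedRegionIdentity = "numeric",
    nGenes = "integer",
    nGeneSets = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msgs <- character()
  if (object@genomeLength < 5000L)
    msgs <- c(msgs, "genomeLength must be >= 5000")
  for (w in c("germlineClassWeights", "somaticClassWeights")) {
    v <- slot(object, w)
    if (!identical(names(v), SUBSTITUTION_CLASSES) ||
        abs(sum(v) - 1) > 1e-9 || any(v < 0))
      msgs <- c(msgs, paste(w, "must be a non-negative 6-vector over the",
                            "substitution classes summing to 1"))
  }
  if (!object@artifactOrientation %in% c("F1R2", "F2R1"))
    msgs <- c(msgs, "artifactOrientation must be F1R2 or F2R1")
  if (object@somaticHetTissue1Prob < 0 || object@somaticHetTissue1Prob > 1)
    msgs <- c(msgs, "somaticHetTissue1Prob must be in [0,1]")
  if (object@duplicatedRegionLength > 0 &&
      (object@duplicatedRegionIdentity <= 0 ||
       object@duplicatedRegionIdentity > 1))
    msgs <- c(msgs, "duplicatedRegionIdentity must be in (0,1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimulationConfig
#'
#' @param seed random seed (mandatory for reproducibility; default 1).
#' @param genomeLength,meanDepth,nGermline,nSomatic,nArtifact see
#'   [SimulationConfig-class].
#' @param germlineClassWeights,somaticClassWeights named or unnamed
#'   6-vectors over [SUBSTITUTION_CLASSES].
#' @param germlineHetFraction,somaticHetTissue1Prob,somaticVafMean see
#'   [SimulationConfig-class].
#' @param somaticVafConc,somaticOtherVaf,errorRate,artifactOrientation see
#'   [SimulationConfig-class].
#' @param duplicatedRegionLength,duplicatedRegionIdentity,nGenes,nGeneSets
#'   see [SimulationConfig-class].
#' @return a validated `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1,
                             genomeLength = 50000,
                             meanDepth = 100,
                             nGermline = 5000,
                             nSomatic = 200,
                             nArtifact = 100,
                             germlineClassWeights = c(0.36, 0.38, 0.065,
                                                      0.065, 0.065, 0.065),
                             somaticClassWeights = c(0.026, 0.026, 0.87,
                                                     0.026, 0.026, 0.026),
                             germlineHetFraction = 2 / 3,
                             somaticHetTissue1Prob = 0.85,
                             somaticVafMean = 0.35,
                             somaticVafConc = 50,
                             somaticOtherVaf = 0.005,
                             errorRate = 1e-3,
                             artifactOrientation = "F1R2",
                             duplicatedRegionLength = 500,
                             duplicatedRegionIdentity = 1.0,
                             nGenes = 20,
                             nGeneSets = 5) {
  gw <- setNames(as.numeric(germlineClassWeights), SUBSTITUTION_CLASSES)
  sw <- setNames(as.numeric(somaticClassWeights), SUBSTITUTION_CLASSES)
  new("SimulationConfig",
      seed = as.integer(seed), genomeLength = as.integer(genomeLength),
      meanDepth = meanDepth, nGermline = as.integer(nGermline),
      nSomatic = as.integer(nSomatic), nArtifact = as.integer(nArtifact),
      germlineClassWeights = gw / sum(gw),
      somaticClassWeights = sw / sum(sw),
      germlineHetFraction = germlineHetFraction,
      somaticHetTissue1Prob = somaticHetTissue1Prob,
      somaticVafMean = somaticVafMean, somaticVafConc = somaticVafConc,
      somaticOtherVaf = somaticOtherVaf, errorRate = errorRate,
      artifactOrientation = artifactOrientation,
      duplicatedRegionLength = as.integer(duplicatedRegionLength),
      duplicatedRegionIdentity = duplicatedRegionIdentity,
      nGenes = as.integer(nGenes), nGeneSets = as.integer(nGeneSets))
}

#' Read a SimulationConfig from YAML
#'
#' Keys mirror [simulationConfig()] arguments; absent keys keep defaults.
#'
#' @param path YAML file.
#' @return a `SimulationConfig`.
#' @export
readSimulationConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulationConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown simulation key(s): ", paste(unknown, collapse = ", "))
  do.call(simulationConfig, vals)
}

#' Simulate a reference genome with decoy duplication, genes and gene sets
#'
#' Bases are i.i.d. uniform except for the configured duplicated decoy
#' segment (a copy of one segment pasted elsewhere at the configured
#' identity). Non-overlapping gene models (alternating strands, 1-3 CDS
#' exons, CDS length divisible by 3) tile part of the genome; gene sets
#' comprise one set biased toward the longest genes (to exercise
#' length-driven over-representation) plus random sets.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `reference` (named `DNAStringSet`, one
#'   chromosome `"chr1"`), `duplicate` (NULL or list `srcStart`, `dstStart`,
#'   `length`, `identity`), `geneModels` (GFF-lite data.frame, see
#'   [readGeneModels()]), `geneSets` (named list).
#' @export
simulateReference <- function(config) {
  set.seed(config@seed)
  L <- config@genomeLength
  bases <- sample(.BASES, L, replace = TRUE)

  dup <- NULL
  dl <- config@duplicatedRegionLength
  if (dl > 0) {
    if (L < 4L * dl) stop("genome too short for the duplicated region")
    srcStart <- sample.int(L %/% 4L, 1L)
    dstStart <- L %/% 2L + sample.int(L %/% 4L, 1L)
    seg <- bases[srcStart:(srcStart + dl - 1L)]
    nMut <- round((1 - config@duplicatedRegionIdentity) * dl)
    if (nMut > 0) {
      at <- sample.int(dl, nMut)
      seg[at] <- vapply(seg[at], function(b)
        sample(setdiff(.BASES, b), 1L), character(1))
    }
    bases[dstStart:(dstStart + dl - 1L)] <- seg
    dup <- list(srcStart = srcStart, dstStart = dstStart, length = dl,
                identity = config@duplicatedRegionIdentity)
  }

  # non-overlapping genes with 1-3 CDS exons each
  models <- NULL
  if (config@nGenes > 0) {
    rows <- list()
    cursor <- 101L
    for (g in seq_len(config@nGenes)) {
      maxSpan <- min(6000L, L - cursor - 100L)
      if (maxSpan < 600L) break
      span <- sample(600:maxSpan, 1L)
      gid <- sprintf("GENE%03d", g)
      strand <- if (g %% 2L == 0L) "-" else "+"
      gStart <- cursor
      gEnd <- cursor + span - 1L
      nEx <- sample(1:3, 1L)
      # carve exons inside the span, total length divisible by 3
      exLen <- sample(60:300, nEx, replace = TRUE)
      exLen <- exLen %/% 3L * 3L
      gaps <- sample(30:200, nEx, replace = TRUE)
      exStart <- gStart + 30L + cumsum(c(0L, (exLen + gaps)[-nEx]))
      exEnd <- exStart + exLen - 1L
      keep <- exEnd <= gEnd - 30L
      if (!any(keep)) { cursor <- gEnd + sample(200:800, 1L); next }
      exStart <- exStart[keep]; exEnd <- exEnd[keep]
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, chrom = "chr1", strand = strand,
        feature = c("gene", rep("CDS", length(exStart))),
        start = c(gStart, exStart), end = c(gEnd, exEnd),
        stringsAsFactors = FALSE)
      cursor <- gEnd + sample(200:800, 1L)
    }
    models <- do.call(rbind, rows)
  }

  sets <- list()
  if (!is.null(models)) {
    spans <- models[models$feature == "gene", , drop = FALSE]
    spans$length <- spans$end - spans$start + 1L
    longIds <- spans$gene_id[order(-spans$length)]
    nLong <- max(3L, ceiling(nrow(spans) * 0.3))
    sets[["AXON_GUIDANCE_LIKE"]] <- head(longIds, nLong)
    if (config@nGeneSets > 0)
      for (i in seq_len(config@nGeneSets))
        sets[[sprintf("RANDOM_SET_%02d", i)]] <-
          sort(sample(spans$gene_id, min(5L, nrow(spans))))
  }

  ref <- DNAStringSet(paste(bases, collapse = ""))
  names(ref) <- "chr1"
  # re-parse through the reader so the geneSpans attribute is attached
  gm <- if (!is.null(models)) {
    tmp <- tempfile(fileext = ".gffl")
    on.exit(unlink(tmp), add = TRUE)
    writeGeneModels(models, tmp)
    readGeneModels(tmp)
  } else NULL
  list(reference = ref, duplicate = dup, geneModels = gm, geneSets = sets)
}

# alt base for a substitution class given the reference base (vectorised);
# the class names the change on the purine (A/G) strand
.altForClass <- function(cls, ref) {
  to <- c("A:T>G:C" = "G", "A:T>T:A" = "T", "A:T>C:G" = "C",
          "G:C>A:T" = "A", "G:C>T:A" = "T", "G:C>C:G" = "C")[cls]
  unname(ifelse(ref %in% c("A", "G"), to, .COMPLEMENT[to]))
}

#' Simulate a tissue pair of pileups with recorded ground truth
#'
#' Per-site depth is Poisson(`meanDepth`); reference-error reads occur at
#' `errorRate` and are spread over the non-reference bases; read strand and
#' orientation are Binomial(0.5) except at artifact sites, where every
#' variant-supporting read carries the configured single orientation (and
#' error reads never land on the artifact allele, keeping the signature
#' pure). Germline variants are shared by both tissues (het VAF ~ Beta
#' centred on 0.5, hom ~ 0.99); somatic variants carry the configured Beta
#' VAF in the het tissue and at most background in the other. Injected
#' variants avoid the duplicated decoy region and the first/last genome
#' positions. Fixed config + seed gives byte-identical output.
#'
#' @param config a [SimulationConfig-class].
#' @param refSim output of [simulateReference()] for the same config.
#' @return list with `t1`, `t2` ([PileupCounts-class]) and `truth`
#'   (data.frame: `chrom`, `pos`, `ref`, `alt`, `origin`, `class`,
#'   `hetTissue`, `vaf1`, `vaf2`).
#' @export
simulatePair <- function(config, refSim) {
  set.seed(config@seed + 1L)
  s <- .refToChar(refSim$reference)
  L <- nchar(s)
  refBase <- strsplit(s, "", fixed = TRUE)[[1]]

  # candidate positions: outside the decoy, away from the edges
  avail <- rep(TRUE, L)
  avail[c(1L, L)] <- FALSE
  if (!is.null(refSim$duplicate)) {
    d <- refSim$duplicate
    avail[d$srcStart:(d$srcStart + d$length - 1L)] <- FALSE
    avail[d$dstStart:(d$dstStart + d$length - 1L)] <- FALSE
  }
  poolAT <- which(avail & refBase %in% c("A", "T"))
  poolGC <- which(avail & refBase %in% c("G", "C"))

  takeFrom <- function(pool, k) {
    if (k > length(pool)) stop("not enough free sites for requested variants")
    pool[sample.int(length(pool), k)]
  }

  drawClassSites <- function(n, weights) {
    if (n == 0L)
      return(data.frame(pos = integer(), class = character(),
                        stringsAsFactors = FALSE))
    cls <- sample(SUBSTITUTION_CLASSES, n, replace = TRUE, prob = weights)
    nAT <- sum(cls %in% c("A:T>G:C", "A:T>T:A", "A:T>C:G"))
    posAT <- takeFrom(poolAT, nAT)
    posGC <- takeFrom(poolGC, n - nAT)
    poolAT <<- setdiff(poolAT, posAT)
    poolGC <<- setdiff(poolGC, posGC)
    isAT <- cls %in% c("A:T>G:C", "A:T>T:A", "A:T>C:G")
    pos <- integer(n)
    pos[isAT] <- posAT
    pos[!isAT] <- posGC
    data.frame(pos = pos, class = cls, stringsAsFactors = FALSE)
  }

  germ <- drawClassSites(config@nGermline, config@germlineClassWeights)
  soma <- drawClassSites(config@nSomatic, config@somaticClassWeights)
  arti <- if (config@nArtifact > 0L) {
    pos <- takeFrom(poolGC, config@nArtifact)
    poolGC <- setdiff(poolGC, pos)
    data.frame(pos = pos, class = "G:C>T:A", stringsAsFactors = FALSE)
  } else data.frame(pos = integer(), class = character(),
                    stringsAsFactors = FALSE)

  truth <- rbind(
    if (nrow(germ)) cbind(germ, origin = "germline"),
    if (nrow(soma)) cbind(soma, origin = "somatic"),
    if (nrow(arti)) cbind(arti, origin = "artifact"))
  if (is.null(truth))
    truth <- data.frame(pos = integer(), class = character(),
                        origin = character(), stringsAsFactors = FALSE)
  nV <- nrow(truth)
  truth$ref <- refBase[truth$pos]
  truth$alt <- if (nV) .altForClass(truth$class, truth$ref) else character()

  # zygosity / VAF assignment
  vaf1 <- numeric(nV); vaf2 <- numeric(nV)
  hetTissue <- character(nV)
  isG <- truth$origin == "germline"
  if (any(isG)) {
    nG <- sum(isG)
    het <- runif(nG) < config@germlineHetFraction
    v1 <- ifelse(het, rbeta(nG, 50, 50), 0.99)
    v2 <- ifelse(het, rbeta(nG, 50, 50), 0.99)
    vaf1[isG] <- v1; vaf2[isG] <- v2
    hetTissue[isG] <- "both"
  }
  isS <- truth$origin %in% c("somatic", "artifact")
  if (any(isS)) {
    nS <- sum(isS)
    a <- config@somaticVafMean * config@somaticVafConc
    b <- (1 - config@somaticVafMean) * config@somaticVafConc
    v <- rbeta(nS, a, b)
    inT1 <- runif(nS) < config@somaticHetTissue1Prob
    vaf1[isS] <- ifelse(inT1, v, config@somaticOtherVaf)
    vaf2[isS] <- ifelse(inT1, config@somaticOtherVaf, v)
    hetTissue[isS] <- ifelse(inT1, "t1", "t2")
  }
  truth$hetTissue <- hetTissue
  truth$vaf1 <- vaf1
  truth$vaf2 <- vaf2
  truth$chrom <- "chr1"
  truth <- truth[order(truth$pos),
                 c("chrom", "pos", "ref", "alt", "origin", "class",
                   "hetTissue", "vaf1", "vaf2")]
  rownames(truth) <- NULL

  altIdx <- rep(0L, L)
  altIdx[truth$pos] <- match(truth$alt, .BASES)
  isArt <- rep(FALSE, L)
  isArt[truth$pos[truth$origin == "artifact"]] <- TRUE

  mk <- function(vafCol) {
    vaf <- numeric(L)
    vaf[truth$pos] <- vafCol
    depth <- rpois(L, config@meanDepth)
    varReads <- rbinom(L, depth, vaf)
    refReads <- depth - varReads
    errReads <- rbinom(L, refReads, config@errorRate)
    refReads <- refReads - errReads

    refIdx <- match(refBase, .BASES)
    alleleCounts <- matrix(0L, L, 4L)
    alleleCounts[cbind(seq_len(L), refIdx)] <- refReads
    iv <- altIdx > 0L
    alleleCounts[cbind(which(iv), altIdx[iv])] <-
      alleleCounts[cbind(which(iv), altIdx[iv])] + varReads[iv]

    # spread errors across the non-reference bases; at artifact sites the
    # artifact allele never receives error reads (pure single orientation)
    errTargets <- matrix(0L, L, 4L)
    e1 <- rbinom(L, errReads, 1 / 3)
    e2 <- rbinom(L, errReads - e1, 1 / 2)
    e3 <- errReads - e1 - e2
    othersMap <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L),
                       c(1L, 2L, 4L), c(1L, 2L, 3L))
    others <- othersMap[refIdx, , drop = FALSE]
    eMat <- cbind(e1, e2, e3)
    if (any(isArt)) {
      w <- which(isArt)
      # move errors destined for the artifact allele onto another base
      for (j in 1:3) {
        hitsAlt <- others[w, j] == altIdx[w]
        if (any(hitsAlt)) {
          k <- w[hitsAlt]
          jj <- if (j == 1L) 2L else 1L
          eMat[k, jj] <- eMat[k, jj] + eMat[k, j]
          eMat[k, j] <- 0L
        }
      }
    }
    for (j in 1:3)
      errTargets[cbind(seq_len(L), others[, j])] <-
        errTargets[cbind(seq_len(L), others[, j])] + eMat[, j]
    alleleCounts <- alleleCounts + errTargets

    # split each allele count into the 16 strand/orientation cells
    counts <- matrix(0L, L, 16L, dimnames = list(NULL, .COUNT_COLS))
    artAltCol <- ifelse(isArt, altIdx, 0L)
    for (b in 1:4) {
      cnt <- alleleCounts[, b]
      fwd <- rbinom(L, cnt, 0.5)
      rev <- cnt - fwd
      fixed <- artAltCol == b
      f1f <- integer(L); f1r <- integer(L)
      free <- !fixed
      f1f[free] <- rbinom(sum(free), fwd[free], 0.5)
      f1r[free] <- rbinom(sum(free), rev[free], 0.5)
      if (any(fixed)) {
        if (config@artifactOrientation == "F1R2") {
          f1f[fixed] <- fwd[fixed]; f1r[fixed] <- rev[fixed]
        } # else leave 0: everything F2R1
      }
      off <- (b - 1L) * 4L
      counts[, off + 1L] <- f1f
      counts[, off + 2L] <- fwd - f1f
      counts[, off + 3L] <- f1r
      counts[, off + 4L] <- rev - f1r
    }

    ad <- .alleleDepthFromCounts(counts)
    bq <- matrix(NA_real_, L, 4L)
    hasReads <- ad > 0
    bq[hasReads] <- round(pmin(40, pmax(25, 35 + rnorm(sum(hasReads), 0, 2))),
                          1)
    mq <- round(pmin(60, pmax(45, 55 + rnorm(L, 0, 2))), 1)
    PileupCounts(rep("chr1", L), seq_len(L), refBase, counts,
                 baseQual = bq, mapQual = mq)
  }

  t1 <- mk(truth$vaf1)
  t2 <- mk(truth$vaf2)
  list(t1 = t1, t2 = t2, truth = truth)
}

#' Simulate very-high-depth amplicon validation data for somatic truth sites
#'
#' For each somatic truth record, draws validation-platform variant reads at
#' `depth` (default 5000x) from a slightly shrunken version of the true VAF
#' (`shrink`, default 0.7, mirroring the lower allele frequencies observed
#' on very deep re-sequencing) and pairs them with the discovery VAFs of the
#' corresponding calls.
#'
#' @param truth truth data.frame from [simulatePair()].
#' @param calls a [PairedCalls-class] from the discovery pipeline (used for
#'   the discovery VAFs; truth VAFs are used for sites without a call).
#' @param depth validation read depth per tissue (default 5000).
#' @param shrink multiplicative VAF shrinkage on the validation platform.
#' @param seed seed for the validation draw.
#' @return a validation table suitable for [validateSites()].
#' @export
simulateValidation <- function(truth, calls = NULL, depth = 5000,
                               shrink = 0.7, seed = 1) {
  set.seed(seed)
  t <- truth[truth$origin == "somatic", , drop = FALSE]
  n <- nrow(t)
  disc1 <- t$vaf1; disc2 <- t$vaf2
  if (!is.null(calls)) {
    d <- as.data.frame(calls)
    m <- match(paste(t$chrom, t$pos), paste(d$chrom, d$pos))
    hit <- !is.na(m)
    disc1[hit] <- d$vaf1[m[hit]]
    disc2[hit] <- d$vaf2[m[hit]]
  }
  vr1 <- rbinom(n, depth, pmin(1, t$vaf1 * shrink))
  vr2 <- rbinom(n, depth, pmin(1, t$vaf2 * shrink))
  data.frame(site = paste0(t$chrom, ":", t$pos),
             t1_disc_vaf = disc1, t2_disc_vaf = disc2,
             t1_val_vaf = vr1 / depth, t2_val_vaf = vr2 / depth,
             t1_val_varreads = vr1, t2_val_varreads = vr2,
             stringsAsFactors = FALSE)
}
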