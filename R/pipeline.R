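#' @include simulate.R calling.R filters.R spectrum.R annotation.R validation.R
NULL

.writeTsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full paired-tissue somatic pipeline on simulated data
#'
#' Orchestrates simulate -> call -> filter -> spectrum/context ->
#' annotate/enrich -> validate into one reproducible run. All stage outputs
#' are TSV/FASTA/VCF text files under `outDir`, plus a YAML manifest with
#' the config snapshot, package version, seed, per-stage site counts and
#' md5 checksums of every output. Re-running with the same config yields
#' byte-identical files.
#'
#' @param config a [SimulationConfig-class], or path to a YAML config.
#' @param outDir output directory (created if needed).
#' @param params a [CallingParams-class] (study defaults by default).
#' @param maskWindow,maskIdentity parameters for [buildIdentityMask()] on
#'   the simulated reference.
#' @param longGeneThreshold gene-length threshold (bp) for [longGeneTest()];
#'   default 2000, matched to the simulated genome scale.
#' @return the manifest, invisibly (also written to `manifest.yaml`).
#' @export
runPipeline <- function(config, outDir, params = CallingParams(),
                        maskWindow = 100L, maskIdentity = 0.87,
                        longGeneThreshold = 2000) {
  if (is.character(config)) config <- readSimulationConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outDir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  manifest <- list(
    tool = "oxisoma",
    version = as.character(packageVersion("oxisoma")),
    seed = config@seed,
    config = .configSnapshot(config),
    params = .paramsSnapshot(params),
    stages = list()
  )

  # -- simulate ---------------------------------------------------------
  refSim <- stage("simulate", simulateReference(config))
  pair <- stage("simulate", simulatePair(config, refSim))
  writeReference(refSim$reference, p("ref.fa"))
  writePileupTable(pair$t1, p("t1.pileup.tsv"))
  writePileupTable(pair$t2, p("t2.pileup.tsv"))
  .writeTsv(pair$truth, p("truth.tsv"))
  if (!is.null(refSim$geneModels))
    writeGeneModels(refSim$geneModels, p("genes.gffl"))
  if (length(refSim$geneSets))
    writeGmt(refSim$geneSets, p("sets.gmt"))
  manifest$stages$simulate <- list(
    sites = length(pair$t1),
    truthRecords = nrow(pair$truth))

  # -- call -------------------------------------------------------------
  calls <- stage("call", classifyPairs(pair$t1, pair$t2, params))
  statusTab <- table(factor(callStatus(calls), levels = .STATUS_LEVELS))
  manifest$stages$call <- as.list(setNames(as.integer(statusTab),
                                           names(statusTab)))

  # -- filter -----------------------------------------------------------
  mask <- stage("filter",
                buildIdentityMask(refSim$reference, maskWindow, maskIdentity))
  calls <- stage("filter", applyArtifactFilters(calls, pair$t1, pair$t2,
                                                mask = mask))
  writeRegionMask(mask, p("mask.bed"))
  variant <- calls[callStatus(calls) %in% c("Somatic", "Germline")]
  writeCallsVcf(variant, p("calls.vcf"), referenceName = "ref.fa")
  som <- callStatus(calls) == "Somatic"
  flagged <- filterFlags(calls) != ""
  manifest$stages$filter <- list(
    somaticIn = sum(som),
    somaticFiltered = sum(som & flagged),
    somaticKept = sum(som & !flagged))

  somCalls <- keptCalls(calls, "Somatic")
  germCalls <- keptCalls(calls, "Germline")
  manifest$stages$somaticPercentage <-
    if (length(somCalls) + length(germCalls) > 0)
      somaticPercentage(length(somCalls),
                        length(somCalls) + length(germCalls)) else NA

  # -- spectrum / context ----------------------------------------------
  specS <- stage("spectrum", mutationSpectrum(calls, "Somatic"))
  specG <- stage("spectrum", mutationSpectrum(calls, "Germline"))
  .writeTsv(data.frame(class = SUBSTITUTION_CLASSES,
                       somatic = classCounts(specS),
                       somatic_prop = classProportions(specS),
                       germline = classCounts(specG),
                       germline_prop = classProportions(specG)),
            p("spectrum.tsv"))
  enr <- if (specS@total > 0 && specG@total > 0)
    spectrumEnrichment(specS, specG) else
    setNames(rep(NA_real_, 6), SUBSTITUTION_CLASSES)
  .writeTsv(data.frame(class = SUBSTITUTION_CLASSES, enrichment = enr),
            p("enrichment.tsv"))
  zyg <- stage("spectrum", zygosityByTissue(calls))
  ctx3 <- stage("spectrum", threePrimeContext(calls, refSim$reference))
  ccg <- stage("spectrum", ccgMotifFraction(calls, refSim$reference))
  .writeTsv(data.frame(metric = c("hetT1", "hetT2", "indeterminate",
                                  "fractionHetT1",
                                  paste0("threePrime_", .BASES),
                                  "ccgFraction"),
                       value = c(zyg$hetT1, zyg$hetT2, zyg$indeterminate,
                                 zyg$fractionHetT1, ctx3, ccg$fraction)),
            p("context.tsv"))
  manifest$stages$spectrum <- list(somaticN = specS@total,
                                   germlineN = specG@total)

  # -- annotate / enrich ------------------------------------------------
  if (!is.null(refSim$geneModels)) {
    eff <- stage("annotate",
                 annotateEffects(somCalls, refSim$geneModels,
                                 refSim$reference))
    .writeTsv(eff, p("annotated.tsv"))
    sns <- synNonsynSummary(eff)
    spans <- attr(refSim$geneModels, "geneSpans")
    fg <- unique(eff$gene_id[!is.na(eff$gene_id)])
    lgt <- if (length(fg)) longGeneTest(fg, spans, longGeneThreshold)
           else NULL
    ora <- if (length(fg) && length(refSim$geneSets))
      overrepresentation(fg, refSim$geneSets, spans$gene_id) else NULL
    if (!is.null(ora)) .writeTsv(ora, p("ora.tsv"))
    manifest$stages$annotate <- list(
      nCoding = sns$nCoding,
      fractionNonsynonymous = sns$fractionNonsynonymous,
      longGeneP = if (!is.null(lgt)) lgt$pValue else NA)
  }

  # -- validate ---------------------------------------------------------
  val <- stage("validate",
               simulateValidation(pair$truth, calls,
                                  seed = config@seed + 2L))
  if (nrow(val)) {
    val <- validateSites(val)
    .writeTsv(val, p("validated.tsv"))
    vs <- validationSummary(val)
    manifest$stages$validate <- list(nValidated = vs$nValidated,
                                     nFailed = vs$nFailed,
                                     rate = vs$rate)
  }

  # -- manifest ---------------------------------------------------------
  files <- sort(setdiff(list.files(outDir), "manifest.yaml"))
  manifest$checksums <- as.list(setNames(
    unname(tools::md5sum(file.path(outDir, files))), files))
  yaml::write_yaml(manifest, p("manifest.yaml"))
  invisible(manifest)
}

.configSnapshot <- function(config) {
  out <- lapply(slotNames(config), function(s) {
    v <- slot(config, s)
    if (!is.null(names(v))) as.list(v) else v
  })
  setNames(out, slotNames(config))
}

.paramsSnapshot <- function(params) {
  setNames(lapply(slotNames(params), function(s) slot(params, s)),
           slotNames(params))
}
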