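#' @include AllGenerics.R
NULL

#' CallingParams: thresholds for somatic SNV calling
#'
#' Holds the seven calling thresholds plus two auxiliary parameters. Defaults
#' are the study values for paired-tissue exome calling: minimum coverage 8
#' reads, heterozygote VAF >= 0.10, homozygote VAF >= 0.90, strand bias
#' removal above 90 percent, base quality >= 20, mapping quality >= 40, and
#' somatic p-value < 0.05.
#'
#' @slot minCoverage integer, minimum read depth to call a site (default 8).
#' @slot minVarFreqHet numeric, minimum VAF for a heterozygote (default 0.10;
#'   the boundary is closed: VAF exactly 0.10 is het).
#' @slot minHomFreq numeric, minimum VAF for a homozygote (default 0.90,
#'   closed boundary).
#' @slot maxStrandBias numeric, variant calls with a larger fraction of
#'   variant reads on one strand are removed (default 0.90, strict).
#' @slot minBaseQuality numeric, minimum mean phred base quality of the
#'   evaluated allele (default 20).
#' @slot minMappingQuality numeric, minimum mean phred mapping quality
#'   (default 40).
#' @slot somaticPThreshold numeric, somatic p-value cut-off (default 0.05).
#' @slot minVarReads integer, optional minimum variant-read support for a
#'   somatic call (default 0 = off; reported descriptively in the study).
#' @slot germlineErrorRate numeric, sequencing-error rate of the hom-ref
#'   error model used by [germlineConfident()] (default 0.01).
#'
#' @name CallingParams-class
#' @aliases CallingParams
#' @export
setClass("CallingParams",
  representation(
    minCoverage = "integer",
    minVarFreqHet = "numeric",
    minHomFreq = "numeric",
    maxStrandBias = "numeric",
    minBaseQuality = "numeric",
    minMappingQuality = "numeric",
    somaticPThreshold = "numeric",
    minVarReads = "integer",
    germlineErrorRate = "numeric"
  ),
  prototype(
    minCoverage = 8L,
    minVarFreqHet = 0.10,
    minHomFreq = 0.90,
    maxStrandBias = 0.90,
    minBaseQuality = 20,
    minMappingQuality = 40,
    somaticPThreshold = 0.05,
    minVarReads = 0L,
    germlineErrorRate = 0.01
  )
)

setValidity("CallingParams", function(object) {
  msgs <- character()
  if (!(object@minVarFreqHet > 0 && object@minVarFreqHet < object@minHomFreq &&
        object@minHomFreq <= 1))
    msgs <- c(msgs, "need 0 < minVarFreqHet < minHomFreq <= 1")
  if (object@minCoverage < 0L || object@minBaseQuality < 0 ||
      object@minMappingQuality < 0 || object@minVarReads < 0L)
    msgs <- c(msgs, "thresholds must be non-negative")
  if (object@somaticPThreshold <= 0 || object@somaticPThreshold > 1)
    msgs <- c(msgs, "somaticPThreshold must be in (0,1]")
  if (object@maxStrandBias <= 0 || object@maxStrandBias > 1)
    msgs <- c(msgs, "maxStrandBias must be in (0,1]")
  if (length(msgs)) msgs else TRUE
})

#' Construct CallingParams
#'
#' @param minCoverage,minVarFreqHet,minHomFreq,maxStrandBias,minBaseQuality
#'   see [CallingParams-class].
#' @param minMappingQuality,somaticPThreshold,minVarReads,germlineErrorRate
#'   see [CallingParams-class].
#' @return a validated `CallingParams` object.
#' @examples
#' CallingParams()                      # study defaults
#' CallingParams(minCoverage = 10)
#' @export
CallingParams <- function(minCoverage = 8, minVarFreqHet = 0.10,
                          minHomFreq = 0.90, maxStrandBias = 0.90,
                          minBaseQuality = 20, minMappingQuality = 40,
                          somaticPThreshold = 0.05, minVarReads = 0,
                          germlineErrorRate = 0.01) {
  new("CallingParams",
      minCoverage = as.integer(minCoverage),
      minVarFreqHet = minVarFreqHet,
      minHomFreq = minHomFreq,
      maxStrandBias = maxStrandBias,
      minBaseQuality = minBaseQuality,
      minMappingQuality = minMappingQuality,
      somaticPThreshold = somaticPThreshold,
      minVarReads = as.integer(minVarReads),
      germlineErrorRate = germlineErrorRate)
}

#' Read CallingParams from a YAML file
#'
#' The YAML keys mirror the constructor arguments field-for-field; absent keys
#' keep their defaults.
#'
#' @param path YAML file.
#' @return a `CallingParams` object.
#' @export
readCallingParams <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(CallingParams))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown calling parameter(s): ", paste(unknown, collapse = ", "))
  do.call(CallingParams, vals)
}

#' @rdname CallingParams-class
#' @param object a `CallingParams` object.
#' @export
setMethod("show", "CallingParams", function(object) {
  cat("CallingParams:\n")
  for (s in slotNames(object))
    cat(sprintf("  %-18s %s\n", s, format(slot(object, s))))
  invisible(NULL)
})
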