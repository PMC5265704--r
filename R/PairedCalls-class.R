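#' @include AllGenerics.R CallingParams-class.R
NULL

#' PairedCalls: joint genotype and somatic status per site
#'
#' One row per site shared by the two tissues: the per-tissue genotype, VAF,
#' depth and variant-read support, the best-supported alternate allele, the
#' one-sided Fisher somatic p-value, the classification
#' (Reference / Germline / Somatic / Undetermined), the substitution class,
#' and any artifact-filter flags.
#'
#' @slot data a `DataFrame` with columns `chrom`, `pos`, `ref`, `alt`,
#'   `gt1`, `gt2`, `vaf1`, `vaf2`, `depth1`, `depth2`, `varReads1`,
#'   `varReads2`, `somaticP`, `status`, `filters` (semicolon-joined flag
#'   names, `""` = unfiltered).
#' @slot params the [CallingParams-class] used to produce the calls.
#'
#' @param x a `PairedCalls` object.
#' @name PairedCalls-class
#' @aliases PairedCalls
#' @export
setClass("PairedCalls",
  representation(data = "DataFrame", params = "CallingParams")
)

.PAIREDCALL_COLS <- c("chrom", "pos", "ref", "alt", "gt1", "gt2",
                      "vaf1", "vaf2", "depth1", "depth2",
                      "varReads1", "varReads2", "somaticP", "status",
                      "filters")

setValidity("PairedCalls", function(object) {
  d <- object@data
  msgs <- character()
  if (!all(.PAIREDCALL_COLS %in% colnames(d)))
    msgs <- c(msgs, paste("missing column(s):",
      paste(setdiff(.PAIREDCALL_COLS, colnames(d)), collapse = ", ")))
  else {
    if (any(!d$status %in% .STATUS_LEVELS))
      msgs <- c(msgs, "invalid status value")
    som <- d$status == "Somatic"
    if (any(som & !(d$gt1 != d$gt2)))
      msgs <- c(msgs, "Somatic requires differing genotypes")
    if (any(som & !(d$somaticP < object@params@somaticPThreshold)))
      msgs <- c(msgs, "Somatic requires somaticP below threshold")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname PairedCalls-class
#' @export
setMethod("length", "PairedCalls", function(x) nrow(x@data))

#' @rdname PairedCalls-class
#' @export
setMethod("callStatus", "PairedCalls", function(x) x@data$status)

#' @rdname PairedCalls-class
#' @export
setMethod("somaticP", "PairedCalls", function(x) x@data$somaticP)

#' @rdname PairedCalls-class
#' @export
setMethod("filterFlags", "PairedCalls", function(x) x@data$filters)

#' @rdname PairedCalls-class
#' @export
setMethod("callingParams", "PairedCalls", function(x) x@params)

#' @rdname PairedCalls-class
#' @param i index vector for subsetting.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PairedCalls", function(x, i, j, ..., drop = FALSE) {
  new("PairedCalls", data = x@data[i, , drop = FALSE], params = x@params)
})

#' @rdname PairedCalls-class
#' @param row.names,optional passed on for the data.frame method contract.
#' @export
setMethod("as.data.frame", "PairedCalls",
  function(x, row.names = NULL, optional = FALSE, ...) {
    as.data.frame(x@data, row.names = row.names, optional = optional, ...)
  })

#' @rdname PairedCalls-class
#' @param object a `PairedCalls` object.
#' @export
setMethod("show", "PairedCalls", function(object) {
  n <- length(object)
  cat("PairedCalls with", n, "sites\n")
  if (n > 0) {
    tab <- table(factor(object@data$status, levels = .STATUS_LEVELS))
    cat("  status:", paste(names(tab), tab, sep = "=", collapse = "  "), "\n")
    nf <- sum(object@data$filters != "")
    cat("  filtered:", nf, "site(s) carry artifact flags\n")
  }
  invisible(NULL)
})

#' Subset calls that survived all artifact filters
#'
#' @param x a `PairedCalls` object.
#' @param status optional status to retain (e.g. `"Somatic"`).
#' @return a `PairedCalls` with flagged (and, if requested, other-status)
#'   sites removed.
#' @export
keptCalls <- function(x, status = NULL) {
  keep <- x@data$filters == ""
  if (!is.null(status)) keep <- keep & x@data$status %in% status
  x[keep]
}
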