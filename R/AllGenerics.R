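#' @include oxisoma-package.R
NULL

#' @rdname PileupCounts-class
#' @export
setGeneric("siteChrom", function(x) standardGeneric("siteChrom"))

#' @rdname PileupCounts-class
#' @export
setGeneric("sitePos", function(x) standardGeneric("sitePos"))

#' @rdname PileupCounts-class
#' @export
setGeneric("siteRef", function(x) standardGeneric("siteRef"))

#' @rdname PileupCounts-class
#' @export
setGeneric("siteDepth", function(x) standardGeneric("siteDepth"))

#' @rdname PileupCounts-class
#' @export
setGeneric("alleleDepth", function(x) standardGeneric("alleleDepth"))

#' @rdname PairedCalls-class
#' @export
setGeneric("callStatus", function(x) standardGeneric("callStatus"))

#' @rdname PairedCalls-class
#' @export
setGeneric("somaticP", function(x) standardGeneric("somaticP"))

#' @rdname PairedCalls-class
#' @export
setGeneric("filterFlags", function(x) standardGeneric("filterFlags"))

#' @rdname PairedCalls-class
#' @export
setGeneric("callingParams", function(x) standardGeneric("callingParams"))

#' @rdname SpectrumTable-class
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @rdname SpectrumTable-class
#' @export
setGeneric("classProportions", function(x) standardGeneric("classProportions"))
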