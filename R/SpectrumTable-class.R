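#' @include AllGenerics.R
NULL

#' The six strand-symmetric substitution classes
#'
#' Every biallelic SNV maps to exactly one of six classes after collapsing
#' complementary changes (e.g. G>T and C>A are the same event seen from the
#' two strands, pooled as `G:C>T:A`).
#'
#' @format character vector of length 6.
#' @export
SUBSTITUTION_CLASSES <- c("A:T>G:C", "G:C>A:T", "G:C>T:A",
                          "A:T>T:A", "A:T>C:G", "G:C>C:G")

#' SpectrumTable: six-class substitution counts for one call subset
#'
#' @slot label character, subset label (e.g. `"somatic"` or `"germline"`).
#' @slot counts named numeric of length 6 (one per substitution class).
#' @slot proportions named numeric of length 6; `NaN` when the subset is
#'   empty (flagged by `total == 0`).
#' @slot total numeric, subset size.
#'
#' @param x a `SpectrumTable`.
#' @name SpectrumTable-class
#' @aliases SpectrumTable
#' @export
setClass("SpectrumTable",
  representation(label = "character", counts = "numeric",
                 proportions = "numeric", total = "numeric")
)

setValidity("SpectrumTable", function(object) {
  msgs <- character()
  if (!identical(names(object@counts), SUBSTITUTION_CLASSES))
    msgs <- c(msgs, "counts must be named by the six substitution classes")
  if (any(object@counts < 0)) msgs <- c(msgs, "counts must be non-negative")
  if (object@total > 0 &&
      abs(sum(object@proportions) - 1) > 1e-9)
    msgs <- c(msgs, "proportions must sum to 1 when total > 0")
  if (length(msgs)) msgs else TRUE
})

#' @rdname SpectrumTable-class
#' @export
setMethod("classCounts", "SpectrumTable", function(x) x@counts)

#' @rdname SpectrumTable-class
#' @export
setMethod("classProportions", "SpectrumTable", function(x) x@proportions)

#' @rdname SpectrumTable-class
#' @param object a `SpectrumTable`.
#' @export
setMethod("show", "SpectrumTable", function(object) {
  cat("SpectrumTable (", object@label, "), n = ", object@total, "\n", sep = "")
  m <- rbind(count = object@counts,
             proportion = round(object@proportions, 3))
  print(m)
  invisible(NULL)
})
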