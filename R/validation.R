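#' @include PairedCalls-class.R
NULL

#' Apply the amplicon re-sequencing validation rule
#'
#' A discovery call is validated when, on the validation platform, (i) the
#' variant allele is supported by at least `minReads` reads in the
#' variant-carrying tissue (the tissue with the higher validation VAF;
#' configurably both tissues), (ii) the variant allele frequencies of the
#' two tissues differ at least `minFold`-fold (larger / smaller; a zero
#' denominator passes when the other tissue's VAF is positive; both zero
#' fails), and (iii) the direction is consistent — the same tissue carries
#' the higher VAF on both platforms. Records with missing tissue data are
#' marked unevaluable.
#'
#' @param table data.frame with columns `site`, `t1_disc_vaf`,
#'   `t2_disc_vaf`, `t1_val_vaf`, `t2_val_vaf`, `t1_val_varreads`,
#'   `t2_val_varreads`.
#' @param minReads minimum validation variant-read support (default 100).
#' @param minFold minimum VAF fold difference (default 2).
#' @param bothTissues require `minReads` support in both tissues rather than
#'   only the variant-carrying one (default FALSE).
#' @return the input with added logical columns `evaluable`,
#'   `readsOk`, `foldOk`, `directionConsistent`, `validated`.
#' @export
validateSites <- function(table, minReads = 100, minFold = 2,
                          bothTissues = FALSE) {
  need <- c("site", "t1_disc_vaf", "t2_disc_vaf", "t1_val_vaf",
            "t2_val_vaf", "t1_val_varreads", "t2_val_varreads")
  if (!all(need %in% colnames(table)))
    stop("validation table needs columns: ", paste(need, collapse = ", "))
  num <- table[need[-1]]
  evaluable <- stats::complete.cases(num)
  vafs <- c("t1_disc_vaf", "t2_disc_vaf", "t1_val_vaf", "t2_val_vaf")
  if (any(evaluable & (Reduce(`|`, lapply(table[vafs], function(v)
        !is.na(v) & (v < 0 | v > 1))))))
    stop("VAFs must lie in [0, 1]")

  hi <- ifelse(table$t1_val_vaf >= table$t2_val_vaf, 1L, 2L)
  carrierReads <- ifelse(hi == 1L, table$t1_val_varreads,
                         table$t2_val_varreads)
  readsOk <- if (bothTissues)
    table$t1_val_varreads >= minReads & table$t2_val_varreads >= minReads
  else carrierReads >= minReads

  vHi <- pmax(table$t1_val_vaf, table$t2_val_vaf)
  vLo <- pmin(table$t1_val_vaf, table$t2_val_vaf)
  foldOk <- ifelse(vHi == 0, FALSE,
            ifelse(vLo == 0, TRUE, vHi / vLo >= minFold))

  # same tissue higher on both platforms; a discovery tie imposes no
  # direction. Symmetric under a consistent tissue-label swap.
  dDisc <- table$t1_disc_vaf - table$t2_disc_vaf
  dVal <- table$t1_val_vaf - table$t2_val_vaf
  directionConsistent <- dDisc * dVal > 0 | dDisc == 0

  table$evaluable <- evaluable
  table$readsOk <- evaluable & readsOk
  table$foldOk <- evaluable & foldOk
  table$directionConsistent <- evaluable & directionConsistent
  table$validated <- evaluable & readsOk & foldOk & directionConsistent
  table
}

#' Summarise validation outcomes
#'
#' @param records data.frame from [validateSites()].
#' @return list with `nValidated`, `nFailed`, `nUnevaluable`, and `rate`
#'   (validated / evaluable).
#' @export
validationSummary <- function(records) {
  if (!all(c("evaluable", "validated") %in% colnames(records)))
    stop("run validateSites() first")
  nEval <- sum(records$evaluable)
  if (nEval == 0) stop("no evaluable validation records")
  nVal <- sum(records$validated)
  list(nValidated = nVal, nFailed = nEval - nVal,
       nUnevaluable = nrow(records) - nEval,
       rate = nVal / nEval)
}
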