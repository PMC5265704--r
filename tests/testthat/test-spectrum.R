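# build a PairedCalls directly from (ref, alt, vaf1, vaf2) triples, already
# classified Somatic/Germline, to exercise the spectrum ops in isolation
makeCalls <- function(ref, alt, status = "Somatic", vaf1 = 0.4, vaf2 = 0.0,
                      pos = NULL, chrom = "chr1") {
  n <- length(ref)
  if (is.null(pos)) pos <- seq(10, by = 10, length.out = n)
  params <- CallingParams()
  d <- S4Vectors::DataFrame(
    chrom = rep(chrom, n), pos = as.integer(pos), ref = ref, alt = alt,
    gt1 = rep("het", n), gt2 = rep("hom_ref", n),
    vaf1 = rep_len(vaf1, n), vaf2 = rep_len(vaf2, n),
    depth1 = rep(100L, n), depth2 = rep(100L, n),
    varReads1 = as.integer(rep_len(vaf1, n) * 100),
    varReads2 = as.integer(rep_len(vaf2, n) * 100),
    somaticP = rep(1e-6, n), status = rep_len(status, n),
    filters = rep("", n))
  new("PairedCalls", data = d, params = params)
}

test_that("collapseClass maps all twelve SNVs to six strand-symmetric classes", {
  expect_equal(collapseClass("G", "T"), "G:C>T:A")
  expect_equal(collapseClass("C", "A"), "G:C>T:A")
  expect_equal(collapseClass("A", "G"), "A:T>G:C")
  # complement invariance over every (ref, alt) pair
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in c("A", "C", "G", "T"))
    for (a in setdiff(c("A", "C", "G", "T"), r))
      expect_equal(collapseClass(r, a), collapseClass(comp[[r]], comp[[a]]))
  expect_error(collapseClass("A", "A"), "differ")
  expect_error(collapseClass("A", "N"), "bases")
})

test_that("spectrum counts and proportions reflect the call mix", {
  # 87 G:C>T:A + 13 others: the transversion-dominated somatic profile
  ref <- c(rep("G", 44), rep("C", 43), rep("A", 13))
  alt <- c(rep("T", 44), rep("A", 43), rep("G", 13))
  s <- mutationSpectrum(makeCalls(ref, alt))
  expect_equal(unname(classCounts(s)["G:C>T:A"]), 87)
  expect_equal(unname(classProportions(s)["G:C>T:A"]), 0.87)
  expect_equal(sum(classProportions(s)), 1, tolerance = 1e-12)

  one <- mutationSpectrum(makeCalls("A", "G"))
  expect_equal(unname(classProportions(one)["A:T>G:C"]), 1.0)

  # uniform 6 x 10
  refs <- c(rep("A", 30), rep("G", 30))
  alts <- c(rep(c("G", "T", "C"), each = 10), rep(c("A", "T", "C"), each = 10))
  u <- mutationSpectrum(makeCalls(refs, alts))
  expect_equal(unname(classProportions(u)), rep(1 / 6, 6))

  # empty subset: flagged via total 0 and NaN proportions
  empty <- mutationSpectrum(makeCalls("G", "T", status = "Germline"),
                            status = "Somatic")
  expect_equal(empty@total, 0)
  expect_true(all(is.nan(classProportions(empty))))
})

test_that("enrichment is the difference of proportions and sums to zero", {
  som <- mutationSpectrum(makeCalls(c(rep("G", 87), rep("A", 13)),
                                    c(rep("T", 87), rep("G", 13))))
  germ <- mutationSpectrum(
    makeCalls(c(rep("G", 7), rep("A", 93)), c(rep("T", 7), rep("G", 93)),
              status = "Germline", vaf1 = 0.5, vaf2 = 0.5),
    status = "Germline")
  enr <- spectrumEnrichment(som, germ)
  expect_equal(unname(enr["G:C>T:A"]), 0.80, tolerance = 1e-12)
  expect_equal(sum(enr), 0, tolerance = 1e-12)
  expect_equal(unname(spectrumEnrichment(som, som)), rep(0, 6))
  empty <- mutationSpectrum(makeCalls("G", "T"), status = "Germline")
  expect_error(spectrumEnrichment(som, empty), "non-empty")
})

test_that("zygosity reporting uses the >10% / <5% thresholds with a gap", {
  calls <- makeCalls(rep("G", 10), rep("T", 10),
                     vaf1 = c(rep(0.40, 7), rep(0.02, 2), 0.07),
                     vaf2 = c(rep(0.02, 7), rep(0.40, 2), 0.30))
  z <- zygosityByTissue(calls)
  expect_equal(z$hetT1, 7)
  expect_equal(z$hetT2, 2)
  expect_equal(z$indeterminate, 1)   # VAF 0.07 in [0.05, 0.10]
  expect_equal(z$fractionHetT1, 7 / 9)

  # boundary: VAF exactly 0.10 is not het, exactly 0.05 not hom
  b <- zygosityByTissue(makeCalls("G", "T", vaf1 = 0.10, vaf2 = 0.02))
  expect_equal(b$indeterminate, 1)
  b2 <- zygosityByTissue(makeCalls("G", "T", vaf1 = 0.40, vaf2 = 0.05))
  expect_equal(b2$indeterminate, 1)
})

test_that("3' context re-orients C>A events to the G strand", {
  #         123456789
  refChar <- "TTGATTCAT"   # G at 3 followed by A; C at 7 preceded by T
  callsG <- makeCalls("G", "T", pos = 3)
  expect_equal(unname(threePrimeContext(callsG, refChar)),
               c(1, 0, 0, 0))            # 3' base A
  callsC <- makeCalls("C", "A", pos = 7)
  # 5' neighbour is T at pos 6; on the G strand that reads A
  expect_equal(unname(threePrimeContext(callsC, refChar)),
               c(1, 0, 0, 0))
  # edge sites are excluded with a warning
  edge <- makeCalls("C", "A", pos = 1)
  expect_warning(res <- threePrimeContext(edge, refChar), "edge")
  expect_equal(sum(res), 0)

  # null behaviour: on a uniform random reference the 3' distribution is
  # approximately uniform
  set.seed(3)
  L <- 4001L
  bases <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  gPos <- which(bases == "G" & seq_along(bases) < L)
  calls <- makeCalls(rep("G", length(gPos)), rep("T", length(gPos)),
                     pos = gPos)
  tab <- threePrimeContext(calls, paste(bases, collapse = ""))
  props <- tab / sum(tab)
  expect_true(all(abs(props - 0.25) < 0.05))
})

test_that("CCG motif detection orients events to the C strand", {
  #          123456789
  refChar <- "ACCGATCGG"
  # C>A at pos 3: trinucleotide CCG with the mutated C in the middle
  expect_equal(ccgMotifFraction(makeCalls("C", "A", pos = 3), refChar)$counted,
               1)
  # C>A at pos 7 has context TCG: not counted
  expect_equal(ccgMotifFraction(makeCalls("C", "A", pos = 7), refChar)$counted,
               0)
  # G>T at pos 8: plus-strand context CGG reads CCG on the C strand
  res <- ccgMotifFraction(makeCalls("G", "T", pos = 8), refChar)
  expect_equal(res$counted, 1)
  expect_equal(res$fraction, 1)
  # mixed: one hit of two evaluable
  mix <- makeCalls(c("C", "C"), c("A", "A"), pos = c(3, 7))
  expect_equal(ccgMotifFraction(mix, refChar)$fraction, 0.5)
})
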