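test_that("genotype thresholds behave as closed lower bounds", {
  params <- CallingParams()
  gcase <- function(refN, altN, ref = "A", alt = "G") {
    site <- makeSite(ref, setNames(list(refN, altN), c(ref, alt)))
    as.data.frame(callGenotype(site, params))
  }
  expect_equal(gcase(50, 50)$genotype, "het")     # VAF 0.50
  expect_equal(gcase(5, 95)$genotype, "hom_alt")  # VAF 0.95
  expect_equal(gcase(4, 3)$genotype, "no_call")   # depth 7 < 8
  expect_equal(gcase(92, 8)$genotype, "hom_ref")  # VAF 0.08 < 0.10
  expect_equal(gcase(90, 10)$genotype, "het")     # VAF exactly 0.10
  expect_equal(gcase(10, 90)$genotype, "hom_alt") # VAF exactly 0.90

  # quality gates force no_call
  lowMQ <- makeSite("A", list(A = 60, G = 40), mapQual = 39)
  expect_equal(as.data.frame(callGenotype(lowMQ, params))$genotype, "no_call")
  lowBQ <- makeSite("A", list(A = 60, G = 40),
                    baseQual = matrix(c(35, NA, 19, NA), 1))
  expect_equal(as.data.frame(callGenotype(lowBQ, params))$genotype, "no_call")
})

test_that("fisherSomaticP matches hand-derivable and enumerated values", {
  expect_equal(fisherSomaticP(10, 0, 10, 0), 1.0)
  expect_equal(fisherSomaticP(10, 0, 0, 10), 1 / choose(20, 10))
  expect_equal(fisherSomaticP(8, 2, 5, 5), oracleFisherP(8, 2, 5, 5),
               tolerance = 1e-12)
  # direction: p is one-sided toward the variant-richer tissue
  expect_lt(fisherSomaticP(50, 0, 30, 20), 0.05)
  expect_equal(fisherSomaticP(50, 0, 30, 20),
               fisherSomaticP(30, 20, 50, 0), tolerance = 1e-12)
  expect_error(fisherSomaticP(0, 0, 0, 0), "zero depth")
  expect_error(fisherSomaticP(-1, 1, 1, 1), "non-negative")
})

test_that("somatic p never increases as tissue-2 variant support grows", {
  # within the regime where tissue 2 is the variant-richer tissue, a larger
  # variant excess can only make the one-sided tail smaller
  for (n1 in c(20, 50)) {
    for (v1 in c(0, 3)) {
      from <- ceiling(v1 / n1 * 50)
      v2s <- from:50
      p <- fisherSomaticP(rep(n1 - v1, length(v2s)), rep(v1, length(v2s)),
                          50 - v2s, v2s)
      expect_true(all(diff(p) <= 1e-12))
    }
  }
})

test_that("classifyPairs assigns the four statuses per the calling rules", {
  t1 <- bindSites(makeSite("G", list(G = 100), pos = 10),
                  makeSite("G", list(G = 60, T = 40), pos = 20),
                  makeSite("A", list(A = 50, G = 50), pos = 30),
                  makeSite("C", list(C = 4, A = 3), pos = 40),
                  makeSite("T", list(T = 40, A = 30, C = 30), pos = 50))
  t2 <- bindSites(makeSite("G", list(G = 97), pos = 10),
                  makeSite("G", list(G = 100), pos = 20),
                  makeSite("A", list(A = 50, G = 50), pos = 30),
                  makeSite("C", list(C = 90, A = 10), pos = 40),
                  makeSite("T", list(T = 60, A = 40), pos = 50))
  calls <- classifyPairs(t1, t2)
  d <- as.data.frame(calls)
  expect_equal(d$status,
               c("Reference", "Somatic", "Germline", "Undetermined",
                 "Undetermined"))
  # the somatic call: het in tissue 1, hom_ref in tissue 2, tiny p
  expect_equal(d$gt1[2], "het")
  expect_equal(d$gt2[2], "hom_ref")
  expect_equal(d$somaticP[2], oracleFisherP(60, 40, 100, 0),
               tolerance = 1e-12)
  expect_lt(d$somaticP[2], 0.05)
  # tri-allelic site (pos 50 in tissue 1) is Undetermined
  expect_equal(d$status[5], "Undetermined")
  # coordinate mismatch errors
  expect_error(classifyPairs(t1, t2[c(2, 1, 3, 4, 5)]), "identical")
})

test_that("swapping tissue labels mirrors the somatic direction", {
  t1 <- bindSites(makeSite("G", list(G = 60, T = 40), pos = 20))
  t2 <- bindSites(makeSite("G", list(G = 100), pos = 20))
  a <- as.data.frame(classifyPairs(t1, t2))
  b <- as.data.frame(classifyPairs(t2, t1))
  expect_equal(a$status, "Somatic")
  expect_equal(b$status, "Somatic")
  expect_equal(a$vaf1, b$vaf2)
  expect_equal(a$somaticP, b$somaticP, tolerance = 1e-12)
})

test_that("somatic percentage follows the (somatic / total) x 100 formula", {
  expect_equal(somaticPercentage(1, 1000), 0.1)
  expect_equal(somaticPercentage(0, 500), 0)
  expect_equal(somaticPercentage(48, 10000), 0.48)
  expect_error(somaticPercentage(1, 0), "undefined")
  expect_error(somaticPercentage(5, 3), "<=")
})

test_that("call-set concordance counts overlaps keyed by chrom:pos:alt", {
  a <- data.frame(chrom = "chr1", pos = 1:10, alt = "T")
  expect_equal(compareCallsets(a, a)$fractionAinB, 1.0)
  b <- data.frame(chrom = "chr1", pos = 11:20, alt = "T")
  expect_equal(compareCallsets(a, b)$fractionAinB, 0.0)
  a33 <- data.frame(chrom = "chr1", pos = 1:33, alt = "T")
  b26 <- data.frame(chrom = "chr1", pos = c(1:26, 101:110), alt = "T")
  res <- compareCallsets(a33, b26)
  expect_equal(res$intersection, 26)
  expect_equal(res$fractionAinB, 26 / 33)
  expect_equal(round(res$fractionAinB, 3), 0.788)
  expect_equal(res$aOnly, 7)
  expect_equal(res$bOnly, 10)
})

test_that("germline confidence rejects the hom-ref error model only with real support", {
  params <- CallingParams()
  expect_true(germlineConfident(40, 100, params))   # clear het
  expect_true(germlineConfident(99, 100, params))   # hom alt
  expect_false(germlineConfident(1, 100, params))   # looks like error
  expect_false(germlineConfident(0, 100, params))
})
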