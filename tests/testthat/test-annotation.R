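test_that("codon effects follow the genetic code on the plus strand", {
  toy <- makeToyGenome()
  # PLUS1 CDS at 11..40, codons ATG GCT GAG ...
  # GCT -> GCC (third codon position): synonymous Ala
  v <- data.frame(chrom = "chr1", pos = 16L, ref = "T", alt = "C")
  eff <- annotateEffects(v, toy$models, toy$refChar)
  expect_equal(eff$effect, "synonymous")
  expect_equal(eff$refAA, "A")
  expect_equal(eff$altAA, "A")
  expect_equal(eff$codonPos, 3L)
  # GAG -> TAG: stop gained
  v <- data.frame(chrom = "chr1", pos = 17L, ref = "G", alt = "T")
  eff <- annotateEffects(v, toy$models, toy$refChar)
  expect_equal(eff$effect, "stopgain")
  expect_equal(eff$refAA, "E")
  expect_equal(eff$altAA, "*")
  # inside the gene span but outside CDS -> UTR; outside genes -> noncoding
  v <- data.frame(chrom = "chr1", pos = c(7L, 60L), ref = "A", alt = "G")
  eff <- annotateEffects(v, toy$models, toy$refChar)
  expect_equal(eff$effect, c("UTR", "noncoding"))
})

test_that("minus-strand effects match whole-transcript re-translation", {
  toy <- makeToyGenome()
  cds <- toy$models[toy$models$gene_id == "MINUS1" &
                    toy$models$feature == "CDS", ]
  refCh <- strsplit(toy$refChar, "")[[1]]
  for (pos in seq(cds$start, cds$end)) {
    for (alt in setdiff(c("A", "C", "G", "T"), refCh[pos])) {
      got <- annotateEffects(
        data.frame(chrom = "chr1", pos = pos, ref = refCh[pos], alt = alt),
        toy$models, toy$refChar)$effect
      expect_equal(got, oracleEffect(pos, alt, toy$models, toy$refChar),
                   info = sprintf("pos=%d alt=%s", pos, alt))
    }
  }
})

test_that("random variants agree with the re-translation oracle on both strands", {
  gen <- makeRandomGenome(seed = 21)
  refCh <- strsplit(gen$refChar, "")[[1]]
  set.seed(22)
  pos <- sample.int(nchar(gen$refChar), 150, replace = TRUE)
  alt <- vapply(pos, function(p)
    sample(setdiff(c("A", "C", "G", "T"), refCh[p]), 1), character(1))
  got <- annotateEffects(
    data.frame(chrom = "chr1", pos = pos, ref = refCh[pos], alt = alt),
    gen$models, gen$refChar)$effect
  want <- mapply(oracleEffect, pos, alt,
                 MoreArgs = list(geneModels = gen$models,
                                 refChar = gen$refChar))
  expect_equal(got, unname(want))
})

test_that("syn/nonsyn summary covers coding sites only", {
  eff <- data.frame(effect = c(rep("nonsynonymous", 60), rep("stopgain", 4),
                               rep("synonymous", 36), rep("UTR", 20),
                               rep("noncoding", 10)))
  s <- synNonsynSummary(eff)
  expect_equal(s$nCoding, 100)
  expect_equal(s$fractionNonsynonymous, 0.64)
  expect_equal(synNonsynSummary(
    data.frame(effect = rep("synonymous", 5)))$fractionNonsynonymous, 0)
  expect_true(is.na(synNonsynSummary(
    data.frame(effect = "UTR"))$fractionNonsynonymous))
})

test_that("long-gene test equals the exhaustive hypergeometric tail", {
  bg <- data.frame(gene_id = sprintf("G%03d", 1:100),
                   length = c(rep(2e5, 18), rep(5e4, 82)))
  fg <- bg[c(1:5, 50:54), ]    # 5 long of 10
  res <- longGeneTest(fg, bg)
  expect_equal(res$k, 5)
  expect_equal(res$K, 18)
  expect_equal(res$pValue, oracleHyperTail(5, 10, 18, 100),
               tolerance = 1e-12)
  # no enrichment when fg == bg
  expect_equal(longGeneTest(bg, bg)$pValue, 1, tolerance = 1e-12)
  # maximal enrichment: all foreground long, no long genes elsewhere
  bg2 <- data.frame(gene_id = sprintf("G%03d", 1:50),
                    length = c(rep(2e5, 5), rep(1e4, 45)))
  res2 <- longGeneTest(bg2[1:5, ], bg2)
  expect_equal(res2$pValue, 1 / choose(50, 5), tolerance = 1e-12)
})

test_that("over-representation matches enumeration and brute-force BH", {
  universe <- sprintf("G%04d", 1:180)
  sets <- list(HIT = universe[1:5],
               PARTIAL = universe[c(1:3, 50:60)],
               MISS = universe[100:120])
  fg <- universe[1:5]
  res <- overrepresentation(fg, sets, universe)
  expect_equal(res$set[1], "HIT")
  hit <- res[res$set == "HIT", ]
  expect_equal(hit$pValue, oracleHyperTail(5, 5, 5, 180), tolerance = 1e-12)
  expect_equal(hit$pValue, 1 / choose(180, 5) * choose(175, 0) * choose(5, 5),
               tolerance = 1e-12)
  miss <- res[res$set == "MISS", ]
  expect_equal(miss$pValue, oracleHyperTail(0, 5, 21, 180), tolerance = 1e-12)
  expect_equal(res$padj, oracleBH(res$pValue), tolerance = 1e-12)
  # padj monotone in rank and <= 1
  expect_true(all(diff(res$padj) >= -1e-12))
  expect_true(all(res$padj <= 1))
  expect_error(overrepresentation("NOT_IN_UNIVERSE", sets, universe),
               "subset")
})

test_that("BH adjustment ties minimum achievable values as defined", {
  expect_equal(oracleBH(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), method = "BH"), rep(0.03, 3))
})
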