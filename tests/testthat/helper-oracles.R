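# Independent oracles used by the unit and acceptance tests. These
# deliberately avoid the code paths they check: brute-force enumeration
# with choose(), whole-transcript re-translation, exhaustive window
# comparison, and the textbook BH definition.

# One-sided Fisher p by exhaustive enumeration of all 2x2 tables with the
# observed margins: probability of tables whose tissue-2 variant count is at
# least (toward tissue 2) / at most (toward tissue 1) as extreme as observed,
# direction chosen toward the tissue with the higher variant fraction.
oracleFisherP <- function(ref1, var1, ref2, var2) {
  n1 <- ref1 + var1
  n2 <- ref2 + var2
  V <- var1 + var2
  N <- n1 + n2
  ks <- max(0, V - n1):min(V, n2)     # feasible tissue-2 variant counts
  probs <- choose(n2, ks) * choose(n1, V - ks) / choose(N, V)
  vaf1 <- if (n1 > 0) var1 / n1 else 0
  vaf2 <- if (n2 > 0) var2 / n2 else 0
  if (vaf2 >= vaf1) sum(probs[ks >= var2]) else sum(probs[ks <= var2])
}

# Exhaustive one-sided hypergeometric tail for over-representation:
# P(X >= k) with X = |draw of n from N containing K specials|.
oracleHyperTail <- function(k, n, K, N) {
  ks <- max(0, n - (N - K)):min(n, K)
  probs <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(probs[ks >= k])
}

# Benjamini-Hochberg from its definition: padj_i = min over j with
# p_(j) >= p_(i) of p_(j) * m / j, capped at 1.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Exhaustive all-pairs ungapped window identity on a small reference:
# returns the sorted window start positions whose identity with some
# non-overlapping window reaches minIdentity.
oracleIdentityWindows <- function(seqChar, window, minIdentity) {
  ch <- strsplit(seqChar, "", fixed = TRUE)[[1]]
  L <- length(ch)
  starts <- seq_len(L - window + 1L)
  hit <- logical(length(starts))
  for (i in starts) {
    for (j in starts) {
      if (abs(i - j) < window) next
      id <- mean(ch[i:(i + window - 1L)] == ch[j:(j + window - 1L)])
      if (id >= minIdentity) { hit[i] <- TRUE; break }
    }
  }
  starts[hit]
}

# Whole-transcript re-translation: effect of a genomic SNV on a gene,
# computed by rebuilding the full CDS with and without the variant and
# translating both, with no codon arithmetic shared with annotateEffects().
oracleEffect <- function(pos, alt, geneModels, refChar) {
  spans <- attr(geneModels, "geneSpans")
  best <- "noncoding"
  sev <- c(stopgain = 1, nonsynonymous = 2, synonymous = 3, UTR = 4,
           noncoding = 5)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (gi in seq_len(nrow(spans))) {
    if (pos < spans$start[gi] || pos > spans$end[gi]) next
    g <- spans$gene_id[gi]
    cds <- geneModels[geneModels$feature == "CDS" &
                      geneModels$gene_id == g, , drop = FALSE]
    cds <- cds[order(cds$start), , drop = FALSE]
    gpos <- unlist(mapply(seq, cds$start, cds$end, SIMPLIFY = FALSE))
    eff <- if (!pos %in% gpos) "UTR" else {
      refCh <- strsplit(refChar, "", fixed = TRUE)[[1]]
      mutCh <- refCh
      mutCh[pos] <- alt
      tx <- function(chars) {
        b <- chars[gpos]
        if (spans$strand[gi] == "-") b <- rev(comp[b])
        paste(b, collapse = "")
      }
      aaRef <- as.character(Biostrings::translate(
        Biostrings::DNAString(tx(refCh)), no.init.codon = TRUE))
      aaAlt <- as.character(Biostrings::translate(
        Biostrings::DNAString(tx(mutCh)), no.init.codon = TRUE))
      if (aaRef == aaAlt) "synonymous"
      else {
        d <- which(strsplit(aaRef, "")[[1]] != strsplit(aaAlt, "")[[1]])
        if (substring(aaAlt, d[1], d[1]) == "*") "stopgain"
        else "nonsynonymous"
      }
    }
    if (sev[[eff]] < sev[[best]]) best <- eff
  }
  best
}
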