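# Shared fixture builders and independent oracles.

# A tiny hand-built repertoire: two synonymous variants of one TCR, one
# singleton TCR, one singleton under a different V gene.
toyClonotypes <- function() {
  data.frame(
    v_gene = c("TRBV19", "TRBV19", "TRBV19", "TRBV20"),
    cdr3_nt = c("TGTGCCAGCAGCATCAGATCATCGTACGAGCAGTACTTC",
                "TGTGCCAGCAGCATCAGATCATCGTACGAGCAGTATTTC",
                "TGTGCCAGCAGCTTGGGGGACGAGCAGTACTTC",
                "TGTGCCAGCAGCATCAGATCATCGTACGAGCAGTACTTC"),
    cdr3_aa = c("CASSIRSSYEQYF", "CASSIRSSYEQYF", "CASSLGDEQYF",
                "CASSIRSSYEQYF"),
    count = c(4, 1, 7, 2),
    stringsAsFactors = FALSE)
}

toyRepertoire <- function(sampleId = "toy") {
  filterRepertoire(Repertoire(sampleId, toyClonotypes()))
}

# Random QC-passing repertoires for property tests: draws amino-acid keys
# with deliberate collisions so degeneracy > 1 occurs.
randomRepertoire <- function(nRecords, seed) {
  set.seed(seed)
  aaPool <- replicate(max(3L, nRecords %/% 3L), paste0(
    "CASS", paste(sample(c("G", "S", "Y", "E", "L", "R", "I"),
                         sample(4:8, 1), replace = TRUE), collapse = ""),
    "QYF"))
  codons <- list(G = c("GGA", "GGC", "GGG", "GGT"),
                 S = c("AGC", "AGT", "TCA", "TCC", "TCG", "TCT"),
                 Y = c("TAC", "TAT"), E = c("GAA", "GAG"),
                 L = c("CTA", "CTC", "CTG", "CTT", "TTA", "TTG"),
                 R = c("AGA", "AGG", "CGA", "CGC", "CGG", "CGT"),
                 I = c("ATA", "ATC", "ATT"), C = "TGT", A = "GCC",
                 Q = "CAG", F = "TTC")
  rows <- lapply(seq_len(nRecords), function(i) {
    aa <- sample(aaPool, 1)
    nt <- paste(vapply(strsplit(aa, "")[[1]],
                       function(ch) sample(codons[[ch]], 1), ""),
                collapse = "")
    data.frame(v_gene = sample(c("TRBV5", "TRBV19"), 1), cdr3_nt = nt,
               cdr3_aa = aa, count = sample(1:20, 1),
               stringsAsFactors = FALSE)
  })
  filterRepertoire(Repertoire(sprintf("rand%d", seed),
                              do.call(rbind, rows)))
}

# Brute-force oracle: nested-loop count of distinct nucleotide strings per
# (v_gene, cdr3_aa) key, independent of the grouped implementation.
bruteDegeneracy <- function(rep) {
  df <- clonotypes(rep)
  keys <- unique(paste(df$v_gene, df$cdr3_aa, sep = "|"))
  out <- setNames(integer(length(keys)), keys)
  for (k in keys) {
    seen <- character(0)
    for (i in seq_len(nrow(df))) {
      if (paste(df$v_gene[i], df$cdr3_aa[i], sep = "|") == k &&
          !(df$cdr3_nt[i] %in% seen))
        seen <- c(seen, df$cdr3_nt[i])
    }
    out[k] <- length(seen)
  }
  out
}

# Exhaustive hypergeometric oracle for the two-sided Fisher p-value:
# table probabilities from choose() products over all tables with the
# observed margins (same tie convention as the implementation).
fisherOracleP <- function(a, b, c, d) {
  m1 <- a + b; n1 <- c + d; k <- a + c
  xs <- max(0, k - n1):min(k, m1)
  logp <- lchoose(m1, xs) + lchoose(n1, k - xs) - lchoose(m1 + n1, k)
  probs <- exp(logp)
  pObs <- probs[xs == a]
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

# Write a small immunoSEQ-dialect TSV and return the path.
writeImmunoseqFixture <- function(df, colnames = c("nucleotide", "aminoAcid",
                                                   "vGeneName", "templates")) {
  path <- tempfile(fileext = ".tsv")
  names(df) <- colnames
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
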