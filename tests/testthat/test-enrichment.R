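universeOf <- function(n) sprintf("k%04d", seq_len(n))

enrichFromCells <- function(a, b, c, d) {
  u <- universeOf(a + b + c + d)
  setK <- u[seq_len(a + b)]
  labK <- u[c(seq_len(a), a + b + seq_len(c))]
  fisherEnrichment(setK, labK, u)
}

test_that("contingency cells, odds ratio and zero-cell correction are as defined", {
  e <- enrichFromCells(5, 5, 5, 5)
  expect_equal(e@oddsRatio, 1)
  expect_equal(e@pValue, 1)
  expect_false(e@corrected)
  expect_equal(as.vector(e@table), c(5, 5, 5, 5))

  e2 <- enrichFromCells(9, 1, 11, 79)
  expect_equal(e2@oddsRatio, (9 * 79) / (1 * 11))
  expect_equal(e2@pValue, fisherOracleP(9, 1, 11, 79))

  e3 <- enrichFromCells(10, 0, 5, 85)
  expect_true(e3@corrected)
  expect_equal(e3@oddsRatio, (10.5 * 85.5) / (0.5 * 5.5))
  expect_equal(e3@log10OddsRatio, log10(e3@oddsRatio))
})

test_that("the exact p equals exhaustive enumeration and fisher.test cross-checks", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(20:200, 1)
    a <- sample(0:10, 1); b <- sample(0:15, 1); c <- sample(0:15, 1)
    d <- n - a - b - c
    if (d < 0) next
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    e <- enrichFromCells(a, b, c, d)
    expect_equal(e@pValue, fisherOracleP(a, b, c, d), tolerance = 1e-12)
    ft <- fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
    expect_equal(e@pValue, ft$p.value, tolerance = 1e-9)
  }
})

test_that("identical set and label gives the hypergeometric point mass", {
  u <- universeOf(40)
  s <- u[1:8]
  e <- fisherEnrichment(s, s, u)
  expect_true(e@corrected)  # b = c = 0
  expect_equal(e@pValue, dhyper(8, 8, 32, 8))
})

test_that("enrichment is symmetric in set and label and validates inputs", {
  u <- universeOf(60)
  s <- u[1:12]; l <- u[c(2:9, 30:40)]
  e1 <- fisherEnrichment(s, l, u)
  e2 <- fisherEnrichment(l, s, u)
  expect_equal(e1@oddsRatio, e2@oddsRatio)
  expect_equal(e1@pValue, e2@pValue)
  expect_error(fisherEnrichment(c(s, "zzz"), l, u), "subset")
  expect_error(fisherEnrichment(s, l, character(0)), "empty")
  # labels = universe: degenerate, corrected branch
  eDeg <- fisherEnrichment(s, u, u)
  expect_true(eDeg@corrected)
})

test_that("the exact p agrees in distribution with a label-permutation p", {
  set.seed(7)
  u <- universeOf(200)
  s <- u[1:30]
  l <- u[c(1:12, 60:87)]  # 40 labels, 12 overlapping
  e <- fisherEnrichment(s, l, u)
  pObs <- dhyper(sum(s %in% l), 30, 170, 40)
  B <- 2000
  stat <- replicate(B, {
    perm <- sample(u, 40)
    dhyper(sum(s %in% perm), 30, 170, 40)
  })
  pPerm <- mean(stat <= pObs * (1 + 1e-7))
  se <- sqrt(e@pValue * (1 - e@pValue) / B)
  expect_lt(abs(pPerm - e@pValue), 4 * se + 1e-3)
})

test_that("top-k expansion selection is matched, deterministic and tie-stable", {
  df <- data.frame(
    v_gene = "TRBV19",
    cdr3_nt = c("TGTGCAAGTAGTGCATACGAACAATATTTC",
                "TGTGCAAGTAGTTGCTACGAACAATATTTC",
                "TGTGCAAGTAGTTGTTACGAACAATATTTC",
                "TGTGCAAGTAGTGATTACGAACAATATTTC"),
    cdr3_aa = c("CASSAYEQYF", "CASSCYEQYF", "CASSCYEQYF", "CASSDYEQYF"),
    count = c(10, 4, 1, 5), stringsAsFactors = FALSE)
  g <- convergentGroups(filterRepertoire(Repertoire("s", df)))
  # totals: A=10, C=5 (two variants, max 4), D=5 (max 5)
  # tie at rank 2 between C and D: higher max variant count wins -> D
  expect_identical(selectExpanded(g, 2),
                   c("TRBV19|CASSAYEQYF", "TRBV19|CASSDYEQYF"))
  expect_identical(selectExpanded(g, 0), character(0))
  expect_warning(sel <- selectExpanded(g, 10), "exceeds")
  expect_equal(length(sel), 3L)

  # lexicographic fallback when totals and max variant counts all tie
  df2 <- df[c(1, 4), ]
  df2$count <- 5
  g2 <- convergentGroups(filterRepertoire(Repertoire("s", df2)))
  expect_identical(selectExpanded(g2, 1), "TRBV19|CASSAYEQYF")
})

test_that("convergence beats matched expansion when enrichment is planted in convergent clones", {
  wins <- 0L
  nSeeds <- 20L
  for (s in seq_len(nSeeds)) {
    sim <- simulateRepertoire(
      simulationConfig(seed = 500 + s, nGroups = 2000,
                       specificOddsMultiplier = 6), "s")
    g <- convergentGroups(filterRepertoire(sim$repertoire))
    res <- convergenceVsExpansion(
      setNames(list(g), "s"),
      setNames(list(sim$truth$key[sim$truth$specific]), "s"))
    if (res$per_sample$or_convergence > res$per_sample$or_expansion)
      wins <- wins + 1L
  }
  expect_gte(wins / nSeeds, 0.95)
})

test_that("samples without convergent TCRs are excluded from the paired comparison", {
  df <- toyClonotypes()[3, ]  # single degeneracy-1 group
  gEmpty <- convergentGroups(filterRepertoire(Repertoire("none", df)))
  gFull <- convergentGroups(toyRepertoire())
  labels <- list(none = character(0), toy = "TRBV19|CASSIRSSYEQYF")
  res <- convergenceVsExpansion(list(none = gEmpty, toy = gFull), labels)
  expect_identical(res$summary$excluded, "none")
  expect_equal(nrow(res$per_sample), 1L)
})
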