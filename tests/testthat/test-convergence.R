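test_that("degeneracy counts distinct nucleotide variants per (V, CDR3aa) key", {
  g <- convergentGroups(toyRepertoire())
  tab <- groupTable(g)
  expect_equal(nrow(tab), 3L)
  # two synonymous nt for TRBV19|CASSIRSSYEQYF -> degeneracy 2
  expect_equal(tab$degeneracy[tab$key == "TRBV19|CASSIRSSYEQYF"], 2L)
  expect_equal(tab$total_count[tab$key == "TRBV19|CASSIRSSYEQYF"], 5)
  # same cdr3_aa+nt under a different V gene is a separate degeneracy-1 group
  expect_equal(tab$degeneracy[tab$key == "TRBV20|CASSIRSSYEQYF"], 1L)
  expect_equal(tab$degeneracy[tab$key == "TRBV19|CASSLGDEQYF"], 1L)
  expect_identical(convergentSet(g), "TRBV19|CASSIRSSYEQYF")
  expect_equal(convergenceLevel(g), 1L)
  expect_equal(convergentCloneFraction(g), 1 / 3)
})

test_that("unfiltered repertoires are refused", {
  rep <- Repertoire("raw", toyClonotypes())
  expect_error(convergentGroups(rep), "QC-filtered")
})

test_that("grouping is invariant to input record order", {
  df <- toyClonotypes()
  g1 <- convergentGroups(filterRepertoire(Repertoire("a", df)))
  g2 <- convergentGroups(filterRepertoire(Repertoire("a", df[c(4, 2, 3, 1), ])))
  expect_identical(groupTable(g1), groupTable(g2))
})

test_that("adding a synonymous variant raises one group's degeneracy by exactly 1", {
  df <- toyClonotypes()
  extra <- data.frame(v_gene = "TRBV19",
                      cdr3_nt = "TGTGCCAGCAGCATAAGATCATCGTACGAGCAGTACTTC",
                      cdr3_aa = "CASSIRSSYEQYF", count = 1,
                      stringsAsFactors = FALSE)
  before <- groupTable(convergentGroups(filterRepertoire(Repertoire("a", df))))
  after <- groupTable(convergentGroups(filterRepertoire(
    Repertoire("a", rbind(df, extra)))))
  expect_equal(after$degeneracy[after$key == "TRBV19|CASSIRSSYEQYF"],
               before$degeneracy[before$key == "TRBV19|CASSIRSSYEQYF"] + 1L)
  others <- setdiff(before$key, "TRBV19|CASSIRSSYEQYF")
  expect_identical(before[match(others, before$key), c("degeneracy", "total_count")],
                   after[match(others, after$key), c("degeneracy", "total_count")])
})

test_that("degeneracy equals the brute-force nested-loop count on random repertoires", {
  for (seed in 1:10) {
    rep <- randomRepertoire(nRecords = 60, seed = seed)
    g <- groupTable(convergentGroups(rep))
    oracle <- bruteDegeneracy(rep)
    expect_identical(setNames(as.integer(g$degeneracy), g$key),
                     oracle[g$key], info = paste("seed", seed))
  }
})

test_that("the degeneracy spectrum is the exact histogram and conserves totals", {
  # degeneracies [1,1,2,2,3] -> {1:2, 2:2, 3:1}, convergent shares {2:2/3, 3:1/3}
  df <- data.frame(
    v_gene = "TRBV19",
    cdr3_nt = c("TGTGCAAGTAGTAGTTACGAACAATATTTC",  # g1 v1
                "TGTGCAAGTAGTAGTTATGAACAATATTTC",  # g1 v2
                "TGTGCAAGTAGTGGGTACGAACAATATTTC",  # g2 v1
                "TGTGCAAGTAGTGGATACGAACAATATTTC",  # g2 v2
                "TGTGCAAGTAGTTTGTACGAACAATATTTC",  # g3 v1
                "TGTGCAAGTAGTTTATACGAACAATATTTC",  # g3 v2
                "TGTGCAAGTAGTCTATACGAACAATATTTC",  # g3 v3
                "TGTGCAAGTAGTGAGTACGAACAATATTTC",  # g4
                "TGTGCAAGTAGTCGGTACGAACAATATTTC"), # g5
    cdr3_aa = c("CASSSYEQYF", "CASSSYEQYF", "CASSGYEQYF", "CASSGYEQYF",
                "CASSLYEQYF", "CASSLYEQYF", "CASSLYEQYF", "CASSEYEQYF",
                "CASSRYEQYF"),
    count = 1, stringsAsFactors = FALSE)
  g <- convergentGroups(filterRepertoire(Repertoire("s", df)))
  spec <- degeneracySpectrum(g)
  expect_equal(spec$n_groups, c(2L, 2L, 1L))
  expect_equal(spec$degeneracy, 1:3)
  expect_equal(spec$convergent_share, c(NA, 2 / 3, 1 / 3))
  # conservation: counts sum to groups; d-weighted counts to clonotypes
  expect_equal(sum(spec$n_groups), nrow(groupTable(g)))
  expect_equal(sum(spec$degeneracy * spec$n_groups), nrow(df))

  expect_warning(er <- filterRepertoire(Repertoire("e", df[0, ])),
                 "removed every clonotype")
  expect_equal(nrow(degeneracySpectrum(convergentGroups(er))), 0L)
})

test_that("length and V-gene profiles match hand-computed means", {
  g <- convergentGroups(toyRepertoire())
  prof <- lengthVGeneProfiles(g)
  # lengths: CASSIRSSYEQYF (13) twice, CASSLGDEQYF (11) once
  expect_equal(prof$length$length, c(11L, 13L))
  expect_equal(prof$length$n_groups, c(1L, 2L))
  # mean degeneracy at length 13: groups have degeneracy 2 and 1
  expect_equal(prof$length$mean_degeneracy, c(1, 1.5))
  expect_equal(prof$v_gene$n_groups[prof$v_gene$v_gene == "TRBV19"], 2L)
  expect_equal(prof$v_family$mean_degeneracy[prof$v_family$v_family == "TRBV19"],
               1.5)
})

test_that("interior amino-acid composition strips 3+3 residues and pools per group", {
  g <- convergentGroups(toyRepertoire())
  comp1 <- aaComposition(g, 1)
  expect_equal(sum(comp1), 1)
  comp2 <- aaComposition(g, 2)
  # single degeneracy-2 group CASSIRSSYEQYF -> interior SIRSSYE
  expect_equal(unname(comp2["S"]), 3 / 7)
  expect_equal(unname(comp2["I"]), 1 / 7)
  expect_equal(unname(comp2["R"]), 1 / 7)
  expect_equal(unname(comp2["Y"]), 1 / 7)
  expect_equal(unname(comp2["E"]), 1 / 7)
  expect_equal(sum(comp2), 1)

  # pooled counts equal a brute-force letter tally over interiors
  tab <- groupTable(g)
  interiors <- substr(tab$cdr3_aa[tab$degeneracy == 1],
                      4, nchar(tab$cdr3_aa[tab$degeneracy == 1]) - 3)
  tally <- table(strsplit(paste(interiors, collapse = ""), "")[[1]])
  for (a in names(tally))
    expect_equal(unname(attr(comp1, "counts")[a]), unname(as.numeric(tally[a])))
  expect_warning(aaComposition(g, 4), "no groups")
})

test_that("amino-acid enrichment uses the exact two-sided binomial test", {
  # direct pmf-summation oracle on pinned cases
  binomOracle <- function(k, m, p0) {
    probs <- dbinom(0:m, m, p0)
    sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
  }
  expect_equal(binom.test(5, 10, 0.5)$p.value, 1)
  expect_equal(binom.test(10, 10, 0.5)$p.value, 2 / 1024)
  expect_equal(binom.test(0, 1, 0.5)$p.value, 1)
  for (cs in list(c(3, 20, 0.1), c(17, 40, 0.25), c(0, 12, 0.3)))
    expect_equal(binom.test(cs[1], cs[2], cs[3])$p.value,
                 binomOracle(cs[1], cs[2], cs[3]))

  # wired through the composition tables
  g <- convergentGroups(toyRepertoire())
  res <- aaEnrichmentTest(g, "S", d = 2)
  expect_equal(res$k, 3)
  expect_equal(res$m, 7)
  expect_equal(res$p_value,
               binom.test(res$k, res$m, res$p0)$p.value)
})

test_that("paired single-cell grouping keys on both chains and counts nt combinations", {
  cl <- data.frame(
    barcode = c("b1", "b2", "b3", "b4"),
    beta_v = "TRBV19",
    beta_cdr3_nt = c("TGTGCCAGCAGCTTC", "TGTGCCAGCAGTTTC",
                     "TGTGCCAGCAGCTTC", "TGTGCCAGCAGCTTC"),
    beta_cdr3_aa = "CASSF",
    alpha_v = c("TRAV1", "TRAV1", "TRAV1", "TRAV2"),
    alpha_cdr3_nt = "TGTGCCGTGTTC",
    alpha_cdr3_aa = "CAVF",
    stringsAsFactors = FALSE)
  pc <- new("PairedCells", cells = cl,
            dropped = list(no_beta = 0L, multi_beta = 0L))
  g <- convergentGroups(pc)
  tab <- groupTable(g)
  # b1..b3 share the (beta,alpha) aa key; two distinct beta nt -> degeneracy 2
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$degeneracy[grepl("TRAV1", tab$key)], 2L)
  expect_equal(tab$degeneracy[grepl("TRAV2", tab$key)], 1L)
})
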