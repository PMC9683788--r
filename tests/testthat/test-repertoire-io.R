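test_that("immunoSEQ reading aggregates duplicate clonotypes and resolves synonyms", {
  df <- data.frame(nt = c("TGTGCCAGCAGC", "TGTGCCAGCAGC", "TGTGCCAGCAGT"),
                   aa = c("CASS", "CASS", "CASS"),
                   v = c("TRBV19*01", "TRBV19*02", "TRBV19"),
                   n = c(3, 2, 5))
  path <- writeImmunoseqFixture(df)
  rep <- readBulkRepertoire(path, "immunoseq")
  expect_equal(nClonotypes(rep), 2L)   # allele suffixes stripped, nt aggregated
  expect_equal(totalReads(rep), 10)
  expect_equal(clonotypes(rep)$count[clonotypes(rep)$cdr3_nt ==
                                       "TGTGCCAGCAGC"], 5)

  # synonym spellings of each column also resolve
  path2 <- writeImmunoseqFixture(df, c("rearrangement", "amino_acid",
                                       "v_gene", "reads"))
  rep2 <- readBulkRepertoire(path2, "immunoseq")
  expect_equal(clonotypes(rep2)[, c("v_gene", "cdr3_nt", "count")],
               clonotypes(rep)[, c("v_gene", "cdr3_nt", "count")])
})

test_that("AIRR dialect is read and missing required columns are named", {
  df <- data.frame(junction = c("TGTGCCAGCAGC", "TGTGCCAGTTCT"),
                   junction_aa = c("CASS", "CASS"),
                   v_call = c("TRBV19*01", "TRBV19*01"),
                   duplicate_count = c(2, 3))
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rep <- readBulkRepertoire(path, "airr")
  expect_equal(nClonotypes(rep), 2L)  # rows differing only in cdr3_nt stay separate
  expect_equal(unique(clonotypes(rep)$v_gene), "TRBV19")

  write.table(df[, -3], path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readBulkRepertoire(path, "airr"), "v_call")
  expect_error(readBulkRepertoire(tempfile(), "airr"), "no such file")
})

test_that("rows with empty CDR3 aa are dropped and conflicting aa is a hard error", {
  df <- data.frame(nt = c("TGTGCCAGCAGC", "TGTGCCAGCAGT"),
                   aa = c("CASS", ""), v = "TRBV19", n = c(1, 1))
  rep <- readBulkRepertoire(writeImmunoseqFixture(df), "immunoseq")
  expect_equal(nClonotypes(rep), 1L)

  bad <- data.frame(v_gene = "TRBV19", cdr3_nt = "TGTGCCAGCAGC",
                    cdr3_aa = c("CASS", "CASR"), count = 1)
  expect_error(Repertoire("x", bad), "conflicting cdr3_aa")
})

test_that("reading is invariant to row order and write/read round-trips", {
  rep <- toyRepertoire()
  shuffled <- toyClonotypes()[c(3, 1, 4, 2), ]
  rep2 <- filterRepertoire(Repertoire("toy", shuffled))
  expect_identical(clonotypes(rep), clonotypes(rep2))

  path <- tempfile(fileext = ".tsv")
  writeReportTSV(rep, path)
  back <- readBulkRepertoire(path, "immunoseq", sampleId = "toy")
  expect_identical(
    clonotypes(back)[, c("v_gene", "cdr3_nt", "count")],
    clonotypes(rep)[, c("v_gene", "cdr3_nt", "count")])

  # byte-identical on repeated writes
  path2 <- tempfile(fileext = ".tsv")
  writeReportTSV(rep, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("writeReportTSV emits a header-only file for empty results", {
  path <- tempfile(fileext = ".tsv")
  writeReportTSV(data.frame(a = character(), b = numeric()), path)
  expect_identical(readLines(path), "a\tb")
})

test_that("CDR3 translation follows the standard code and flags stops/frames", {
  expect_equal(as.character(translateCDR3("TGTGCCAGCAGC")), "CASS")
  out <- translateCDR3(c("TGTGCCAGCAGC", "TGA"))
  expect_identical(attr(out, "productive"), c(TRUE, FALSE))
  expect_error(translateCDR3("TGTGC"), "frame")
  expect_error(translateCDR3("TGTGCN"), "A, C, G, T")
})

test_that("10x contigs pair one productive beta with the best-supported alpha", {
  contigs <- data.frame(
    barcode = c("bc1", "bc1", "bc1", "bc2", "bc2", "bc3", "bc4"),
    chain = c("TRB", "TRA", "TRA", "TRB", "TRB", "TRB", "TRA"),
    v_gene = c("TRBV19*01", "TRAV1", "TRAV2", "TRBV5", "TRBV6", "TRBV7",
               "TRAV3"),
    cdr3 = c("CASSF", "CAVF", "CAMF", "CASRF", "CASTF", "CASQF", "CALF"),
    cdr3_nt = c("TGTGCCAGCAGCTTC", "TGTGCCGTGTTC", "TGTGCCATGTTC",
                "TGTGCCAGCAGATTC", "TGTGCCAGCACTTTC", "TGTGCCAGCCAGTTC",
                "TGTGCCCTGTTC"),
    productive = "true",
    reads = c(10, 3, 8, 5, 5, 2, 1))
  path <- tempfile(fileext = ".csv")
  write.csv(contigs, path, row.names = FALSE)
  pc <- read10xContigs(path)
  cl <- cells(pc)
  # bc1: one beta + the higher-read alpha (TRAV2); bc2: two betas dropped;
  # bc3: beta only, alpha absent; bc4: no beta, dropped
  expect_equal(cl$barcode, c("bc1", "bc3"))
  expect_equal(cl$alpha_v[cl$barcode == "bc1"], "TRAV2")
  expect_true(is.na(cl$alpha_cdr3_aa[cl$barcode == "bc3"]))
  expect_equal(droppedCells(pc)$multi_beta, 1L)
  expect_equal(droppedCells(pc)$no_beta, 1L)

  # a file with no beta contigs warns and returns an empty result
  write.csv(contigs[contigs$chain == "TRA", ], path, row.names = FALSE)
  expect_warning(pc0 <- read10xContigs(path), "no productive beta")
  expect_equal(nrow(cells(pc0)), 0L)
})
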