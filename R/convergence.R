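# Core statistic: amino-acid-level TCR grouping, nucleotide-variant
# degeneracy, and the descriptive statistics built on it.

#' Group clonotypes into amino-acid-level TCRs and count degeneracy
#'
#' Partitions a QC-filtered repertoire into amino-acid-level TCR groups.
#' In \code{bulk_beta} mode the grouping key is (V gene, CDR3 amino-acid
#' sequence); the degeneracy of a group is the number of distinct CDR3
#' nucleotide sequences observed for that key within the sample. A group
#' with degeneracy >= 2 is convergent. Degeneracy is computed strictly
#' within one sample; pooling repertoires before grouping would conflate
#' convergence with publicity and is deliberately not offered here.
#'
#' In \code{paired_sc} mode the input is a \code{\link{PairedCells-class}}
#' object; the key concatenates the beta and alpha (V gene, CDR3 aa) pairs
#' and degeneracy counts distinct (beta nt, alpha nt) combinations. Cells
#' without an alpha chain are keyed on the beta chain with an explicit
#' missing-alpha marker.
#'
#' @param x a QC-filtered \code{\link{Repertoire-class}} (\code{bulk_beta})
#'   or a \code{\link{PairedCells-class}} (\code{paired_sc}).
#' @param mode \code{"bulk_beta"} or \code{"paired_sc"}; defaults to the
#'   mode matching the input class.
#' @param includeJ also include the J gene in the grouping key (off by
#'   default: the convergence definition names only the CDR3 amino-acid
#'   sequence and the variable gene).
#' @return A \code{\link{ConvergentGroups-class}} object.
#' @examples
#' df <- data.frame(v_gene = "TRBV19",
#'                  cdr3_nt = c("TGTGCCAGCAGCATCAGATCATCGTACGAGCAGTACTTC",
#'                              "TGTGCCAGCAGCATCAGATCATCGTACGAGCAGTATTTC"),
#'                  cdr3_aa = "CASSIRSSYEQYF", count = c(4, 1))
#' rep <- filterRepertoire(Repertoire("toy", df))
#' convergentGroups(rep)  # one group, degeneracy 2
#' @export
convergentGroups <- function(x, mode = NULL, includeJ = FALSE) {
  if (is(x, "Repertoire")) {
    if (is.null(mode)) mode <- "bulk_beta"
    if (mode != "bulk_beta")
      stopf("a Repertoire can only be grouped in 'bulk_beta' mode")
    if (!x@qcFiltered)
      stopf("repertoire '%s' has not been QC-filtered; run filterRepertoire() first",
            x@sampleId)
    df <- x@clonotypes
    keyv <- if (includeJ && !all(is.na(df$j_gene)))
      paste(df$v_gene, df$j_gene, df$cdr3_aa, sep = "|")
    else tcrKey(df$v_gene, df$cdr3_aa)
    dt <- as.data.table(data.frame(
      key = keyv, v_gene = df$v_gene, cdr3_aa = df$cdr3_aa,
      cdr3_nt = df$cdr3_nt, count = df$count, stringsAsFactors = FALSE))
    sid <- x@sampleId
  } else if (is(x, "PairedCells")) {
    if (is.null(mode)) mode <- "paired_sc"
    if (mode != "paired_sc")
      stopf("PairedCells can only be grouped in 'paired_sc' mode")
    cl <- x@cells
    av <- ifelse(is.na(cl$alpha_v), "<no-alpha>", cl$alpha_v)
    aa <- ifelse(is.na(cl$alpha_cdr3_aa), "", cl$alpha_cdr3_aa)
    ant <- ifelse(is.na(cl$alpha_cdr3_nt), "", cl$alpha_cdr3_nt)
    dt <- as.data.table(data.frame(
      key = tcrKey(cl$beta_v, cl$beta_cdr3_aa, av, aa),
      v_gene = cl$beta_v, cdr3_aa = cl$beta_cdr3_aa,
      cdr3_nt = paste(cl$beta_cdr3_nt, ant, sep = "+"),
      count = 1, stringsAsFactors = FALSE))
    sid <- "paired_sc"
  } else {
    stopf("cannot compute convergent groups from a %s", class(x)[1L])
  }
  # aggregate duplicated nucleotide variants (paired_sc cells can repeat a
  # clonotype), then count distinct variants per key
  dt <- dt[, list(count = sum(count)),
           by = c("key", "v_gene", "cdr3_aa", "cdr3_nt")]
  setorder(dt, key, cdr3_nt)
  g <- dt[, list(v_gene = v_gene[1L], cdr3_aa = cdr3_aa[1L],
                 degeneracy = .N, n_variants = .N,
                 total_count = sum(count),
                 max_variant_count = max(c(0, count)),
                 variants = list(cdr3_nt)),
          by = "key"]
  setorder(g, key)
  gdf <- as.data.frame(g)
  rownames(gdf) <- NULL
  new("ConvergentGroups", sampleId = sid, mode = mode, groups = gdf)
}

#' Convergent TCR keys and convergence level
#'
#' The convergent set is exactly the amino-acid-level keys with degeneracy
#' >= 2. The convergence level of a sample is the size of this set; the
#' convergent clone fraction is the level divided by the number of groups.
#'
#' @param groups a \code{\link{ConvergentGroups-class}}.
#' @return \code{convergentSet}: character vector of keys (sorted).
#' @examples
#' \dontrun{convergentSet(convergentGroups(rep))}
#' @export
convergentSet <- function(groups) {
  stopifnot(is(groups, "ConvergentGroups"))
  g <- groups@groups
  sort(g$key[g$degeneracy >= 2L])
}

#' @rdname convergentSet
#' @return \code{convergenceLevel}: integer count of convergent groups.
#' @export
convergenceLevel <- function(groups) {
  stopifnot(is(groups, "ConvergentGroups"))
  sum(groups@groups$degeneracy >= 2L)
}

#' @rdname convergentSet
#' @return \code{convergentCloneFraction}: convergent groups / all groups.
#' @export
convergentCloneFraction <- function(groups) {
  stopifnot(is(groups, "ConvergentGroups"))
  g <- groups@groups
  if (nrow(g) == 0L) return(NaN)
  sum(g$degeneracy >= 2L) / nrow(g)
}

#' Degeneracy spectrum
#'
#' Histogram of group degeneracies: for each degeneracy d = 1, 2, 3, ...
#' the number of amino-acid-level groups encoded by exactly d distinct
#' nucleotide variants, together with each convergent class's share of all
#' convergent groups. The spectrum conserves both totals: the counts sum
#' to the number of groups, and d-weighted counts sum to the number of
#' nucleotide-level clonotypes.
#'
#' @param groups a \code{\link{ConvergentGroups-class}}.
#' @return data.frame with columns \code{degeneracy}, \code{n_groups} and
#'   \code{convergent_share} (NA for d = 1; for d >= 2 the fraction of all
#'   convergent groups in that class).
#' @export
degeneracySpectrum <- function(groups) {
  stopifnot(is(groups, "ConvergentGroups"))
  d <- groups@groups$degeneracy
  if (length(d) == 0L)
    return(data.frame(degeneracy = integer(), n_groups = integer(),
                      convergent_share = numeric()))
  tab <- table(d)
  out <- data.frame(degeneracy = as.integer(names(tab)),
                    n_groups = as.integer(tab))
  nConv <- sum(out$n_groups[out$degeneracy >= 2L])
  out$convergent_share <- ifelse(out$degeneracy >= 2L & nConv > 0L,
                                 out$n_groups / nConv, NA_real_)
  out
}

#' CDR3 length and V-gene usage profiles
#'
#' Per-length and per-V-gene group counts for all groups and for
#' convergent groups, plus the mean degeneracy per CDR3 length and per
#' V-gene family.
#'
#' @param groups a \code{\link{ConvergentGroups-class}}.
#' @return list of data.frames \code{length} (columns \code{length},
#'   \code{n_groups}, \code{n_convergent}, \code{mean_degeneracy}) and
#'   \code{v_gene} (columns \code{v_gene}, \code{v_family},
#'   \code{n_groups}, \code{n_convergent}) and \code{v_family}
#'   (\code{v_family}, \code{n_groups}, \code{mean_degeneracy}).
#' @export
lengthVGeneProfiles <- function(groups) {
  stopifnot(is(groups, "ConvergentGroups"))
  g <- as.data.table(groups@groups[, c("v_gene", "cdr3_aa", "degeneracy")])
  g[, len := nchar(cdr3_aa)]
  g[, conv := degeneracy >= 2L]
  g[, fam := normalizeVGene(v_gene, level = "family")]
  lenTab <- g[, list(n_groups = .N, n_convergent = sum(conv),
                     mean_degeneracy = mean(degeneracy)), by = "len"]
  setorder(lenTab, len)
  setnames(lenTab, "len", "length")
  vTab <- g[, list(v_family = fam[1L], n_groups = .N,
                   n_convergent = sum(conv)), by = "v_gene"]
  setorder(vTab, v_gene)
  famTab <- g[, list(n_groups = .N, mean_degeneracy = mean(degeneracy)),
              by = "fam"]
  setorder(famTab, fam)
  setnames(famTab, "fam", "v_family")
  list(length = as.data.frame(lenTab), v_gene = as.data.frame(vTab),
       v_family = as.data.frame(famTab))
}

#' Interior amino-acid composition at a degeneracy class
#'
#' For the groups with degeneracy exactly \code{d}, strips the first three
#' and last three CDR3 residues (these are templated by the V and J genes)
#' and pools the interior residues of all groups, counting each
#' amino-acid-level group once (unique-TCR weighting, not read-weighted).
#' Returns the proportion of each of the 20 amino acids among pooled
#' interior residues.
#'
#' @param groups a \code{\link{ConvergentGroups-class}}.
#' @param d degeneracy class (1 = non-convergent baseline).
#' @return named numeric vector of 20 proportions summing to 1, with
#'   attributes \code{"counts"} (the raw residue tallies) and
#'   \code{"total"} (pooled interior residue count). Groups whose CDR3 is
#'   shorter than 7 residues have an empty interior and are skipped
#'   (counted in attribute \code{"skipped"}); a class with zero groups
#'   returns an empty vector with a warning.
#' @examples
#' \dontrun{aaComposition(groups, d = 2)}
#' @export
aaComposition <- function(groups, d) {
  stopifnot(is(groups, "ConvergentGroups"), length(d) == 1L, d >= 1)
  g <- groups@groups
  seqs <- g$cdr3_aa[g$degeneracy == d]
  if (length(seqs) == 0L) {
    warnf("no groups with degeneracy %d", d)
    return(structure(numeric(0), counts = numeric(0), total = 0L,
                     skipped = 0L))
  }
  skip <- nchar(seqs) < 7L
  interior <- substr(seqs[!skip], 4L, nchar(seqs[!skip]) - 3L)
  letters <- unlist(strsplit(interior, "", fixed = TRUE), use.names = FALSE)
  counts <- table(factor(letters, levels = AA_ALPHABET))
  total <- sum(counts)
  props <- as.numeric(counts) / total
  structure(setNames(props, AA_ALPHABET),
            counts = setNames(as.numeric(counts), AA_ALPHABET),
            total = total, skipped = sum(skip))
}

#' Exact binomial test of amino-acid enrichment across degeneracy classes
#'
#' Two-sided exact binomial test of whether amino acid \code{aa} occurs
#' among the pooled interior residues of degeneracy class \code{d} at a
#' rate different from its baseline proportion in the non-convergent class
#' (degeneracy 1): k occurrences out of m interior residues, against
#' success probability p0 taken from the baseline composition. The
#' two-sided p-value sums the probabilities of all outcomes no more likely
#' than the observed one.
#'
#' @param groups a \code{\link{ConvergentGroups-class}}.
#' @param aa single amino-acid letter.
#' @param d degeneracy class tested (>= 2 in typical use).
#' @param baseline optional composition to use as baseline (a vector from
#'   \code{\link{aaComposition}}); defaults to the class-1 composition of
#'   \code{groups}.
#' @return list with \code{p_value}, observed count \code{k}, interior
#'   residue total \code{m}, baseline proportion \code{p0} and observed
#'   proportion \code{p_hat}.
#' @export
aaEnrichmentTest <- function(groups, aa, d, baseline = NULL) {
  stopifnot(aa %in% AA_ALPHABET)
  if (is.null(baseline)) baseline <- aaComposition(groups, 1L)
  comp <- aaComposition(groups, d)
  m <- attr(comp, "total")
  if (m == 0L) stopf("degeneracy class %d has no interior residues", d)
  p0 <- unname(baseline[aa])
  if (is.na(p0) || p0 <= 0 || p0 >= 1)
    stopf("baseline proportion for '%s' must lie strictly in (0, 1)", aa)
  k <- unname(attr(comp, "counts")[aa])
  pv <- binom.test(k, m, p = p0, alternative = "two.sided")$p.value
  list(p_value = pv, k = k, m = m, p0 = p0, p_hat = k / m)
}
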