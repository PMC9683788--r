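# Fisher's exact association between a TCR set and a label set, and the
# matched clonal-expansion comparator.

# Exact two-sided Fisher p-value over all 2x2 tables with the observed
# margins: sum the hypergeometric probabilities of the tables no more
# probable than the observed one (with a small relative tolerance against
# floating-point ties, as is conventional).
.fisherTwoSidedP <- function(a, b, c, d) {
  m1 <- a + b            # TCR-set size
  n1 <- c + d            # complement size
  k <- a + c             # label-set size
  lo <- max(0L, k - n1)
  hi <- min(k, m1)
  x <- lo:hi
  probs <- dhyper(x, m1, n1, k)
  pObs <- dhyper(a, m1, n1, k)
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Fisher's exact enrichment of a TCR set for a label set
#'
#' Builds the 2x2 contingency table of TCR-set membership against label
#' membership over the universe of unique TCR keys of one sample, and
#' tests for association with Fisher's exact test (two-sided, by
#' hypergeometric enumeration). The reported odds ratio is the sample odds
#' ratio (a*d)/(b*c); when any cell is zero, the Haldane-Anscombe
#' correction adds 0.5 to every cell and the result is flagged
#' \code{corrected}. (The conditional-MLE odds ratio some software reports
#' is deliberately not used; the p-value does not depend on the choice.)
#'
#' @param setKeys TCR keys of the tested set (e.g. the convergent set);
#'   must be a subset of \code{universeKeys}.
#' @param labelKeys TCR keys carrying the label (e.g. antigen-specific);
#'   must be a subset of \code{universeKeys}.
#' @param universeKeys all unique TCR keys of the sample (post-QC).
#' @return An \code{\link{EnrichmentResult-class}} object.
#' @examples
#' u <- sprintf("k%03d", 1:100)
#' fisherEnrichment(u[1:10], u[c(1:9, 11:21)], u)
#' @export
fisherEnrichment <- function(setKeys, labelKeys, universeKeys) {
  universeKeys <- unique(universeKeys)
  if (length(universeKeys) == 0L) stopf("the TCR universe is empty")
  setKeys <- unique(setKeys)
  labelKeys <- unique(labelKeys)
  if (!all(setKeys %in% universeKeys))
    stopf("setKeys must be a subset of universeKeys")
  if (!all(labelKeys %in% universeKeys))
    stopf("labelKeys must be a subset of universeKeys")
  inSet <- universeKeys %in% setKeys
  inLab <- universeKeys %in% labelKeys
  a <- sum(inSet & inLab)
  b <- sum(inSet & !inLab)
  c <- sum(!inSet & inLab)
  d <- sum(!inSet & !inLab)
  tab <- matrix(c(a, c, b, d), 2L, 2L,
                dimnames = list(set = c("in_set", "out_set"),
                                label = c("in_label", "out_label")))
  corrected <- any(c(a, b, c, d) == 0L)
  if (corrected) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    or <- (a * d) / (b * c)
  }
  p <- .fisherTwoSidedP(a, b, c, d)
  new("EnrichmentResult", table = tab, oddsRatio = or, pValue = p,
      log10OddsRatio = log10(or), corrected = corrected)
}

#' Select the top-k clonally expanded TCRs
#'
#' The k amino-acid-level groups with the largest total read counts. In
#' matched mode, k is set to the number of convergent TCRs of the same
#' sample, so that expansion and convergence are compared at equal set
#' size. Ties at the k-th rank are broken deterministically: higher
#' largest-single-variant count first, then lexicographic (V gene, CDR3
#' aa) order.
#'
#' @param groups a \code{\link{ConvergentGroups-class}}.
#' @param k number of keys to select; \code{k = 0} gives an empty set. If
#'   \code{k} exceeds the number of groups, all groups are returned with a
#'   warning.
#' @return character vector of exactly \code{min(k, n_groups)} TCR keys.
#' @export
selectExpanded <- function(groups, k) {
  stopifnot(is(groups, "ConvergentGroups"), length(k) == 1L, k >= 0)
  g <- groups@groups
  if (k > nrow(g)) {
    warnf("k = %d exceeds the %d available groups; returning all", k, nrow(g))
    k <- nrow(g)
  }
  if (k == 0L) return(character(0))
  ord <- order(-g$total_count, -g$max_variant_count, g$v_gene, g$cdr3_aa,
               method = "radix")
  g$key[ord[seq_len(k)]]
}

#' Convergence versus matched clonal expansion across a cohort
#'
#' For every sample: the Fisher enrichment of the convergent TCR set for
#' the sample's label set, and of the matched expanded set (top-k by read
#' count with k = number of convergent TCRs) for the same labels. Samples
#' with zero convergent TCRs cannot be matched and are excluded (listed in
#' the summary). The summary reports mean odds ratios and the mean paired
#' difference of log10 odds ratios; the paired group comparison is
#' delegated to a standard paired t-test on log10 odds ratios.
#'
#' @param groupsList named list of \code{\link{ConvergentGroups-class}}
#'   objects, one per sample.
#' @param labelsList named list (same names) of character vectors of
#'   labelled TCR keys per sample.
#' @return list with \code{per_sample} (data.frame: sample, k,
#'   or_convergence, or_expansion, p_convergence, p_expansion,
#'   log10_or_diff) and \code{summary} (means, paired t-test p-value,
#'   excluded samples).
#' @export
convergenceVsExpansion <- function(groupsList, labelsList) {
  stopifnot(length(groupsList) >= 1L,
            all(names(groupsList) %in% names(labelsList)))
  rows <- list()
  excluded <- character(0)
  for (sid in names(groupsList)) {
    grp <- groupsList[[sid]]
    universe <- grp@groups$key
    labels <- intersect(labelsList[[sid]], universe)
    conv <- convergentSet(grp)
    if (length(conv) == 0L) {
      excluded <- c(excluded, sid)
      next
    }
    expd <- selectExpanded(grp, length(conv))
    eC <- fisherEnrichment(conv, labels, universe)
    eE <- fisherEnrichment(expd, labels, universe)
    rows[[sid]] <- data.frame(
      sample = sid, k = length(conv),
      or_convergence = eC@oddsRatio, or_expansion = eE@oddsRatio,
      p_convergence = eC@pValue, p_expansion = eE@pValue,
      log10_or_diff = eC@log10OddsRatio - eE@log10OddsRatio,
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(per)) stopf("no sample had a nonempty convergent set")
  pPaired <- if (nrow(per) >= 2L)
    stats::t.test(log10(per$or_convergence), log10(per$or_expansion),
                  paired = TRUE)$p.value
  else NA_real_
  list(per_sample = per,
       summary = list(mean_or_convergence = mean(per$or_convergence),
                      mean_or_expansion = mean(per$or_expansion),
                      mean_log10_or_diff = mean(per$log10_or_diff),
                      paired_p = pPaired, excluded = excluded))
}
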