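# S4 classes for repertoire containers and analysis results.

#' CDR3 quality-control policy
#'
#' Filtering rules applied to CDR3 amino-acid sequences before any
#' convergence analysis: length within \code{[minLen, maxLen]} (inclusive),
#' first residue \code{requiredStart} (cysteine), last residue
#' \code{requiredEnd} (phenylalanine), and all characters drawn from the 20
#' standard amino acids (no \code{*}, \code{X} or \code{_}).
#'
#' @slot minLen,maxLen inclusive CDR3 amino-acid length bounds.
#' @slot requiredStart,requiredEnd single required first/last residues.
#' @export
setClass("QCPolicy",
  representation(minLen = "integer", maxLen = "integer",
                 requiredStart = "character", requiredEnd = "character"),
  prototype(minLen = 8L, maxLen = 23L, requiredStart = "C",
            requiredEnd = "F"),
  validity = function(object) {
    msg <- character()
    if (length(object@minLen) != 1L || length(object@maxLen) != 1L)
      msg <- c(msg, "minLen and maxLen must be single integers")
    else if (object@minLen > object@maxLen)
      msg <- c(msg, "minLen must be <= maxLen")
    if (nchar(object@requiredStart) != 1L || nchar(object@requiredEnd) != 1L)
      msg <- c(msg, "requiredStart/requiredEnd must be single residues")
    if (length(msg)) msg else TRUE
  })

#' @describeIn QCPolicy-class Constructor.
#' @param minLen,maxLen inclusive length bounds (defaults 8 and 23).
#' @param requiredStart,requiredEnd required first and last residues
#'   (defaults \code{"C"} and \code{"F"}).
#' @return A \code{QCPolicy} object.
#' @examples
#' qcPolicy()
#' qcPolicy(minLen = 10)
#' @export
qcPolicy <- function(minLen = 8L, maxLen = 23L, requiredStart = "C",
                     requiredEnd = "F") {
  new("QCPolicy", minLen = as.integer(minLen), maxLen = as.integer(maxLen),
      requiredStart = requiredStart, requiredEnd = requiredEnd)
}

#' Repertoire: the QC unit of one sample
#'
#' All clonotypes of one sample, aggregated to unique
#' \code{(v_gene, cdr3_nt)} keys. \code{clonotypes} is a data.frame with
#' columns \code{v_gene}, \code{j_gene}, \code{cdr3_nt}, \code{cdr3_aa},
#' \code{count}, kept in canonical \code{(v_gene, cdr3_aa, cdr3_nt)} order.
#'
#' @slot sampleId single sample identifier.
#' @slot clonotypes data.frame of aggregated nucleotide-level clonotypes.
#' @slot qcFiltered has \code{\link{filterRepertoire}} been applied?
#' @slot qcSummary list of per-rule removal counts (empty before QC).
#' @export
setClass("Repertoire",
  representation(sampleId = "character", clonotypes = "data.frame",
                 qcFiltered = "logical", qcSummary = "list"),
  prototype(sampleId = NA_character_, qcFiltered = FALSE, qcSummary = list()),
  validity = function(object) {
    msg <- character()
    need <- c("v_gene", "j_gene", "cdr3_nt", "cdr3_aa", "count")
    df <- object@clonotypes
    if (!all(need %in% names(df)))
      msg <- c(msg, paste("clonotypes must have columns:",
                          paste(need, collapse = ", ")))
    else {
      if (anyDuplicated(paste(df$v_gene, df$cdr3_nt, sep = "|")))
        msg <- c(msg, "duplicate (v_gene, cdr3_nt) clonotype keys")
      if (any(df$count < 0)) msg <- c(msg, "negative counts")
    }
    if (length(object@sampleId) != 1L)
      msg <- c(msg, "sampleId must be a single string")
    if (length(msg)) msg else TRUE
  })

#' Construct a Repertoire from a clonotype table
#'
#' Rows sharing a \code{(v_gene, cdr3_nt)} key are aggregated by summing
#' counts; rows with an empty CDR3 amino-acid sequence are dropped. Rows
#' with identical \code{(v_gene, cdr3_nt)} but conflicting \code{cdr3_aa}
#' are a hard error (they indicate data corruption, not a resolvable
#' ambiguity).
#'
#' @param sampleId sample identifier.
#' @param clonotypes data.frame with columns \code{v_gene}, \code{cdr3_nt},
#'   \code{cdr3_aa}, \code{count} (and optionally \code{j_gene}).
#' @param qcFiltered mark the repertoire as already QC-filtered (used by the
#'   simulator, whose output passes QC by construction).
#' @param qcSummary optional list of per-rule removal counts.
#' @return A \code{\link{Repertoire-class}} object.
#' @examples
#' df <- data.frame(v_gene = "TRBV19", cdr3_nt = c("TGTGCC", "TGTGCC"),
#'                  cdr3_aa = "CA", count = c(3, 2))
#' Repertoire("s1", df)
#' @export
Repertoire <- function(sampleId, clonotypes, qcFiltered = FALSE,
                       qcSummary = list()) {
  if (!"j_gene" %in% names(clonotypes))
    clonotypes$j_gene <- rep(NA_character_, nrow(clonotypes))
  dt <- as.data.table(clonotypes[, c("v_gene", "j_gene", "cdr3_nt",
                                     "cdr3_aa", "count")])
  dt <- dt[!is.na(cdr3_aa) & nzchar(cdr3_aa)]
  naa <- dt[, list(n_aa = length(unique(cdr3_aa))),
            by = c("v_gene", "cdr3_nt")]
  conflict <- which(naa$n_aa > 1L)
  if (length(conflict)) {
    stopf("conflicting cdr3_aa for identical (v_gene, cdr3_nt): %s / %s",
          naa$v_gene[conflict[1L]], naa$cdr3_nt[conflict[1L]])
  }
  agg <- dt[, list(cdr3_aa = cdr3_aa[1L], j_gene = j_gene[1L],
                   count = sum(as.numeric(count))),
            by = c("v_gene", "cdr3_nt")]
  df <- canonicalOrder(as.data.frame(agg))
  rownames(df) <- NULL
  df <- df[, c("v_gene", "j_gene", "cdr3_nt", "cdr3_aa", "count")]
  new("Repertoire", sampleId = as.character(sampleId), clonotypes = df,
      qcFiltered = qcFiltered, qcSummary = qcSummary)
}

#' Cohort: repertoires from multiple individuals
#'
#' @slot repertoires named list of \code{\link{Repertoire-class}} objects,
#'   one per individual; names are the sample identifiers.
#' @export
setClass("Cohort",
  representation(repertoires = "list"),
  validity = function(object) {
    msg <- character()
    ok <- vapply(object@repertoires, is, logical(1), "Repertoire")
    if (!all(ok)) msg <- c(msg, "all elements must be Repertoire objects")
    ids <- vapply(object@repertoires, function(r) r@sampleId, character(1))
    if (anyDuplicated(ids)) msg <- c(msg, "duplicate sample identifiers")
    if (length(msg)) msg else TRUE
  })

#' @describeIn Cohort-class Constructor from a list of repertoires.
#' @param repertoires list of \code{Repertoire} objects.
#' @return A \code{Cohort} object (named by sample id).
#' @export
Cohort <- function(repertoires) {
  ids <- vapply(repertoires, function(r) r@sampleId, character(1))
  names(repertoires) <- ids
  new("Cohort", repertoires = repertoires)
}

#' Paired single-cell TCRs
#'
#' One row per retained cell: exactly one productive beta chain, plus the
#' productive alpha chain with the highest read support when present
#' (\code{NA} otherwise). \code{dropped} records how many cells were
#' discarded for having zero or multiple productive beta chains.
#'
#' @slot cells data.frame with columns \code{barcode}, \code{beta_v},
#'   \code{beta_cdr3_nt}, \code{beta_cdr3_aa}, \code{alpha_v},
#'   \code{alpha_cdr3_nt}, \code{alpha_cdr3_aa}.
#' @slot dropped list with counts \code{no_beta} and \code{multi_beta}.
#' @export
setClass("PairedCells",
  representation(cells = "data.frame", dropped = "list"))

#' Convergent TCR groups of one sample
#'
#' Partition of a QC-filtered repertoire into amino-acid-level TCR groups.
#' Each group is one \code{(v_gene, cdr3_aa)} key (plus the alpha chain in
#' \code{paired_sc} mode); its degeneracy is the number of distinct
#' nucleotide variants observed for it within the sample. Groups with
#' degeneracy >= 2 are convergent.
#'
#' @slot sampleId sample the groups were computed in (degeneracy is never
#'   pooled across samples).
#' @slot mode \code{"bulk_beta"} or \code{"paired_sc"}.
#' @slot groups data.frame with one row per group: \code{key},
#'   \code{v_gene}, \code{cdr3_aa}, \code{degeneracy}, \code{n_variants},
#'   \code{total_count}, \code{max_variant_count} and list-column
#'   \code{variants} (the distinct nucleotide sequences).
#' @export
setClass("ConvergentGroups",
  representation(sampleId = "character", mode = "character",
                 groups = "data.frame"),
  validity = function(object) {
    msg <- character()
    need <- c("key", "v_gene", "cdr3_aa", "degeneracy", "n_variants",
              "total_count", "max_variant_count")
    if (!all(need %in% names(object@groups)))
      msg <- c(msg, paste("groups must have columns:",
                          paste(need, collapse = ", ")))
    else {
      if (any(object@groups$degeneracy < 1L))
        msg <- c(msg, "degeneracy must be >= 1")
      if (!identical(as.integer(object@groups$degeneracy),
                     as.integer(object@groups$n_variants)))
        msg <- c(msg, "degeneracy must equal the number of variants")
    }
    if (!object@mode %in% c("bulk_beta", "paired_sc"))
      msg <- c(msg, "mode must be 'bulk_beta' or 'paired_sc'")
    if (length(msg)) msg else TRUE
  })

#' Public TCR set derived from a reference cohort
#'
#' @slot keys character vector of amino-acid-level TCR keys
#'   (\code{"V|CDR3aa"}) shared by at least \code{minIndividuals} distinct
#'   individuals of the source cohort.
#' @slot nIndividuals size of the source cohort.
#' @slot threshold sharing fraction (default 0.05).
#' @slot minIndividuals \code{ceiling(threshold * nIndividuals)}.
#' @export
setClass("PublicSet",
  representation(keys = "character", nIndividuals = "integer",
                 threshold = "numeric", minIndividuals = "integer"),
  validity = function(object) {
    if (object@threshold <= 0 || object@threshold > 1)
      return("threshold must be in (0, 1]")
    if (object@minIndividuals != ceiling(object@threshold * object@nIndividuals))
      return("minIndividuals must equal ceiling(threshold * nIndividuals)")
    TRUE
  })

#' Fisher's exact enrichment of a TCR set for a label set
#'
#' @slot table 2x2 integer contingency matrix over the universe of unique
#'   TCR keys: rows = in/out of the TCR set, columns = in/out of the label
#'   set.
#' @slot oddsRatio sample odds ratio (a*d)/(b*c); when any cell is zero the
#'   Haldane-Anscombe correction (+0.5 to every cell) is applied and
#'   \code{corrected} is set.
#' @slot pValue exact two-sided p-value (hypergeometric enumeration).
#' @slot log10OddsRatio \code{log10(oddsRatio)}.
#' @slot corrected was the zero-cell continuity correction applied?
#' @export
setClass("EnrichmentResult",
  representation(table = "matrix", oddsRatio = "numeric",
                 pValue = "numeric", log10OddsRatio = "numeric",
                 corrected = "logical"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@table), c(2L, 2L)))
      msg <- c(msg, "table must be 2x2")
    if (object@pValue < 0 || object@pValue > 1)
      msg <- c(msg, "pValue must lie in [0, 1]")
    if (object@oddsRatio <= 0)
      msg <- c(msg, "oddsRatio must be positive")
    if (length(msg)) msg else TRUE
  })
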