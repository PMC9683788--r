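# CDR3 quality control applied before any convergence analysis.

#' Does a CDR3 amino-acid sequence pass quality control?
#'
#' A CDR3 passes when (1) its length lies within the inclusive bounds of
#' the policy (default 8 to 23 residues), (2) it starts with the required
#' first residue (cysteine) and ends with the required last residue
#' (phenylalanine), and (3) every character is one of the 20 standard
#' amino acids (sequences containing \code{*}, \code{X}, \code{_} or other
#' non-standard symbols fail).
#'
#' @param cdr3_aa character vector of CDR3 amino-acid sequences.
#' @param policy a \code{\link{qcPolicy}}.
#' @return logical vector, one element per input sequence.
#' @examples
#' passesQC("CASSIRSSYEQYF")  # TRUE: 13 aa, C...F
#' passesQC("CASSLGF")        # FALSE: 7 aa, below the minimum length
#' @export
passesQC <- function(cdr3_aa, policy = qcPolicy()) {
  cdr3_aa <- as.character(cdr3_aa)
  n <- nchar(cdr3_aa)
  okAlpha <- !grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"),
                    cdr3_aa) & n > 0L
  okLen <- n >= policy@minLen & n <= policy@maxLen
  okStart <- substr(cdr3_aa, 1L, 1L) == policy@requiredStart
  okEnd <- substr(cdr3_aa, n, n) == policy@requiredEnd
  okAlpha & okLen & okStart & okEnd
}

# First-failing-rule attribution, in fixed order: alphabet, length, start,
# end. Deterministic bookkeeping for the QC summary.
.qcFailRule <- function(cdr3_aa, policy) {
  n <- nchar(cdr3_aa)
  rule <- rep(NA_character_, length(cdr3_aa))
  bad <- grepl(paste0("[^", paste(AA_ALPHABET, collapse = ""), "]"),
               cdr3_aa) | n == 0L
  rule[bad] <- "alphabet_fail"
  idx <- is.na(rule) & (n < policy@minLen | n > policy@maxLen)
  rule[idx] <- "length_fail"
  idx <- is.na(rule) & substr(cdr3_aa, 1L, 1L) != policy@requiredStart
  rule[idx] <- "start_fail"
  idx <- is.na(rule) & substr(cdr3_aa, n, n) != policy@requiredEnd
  rule[idx] <- "end_fail"
  rule
}

#' Filter a repertoire by CDR3 quality control
#'
#' Removes clonotypes whose CDR3 amino-acid sequence fails
#' \code{\link{passesQC}} and recomputes the clonotype count n and total
#' reads N. The returned repertoire carries a QC summary attributing every
#' removed record to the first rule it failed, in the fixed order alphabet,
#' length, start, end, so that retained + per-rule removals always equals
#' the input count. Filtering is idempotent.
#'
#' @param rep a \code{\link{Repertoire-class}}.
#' @param policy a \code{\link{qcPolicy}}.
#' @return A QC-filtered \code{Repertoire}; \code{\link{qcSummary}} lists
#'   \code{input}, \code{retained} and per-rule removal counts.
#' @export
filterRepertoire <- function(rep, policy = qcPolicy()) {
  stopifnot(is(rep, "Repertoire"))
  df <- rep@clonotypes
  keep <- passesQC(df$cdr3_aa, policy)
  rule <- .qcFailRule(df$cdr3_aa[!keep], policy)
  summary <- list(input = nrow(df), retained = sum(keep),
                  alphabet_fail = sum(rule == "alphabet_fail"),
                  length_fail = sum(rule == "length_fail"),
                  start_fail = sum(rule == "start_fail"),
                  end_fail = sum(rule == "end_fail"))
  if (summary$retained == 0L)
    warnf("QC removed every clonotype of sample '%s'", rep@sampleId)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  new("Repertoire", sampleId = rep@sampleId, clonotypes = out,
      qcFiltered = TRUE, qcSummary = summary)
}
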