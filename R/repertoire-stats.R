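# Repertoire clonality and diversity indices.

#' TCR clonality (1 - Pielou's evenness)
#'
#' Clonality of a clone-size distribution, defined as one minus Pielou's
#' evenness:
#' \deqn{1 + \sum_i p_i \log_2 p_i / \log_2 n,}
#' where p_i is the proportional abundance of clonotype i and n the number
#' of clonotypes. 0 means a perfectly even repertoire; values near 1 mean
#' domination by a single clone. Counts may be passed instead of
#' frequencies; they are normalised internally, so clonality is invariant
#' to scaling the counts.
#'
#' @param p numeric vector of clone frequencies summing to 1 (within
#'   1e-9), or non-negative counts with \code{counts = TRUE}. Zero entries
#'   are dropped (0 log 0 := 0). At least 2 positive clonotypes are
#'   required: for n = 1 the index is singular and an error is raised.
#' @param counts interpret \code{p} as counts and normalise.
#' @return clonality in [0, 1] (clipped against floating-point drift).
#' @examples
#' clonality(rep(0.25, 4))        # 0: maximal evenness
#' clonality(c(0.999, 0.001))     # ~0.9886
#' clonality(c(50, 25, 25), counts = TRUE)
#' @export
clonality <- function(p, counts = FALSE) {
  p <- as.numeric(p)
  if (any(p < 0)) stopf("frequencies must be non-negative")
  if (counts) {
    if (sum(p) <= 0) stopf("counts must have a positive sum")
    p <- p / sum(p)
  } else if (abs(sum(p) - 1) > 1e-9) {
    stopf("frequencies must sum to 1 (got %.12g); use counts = TRUE for raw counts",
          sum(p))
  }
  p <- p[p > 0]
  n <- length(p)
  if (n < 2L)
    stopf("clonality is undefined for fewer than 2 clonotypes (n = %d)", n)
  val <- 1 + sum(p * log2(p)) / log2(n)
  min(1, max(0, val))
}

#' TCR diversity (n/N)
#'
#' Number of unique TCR clonotypes n divided by the total number of
#' sequence reads N.
#'
#' @param n clonotype count (>= 1).
#' @param N total reads (>= n).
#' @return n/N in (0, 1].
#' @examples
#' diversity(10, 100)  # 0.1
#' @export
diversity <- function(n, N) {
  if (N <= 0) stopf("diversity is undefined for N = 0")
  if (n < 1 || n > N) stopf("require 1 <= n <= N (got n = %g, N = %g)", n, N)
  n / N
}

#' One-row summary of repertoire indices
#'
#' Clonality and diversity computed from the QC-passed nucleotide-level
#' clonotypes of a repertoire (the unit the sequencer reports), plus the
#' convergence level when groups are supplied.
#'
#' @param rep a QC-filtered \code{\link{Repertoire-class}}.
#' @param groups optional \code{\link{ConvergentGroups-class}} for the same
#'   sample, to fill \code{convergence_level}.
#' @return data.frame with columns \code{sample_id}, \code{n}, \code{N},
#'   \code{clonality}, \code{diversity}, \code{convergence_level}.
#' @export
repertoireStats <- function(rep, groups = NULL) {
  stopifnot(is(rep, "Repertoire"))
  cnt <- rep@clonotypes$count
  lvl <- NA_integer_
  if (!is.null(groups)) {
    stopifnot(is(groups, "ConvergentGroups"))
    if (!identical(groups@sampleId, rep@sampleId))
      stopf("groups were computed in sample '%s', not '%s'",
            groups@sampleId, rep@sampleId)
    lvl <- convergenceLevel(groups)
  }
  data.frame(sample_id = rep@sampleId, n = length(cnt), N = sum(cnt),
             clonality = if (length(cnt) >= 2L) clonality(cnt, counts = TRUE)
                         else NA_real_,
             diversity = diversity(length(cnt), sum(cnt)),
             convergence_level = lvl, stringsAsFactors = FALSE)
}
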