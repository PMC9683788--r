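# Public TCR derivation and the public fraction of convergent TCRs.

#' Derive the public TCR set of a cohort
#'
#' A TCR key (V gene + CDR3 amino-acid sequence) is public when it is
#' present (any count >= 1, post-QC) in at least
#' \code{ceiling(threshold * N)} of the cohort's N individuals. The
#' ceiling convention reproduces the reference pairing of a 5\% threshold
#' with a minimum of 34 individuals in a 666-sample cohort. Presence is at
#' the amino-acid key level: read counts play no role.
#'
#' @param cohort a \code{\link{Cohort-class}} with one repertoire per
#'   individual (>= 2 individuals). Repertoires should be QC-filtered.
#' @param threshold sharing fraction in (0, 1]; default 0.05.
#' @return A \code{\link{PublicSet-class}} object.
#' @examples
#' publicMinIndividuals(666, 0.05)  # 34
#' @export
derivePublicSet <- function(cohort, threshold = 0.05) {
  stopifnot(is(cohort, "Cohort"))
  if (threshold <= 0 || threshold > 1)
    stopf("threshold must lie in (0, 1], got %g", threshold)
  reps <- cohort@repertoires
  if (length(reps) < 2L) stopf("a cohort needs at least 2 individuals")
  nInd <- length(reps)
  minInd <- publicMinIndividuals(nInd, threshold)
  perInd <- lapply(reps, function(r) {
    df <- r@clonotypes
    unique(tcrKey(df$v_gene, df$cdr3_aa))
  })
  tab <- table(unlist(perInd, use.names = FALSE))
  keys <- sort(names(tab)[tab >= minInd])
  new("PublicSet", keys = keys, nIndividuals = nInd,
      threshold = threshold, minIndividuals = minInd)
}

#' @rdname derivePublicSet
#' @param nIndividuals cohort size.
#' @return \code{publicMinIndividuals}: the minimum number of individuals
#'   a key must appear in, \code{ceiling(threshold * nIndividuals)}.
#' @export
publicMinIndividuals <- function(nIndividuals, threshold = 0.05) {
  if (threshold <= 0 || threshold > 1)
    stopf("threshold must lie in (0, 1], got %g", threshold)
  as.integer(ceiling(threshold * nIndividuals))
}

#' Public fraction of a sample's convergent TCRs
#'
#' The convergence-publicity overlap divided by the number of convergent
#' TCRs: |convergent intersect public| / |convergent|.
#'
#' @param convergentKeys character vector of convergent TCR keys (from
#'   \code{\link{convergentSet}}); must be nonempty.
#' @param publicSet a \code{\link{PublicSet-class}} (or character vector of
#'   public keys).
#' @return fraction in [0, 1].
#' @export
publicFraction <- function(convergentKeys, publicSet) {
  if (length(convergentKeys) == 0L)
    stopf("the convergent set is empty: the public fraction is undefined")
  keys <- if (is(publicSet, "PublicSet")) publicSet@keys else
    as.character(publicSet)
  length(intersect(unique(convergentKeys), keys)) /
    length(unique(convergentKeys))
}
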