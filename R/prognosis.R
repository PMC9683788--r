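# Convergence-level stratification and survival-analysis table assembly.
# Kaplan-Meier / log-rank / Cox fitting is delegated to the survival
# package; the bespoke content is the stratifying statistic.

#' Stratify samples by the cohort median convergence level
#'
#' Samples with a convergence level above the cohort median are labelled
#' \code{"high"}, below the median \code{"low"}. The median uses the
#' midpoint convention for even cohort sizes. Samples exactly at the
#' median are assigned \code{"high"} and flagged in the tie report (the
#' high/low wording leaves ties undefined; a deterministic, visible rule
#' is used rather than dropping samples). If all levels are identical the
#' stratification is refused.
#'
#' @param levels named integer/numeric vector of per-sample convergence
#'   levels (>= 2 samples).
#' @return list with \code{group} (named character vector, \code{"high"} /
#'   \code{"low"}), \code{median}, and \code{ties} (names of samples at
#'   the median).
#' @examples
#' stratifyByMedian(c(a = 1, b = 2, c = 3, d = 4))$group
#' @export
stratifyByMedian <- function(levels) {
  if (length(levels) < 2L) stopf("need at least 2 samples to stratify")
  if (is.null(names(levels)))
    names(levels) <- sprintf("sample%03d", seq_along(levels))
  if (length(unique(levels)) == 1L)
    stopf("all convergence levels are identical (%g); stratification is undefined",
          levels[1L])
  med <- median(levels)
  group <- ifelse(levels > med, "high", ifelse(levels < med, "low", "high"))
  ties <- names(levels)[levels == med]
  list(group = setNames(group, names(levels)), median = med, ties = ties)
}

#' Assemble the survival-analysis table
#'
#' Joins per-sample repertoire summaries to a clinical table and attaches
#' the high/low convergence stratification plus exactly the four
#' covariates of the multivariate model: TCR clonality, TCR diversity,
#' treatment, and sequencing depth (the total number of detected TCR
#' clonotypes). Unmatched sample ids abort the run unless
#' \code{allowPartial} is set.
#'
#' @param summaries data.frame with columns \code{sample_id},
#'   \code{convergence_level}, \code{clonality}, \code{diversity},
#'   \code{total_clonotypes}, \code{treatment} (treatment may instead come
#'   from the clinical table).
#' @param clinical data.frame with columns \code{sample_id}, \code{time},
#'   \code{event} (days and 0/1 event flag); a \code{treatment} column is
#'   used when the summaries lack one.
#' @param allowPartial keep only matched samples instead of aborting on
#'   unmatched ids.
#' @return data.frame with columns \code{sample_id}, \code{group_label},
#'   \code{convergence_level}, \code{clonality}, \code{diversity},
#'   \code{total_clonotypes}, \code{treatment}, \code{time}, \code{event};
#'   the stratification tie report is attached as attribute \code{"ties"}.
#' @export
buildSurvivalTable <- function(summaries, clinical, allowPartial = FALSE) {
  need <- c("sample_id", "convergence_level", "clonality", "diversity",
            "total_clonotypes")
  miss <- setdiff(need, names(summaries))
  if (length(miss))
    stopf("summaries are missing column(s): %s", paste(miss, collapse = ", "))
  needC <- c("sample_id", "time", "event")
  missC <- setdiff(needC, names(clinical))
  if (length(missC))
    stopf("clinical table is missing column(s): %s",
          paste(missC, collapse = ", "))
  unmatched <- c(setdiff(summaries$sample_id, clinical$sample_id),
                 setdiff(clinical$sample_id, summaries$sample_id))
  if (length(unmatched) && !allowPartial)
    stopf("unmatched sample id(s): %s (use allowPartial to keep the intersection)",
          paste(unmatched, collapse = ", "))
  ids <- intersect(summaries$sample_id, clinical$sample_id)
  if (length(ids) < 2L) stopf("fewer than 2 matched samples")
  s <- summaries[match(ids, summaries$sample_id), , drop = FALSE]
  cl <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
  strat <- stratifyByMedian(setNames(s$convergence_level, ids))
  treatment <- if ("treatment" %in% names(s)) s$treatment
               else if ("treatment" %in% names(cl)) cl$treatment
               else stopf("neither table has a 'treatment' column")
  out <- data.frame(sample_id = ids,
                    group_label = unname(strat$group[ids]),
                    convergence_level = s$convergence_level,
                    clonality = s$clonality,
                    diversity = s$diversity,
                    total_clonotypes = s$total_clonotypes,
                    treatment = treatment,
                    time = cl$time, event = cl$event,
                    stringsAsFactors = FALSE)
  attr(out, "ties") <- strat$ties
  out
}

#' Fit the delegated survival models
#'
#' Thin wrapper handing the assembled table to the survival package:
#' Kaplan-Meier curves per convergence group, the log-rank test, a
#' univariate Cox model on the group label, and the multivariate Cox model
#' adjusting for clonality, diversity, treatment and sequencing depth. The
#' fitted objects are returned unmodified.
#'
#' @param tab a table from \code{\link{buildSurvivalTable}}.
#' @return list with \code{km} (survfit), \code{logrank} (survdiff),
#'   \code{logrank_p}, \code{cox} (univariate coxph) and \code{cox_multi}
#'   (multivariate coxph).
#' @export
fitSurvival <- function(tab) {
  tab$group_label <- factor(tab$group_label, levels = c("low", "high"))
  km <- survfit(Surv(time, event) ~ group_label, data = tab)
  lr <- survdiff(Surv(time, event) ~ group_label, data = tab)
  lrP <- stats::pchisq(lr$chisq, df = length(lr$n) - 1L, lower.tail = FALSE)
  cox <- coxph(Surv(time, event) ~ group_label, data = tab)
  coxM <- coxph(Surv(time, event) ~ group_label + clonality + diversity +
                  treatment + total_clonotypes, data = tab)
  list(km = km, logrank = lr, logrank_p = lrP, cox = cox, cox_multi = coxM)
}
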