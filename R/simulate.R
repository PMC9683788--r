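# Seed-deterministic synthetic repertoires with planted ground truth:
# degeneracy spectra (by construction, not sampling), skewed clone sizes,
# antigen-specific labels with a controlled odds multiplier for convergent
# groups, and cross-individual sharing for cohort/publicity tests.

# Synonymous codon sets of the standard genetic code (stop codons removed).
.codonSets <- local({
  sets <- NULL
  function() {
    if (is.null(sets)) {
      gc <- GENETIC_CODE
      gc <- gc[gc != "*"]
      sets <<- split(names(gc), unname(gc))
    }
    sets
  }
})

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic repertoire
#' generator. The defaults emulate the structure of real bulk TCR-beta
#' repertoires: about 5.4\% of amino-acid-level TCR groups are convergent,
#' and among convergent groups 90.65\% have degeneracy 2, 7.16\% degeneracy
#' 3, and the remainder degeneracy 4 (a roughly 10-fold decay per unit of
#' degeneracy); clone sizes follow a discrete power law with tail exponent
#' 2.5; CDR3 lengths follow a discretised normal (mean 14.5, sd 2) on
#' [8, 23]; interior amino-acid weights are qualitatively skewed toward
#' serine, tyrosine and glutamic acid.
#'
#' @param seed integer seed; every draw of the generator flows from it.
#' @param nGroups number of amino-acid-level TCR groups.
#' @param spectrum named integer vector mapping degeneracy d to the number
#'   of groups with exactly d nucleotide variants (names are d values);
#'   must sum to \code{nGroups}. Default: \code{defaultSpectrum(nGroups)}.
#' @param cloneSizeExponent power-law tail exponent of per-variant read
#'   counts (> 1).
#' @param cloneSizeMin minimum per-variant read count.
#' @param lengthProbs named probability vector over CDR3 amino-acid lengths
#'   (support within [8, 23]).
#' @param interiorFreqs named non-negative weights over the 20 amino acids
#'   for interior CDR3 residues (normalised internally).
#' @param codonUsage optional named list: per amino acid, weights over its
#'   synonymous codons (default uniform).
#' @param specificFraction probability that a non-convergent group carries
#'   the antigen-specific label.
#' @param specificOddsMultiplier odds multiplier for convergent groups
#'   being labelled specific; 1 means labels are independent of
#'   convergence, and the expected enrichment odds ratio equals the
#'   multiplier by construction.
#' @param nIndividuals,sharingProbability cohort block (for
#'   \code{\link{simulateCohort}}): number of individuals (>= 2) and the
#'   i.i.d. probability that a group is present in any given individual.
#' @return a validated configuration (classed list).
#' @examples
#' cfg <- simulationConfig(seed = 1, nGroups = 1000)
#' sum(cfg$spectrum)  # 1000
#' @export
simulationConfig <- function(seed, nGroups = 10000L,
                             spectrum = defaultSpectrum(nGroups),
                             cloneSizeExponent = 2.5, cloneSizeMin = 1L,
                             lengthProbs = defaultLengthProbs(),
                             interiorFreqs = defaultInteriorFreqs(),
                             codonUsage = NULL,
                             specificFraction = 0.1,
                             specificOddsMultiplier = 1,
                             nIndividuals = NULL,
                             sharingProbability = NULL) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  spectrum <- spectrum[spectrum > 0]
  d <- as.integer(names(spectrum))
  if (any(is.na(d)) || any(d < 1L))
    stopf("spectrum names must be degeneracies >= 1")
  if (sum(spectrum) != nGroups)
    stopf("spectrum counts must sum to nGroups (%d != %d)",
          sum(spectrum), nGroups)
  if (cloneSizeExponent <= 1) stopf("cloneSizeExponent must exceed 1")
  lens <- as.integer(names(lengthProbs))
  if (any(lens < 8L) || any(lens > 23L))
    stopf("lengthProbs support must lie within [8, 23]")
  if (abs(sum(lengthProbs) - 1) > 1e-9)
    stopf("lengthProbs must sum to 1")
  if (!all(AA_ALPHABET %in% names(interiorFreqs)))
    stopf("interiorFreqs must name all 20 amino acids")
  if (specificFraction < 0 || specificFraction >= 1)
    stopf("specificFraction must lie in [0, 1)")
  if (specificOddsMultiplier <= 0) stopf("specificOddsMultiplier must be > 0")
  if (!is.null(nIndividuals)) {
    if (nIndividuals < 2L) stopf("a cohort needs at least 2 individuals")
    if (is.null(sharingProbability) || sharingProbability < 0 ||
        sharingProbability > 1)
      stopf("sharingProbability must lie in [0, 1]")
  }
  structure(list(seed = as.integer(seed), nGroups = as.integer(nGroups),
                 spectrum = spectrum,
                 cloneSizeExponent = cloneSizeExponent,
                 cloneSizeMin = as.integer(cloneSizeMin),
                 lengthProbs = lengthProbs,
                 interiorFreqs = interiorFreqs[AA_ALPHABET] /
                   sum(interiorFreqs[AA_ALPHABET]),
                 codonUsage = codonUsage,
                 specificFraction = specificFraction,
                 specificOddsMultiplier = specificOddsMultiplier,
                 nIndividuals = nIndividuals,
                 sharingProbability = sharingProbability),
            class = "tcr_sim_config")
}

#' @rdname simulationConfig
#' @param convergentFraction fraction of groups that are convergent
#'   (default 0.054); split across degeneracies 2/3/4 as 90.65\% / 7.16\% /
#'   remainder.
#' @return \code{defaultSpectrum}: named integer vector (degeneracy ->
#'   group count) summing to \code{nGroups}.
#' @export
defaultSpectrum <- function(nGroups, convergentFraction = 0.054) {
  nConv <- round(nGroups * convergentFraction)
  d2 <- round(nConv * 0.9065)
  d3 <- round(nConv * 0.0716)
  d4 <- nConv - d2 - d3
  out <- c("1" = nGroups - nConv, "2" = d2, "3" = d3, "4" = d4)
  out[out > 0]
}

#' @rdname simulationConfig
#' @export
defaultLengthProbs <- function() {
  x <- 8:23
  p <- dnorm(x, mean = 14.5, sd = 2)
  setNames(p / sum(p), x)
}

#' @rdname simulationConfig
#' @export
defaultInteriorFreqs <- function() {
  w <- setNames(rep(1, 20), AA_ALPHABET)
  w["S"] <- 3; w["Y"] <- 2.5; w["E"] <- 2
  w["G"] <- 1.5; w["L"] <- 1.5; w["R"] <- 0.8
  w
}

# One nucleotide encoding of an amino-acid string, sampled codon by codon.
.sampleEncoding <- function(aaChars, codonSets, codonUsage) {
  codons <- vapply(aaChars, function(ch) {
    set <- codonSets[[ch]]
    if (is.null(codonUsage) || is.null(codonUsage[[ch]]))
      set[sample.int(length(set), 1L)]
    else sample(set, 1L, prob = codonUsage[[ch]])
  }, character(1), USE.NAMES = FALSE)
  paste(codons, collapse = "")
}

# Number of distinct encodings of an amino-acid string.
.nEncodings <- function(aaChars, codonSets) {
  prod(vapply(aaChars, function(ch) length(codonSets[[ch]]), numeric(1)))
}

# Discrete power-law clone sizes (Pareto tail, floored).
.drawCloneSizes <- function(n, minCount, exponent) {
  u <- runif(n)
  pmax(minCount, floor(minCount * u^(-1 / (exponent - 1))))
}

# Draw the amino-acid-level groups (keys, degeneracies, labels). Shared by
# the single-sample and cohort generators.
.drawGroups <- function(config) {
  spec <- config$spectrum
  degs <- rep(as.integer(names(spec)), times = spec)
  n <- length(degs)
  vPool <- sprintf("TRBV%d", 1:30)
  lens <- as.integer(names(config$lengthProbs))
  repeat {
    L <- sample(lens, n, replace = TRUE, prob = config$lengthProbs)
    vg <- sample(vPool, n, replace = TRUE)
    interior <- vapply(L, function(l)
      paste(sample(AA_ALPHABET, l - 2L, replace = TRUE,
                   prob = config$interiorFreqs), collapse = ""),
      character(1))
    aa <- paste0("C", interior, "F")
    if (!anyDuplicated(paste(vg, aa))) break
  }
  q <- config$specificFraction
  m <- config$specificOddsMultiplier
  odds <- q / (1 - q)
  pConv <- (m * odds) / (1 + m * odds)
  specific <- ifelse(degs >= 2L,
                     runif(n) < pConv,
                     runif(n) < q)
  data.frame(key = tcrKey(vg, aa), v_gene = vg, cdr3_aa = aa,
             degeneracy = degs, specific = specific,
             stringsAsFactors = FALSE)
}

# Back-translate one group into exactly d distinct nucleotide variants.
# Duplicate draws are rejected (bounded retries); a CDR3 with fewer than d
# encodings triggers a redraw of the interior residues.
.drawVariants <- function(aa, d, config, codonSets, maxRetries = 100L) {
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  if (.nEncodings(chars, codonSets) < d) return(NULL)
  variants <- character(0)
  tries <- 0L
  while (length(variants) < d) {
    nt <- .sampleEncoding(chars, codonSets, config$codonUsage)
    if (nt %in% variants) {
      tries <- tries + 1L
      if (tries > maxRetries) return(NULL)
    } else {
      variants <- c(variants, nt)
    }
  }
  variants
}

# Nucleotide-level realisation of a group table: variants + clone sizes.
.realiseClonotypes <- function(groups, config, codonSets) {
  n <- nrow(groups)
  vlist <- vector("list", n)
  aa <- groups$cdr3_aa
  deg <- groups$degeneracy
  for (i in seq_len(n)) {
    v <- .drawVariants(aa[i], deg[i], config, codonSets)
    attempts <- 0L
    while (is.null(v)) {
      # redraw the interior: low-degeneracy residues can exhaust encodings
      attempts <- attempts + 1L
      if (attempts > 50L)
        stopf("cannot realise %d distinct encodings of a length-%d CDR3",
              deg[i], nchar(aa[i]))
      L <- nchar(aa[i])
      interior <- paste(sample(AA_ALPHABET, L - 2L, replace = TRUE,
                               prob = config$interiorFreqs), collapse = "")
      aa[i] <- paste0("C", interior, "F")
      v <- .drawVariants(aa[i], deg[i], config, codonSets)
    }
    vlist[[i]] <- v
  }
  groups$cdr3_aa <- aa
  groups$key <- tcrKey(groups$v_gene, groups$cdr3_aa)
  counts <- .drawCloneSizes(sum(deg), config$cloneSizeMin,
                            config$cloneSizeExponent)
  df <- data.frame(
    v_gene = rep(groups$v_gene, times = deg),
    cdr3_nt = unlist(vlist, use.names = FALSE),
    cdr3_aa = rep(groups$cdr3_aa, times = deg),
    count = counts, stringsAsFactors = FALSE)
  idx <- factor(rep(seq_len(n), times = deg), levels = seq_len(n))
  groups$total_count <- as.numeric(tapply(counts, idx, sum))
  list(clonotypes = df, groups = groups)
}

#' Simulate one repertoire with planted ground truth
#'
#' Generates a bulk TCR-beta repertoire realising the configured degeneracy
#' spectrum exactly: every amino-acid-level group receives precisely its
#' planted number of distinct nucleotide variants (drawn by
#' back-translation through the configured codon usage, rejecting
#' duplicates), every variant translates to the group's CDR3 under the
#' standard genetic code, and every CDR3 passes quality control by
#' construction (C...F, length in [8, 23]). Per-variant read counts follow
#' the configured power law; antigen-specific labels are Bernoulli with
#' odds multiplied by \code{specificOddsMultiplier} for convergent groups.
#' Output is fully reproducible from the seed.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param sampleId sample identifier for the emitted repertoire.
#' @param dir optional output directory; when given, the repertoire is
#'   written as an immunoSEQ-dialect TSV (\code{<sampleId>.tsv}) and the
#'   truth table as \code{<sampleId>_truth.tsv}.
#' @return list with \code{repertoire} (a \code{\link{Repertoire-class}}),
#'   \code{truth} (data.frame: key, v_gene, cdr3_aa, degeneracy, specific,
#'   total_count) and, when \code{dir} is given, the file \code{paths}.
#' @examples
#' sim <- simulateRepertoire(simulationConfig(seed = 7, nGroups = 200))
#' table(sim$truth$degeneracy)
#' @export
simulateRepertoire <- function(config, sampleId = "sim", dir = NULL) {
  stopifnot(inherits(config, "tcr_sim_config"))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  codonSets <- .codonSets()
  groups <- .drawGroups(config)
  real <- .realiseClonotypes(groups, config, codonSets)
  rep <- Repertoire(sampleId, real$clonotypes)
  truth <- real$groups[order(real$groups$key, method = "radix"), ,
                       drop = FALSE]
  rownames(truth) <- NULL
  out <- list(repertoire = rep, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    repPath <- file.path(dir, paste0(sampleId, ".tsv"))
    truthPath <- file.path(dir, paste0(sampleId, "_truth.tsv"))
    writeReportTSV(rep, repPath)
    .writeTSV(truth, truthPath)
    out$paths <- c(repertoire = repPath, truth = truthPath)
  }
  out
}

#' Simulate a multi-individual cohort with controlled TCR sharing
#'
#' Draws one master list of amino-acid-level groups, then assigns each
#' group to each individual independently with probability
#' \code{sharingProbability}. Shared groups share the amino-acid key
#' across individuals, but nucleotide variants and clone sizes are drawn
#' independently per individual (sharing is an amino-acid-level property;
#' convergence remains per-sample). The truth table records how many
#' individuals carry each group.
#'
#' @param config a \code{\link{simulationConfig}} with the cohort block set
#'   (\code{nIndividuals}, \code{sharingProbability}).
#' @param dir optional output directory for per-individual immunoSEQ TSVs
#'   and the cohort truth table.
#' @return list with \code{cohort} (a \code{\link{Cohort-class}}) and
#'   \code{truth} (data.frame with per-group \code{sharing_count} and the
#'   per-individual presence matrix as attribute \code{"presence"}).
#' @export
simulateCohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "tcr_sim_config"))
  if (is.null(config$nIndividuals))
    stopf("config has no cohort block (nIndividuals, sharingProbability)")
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  codonSets <- .codonSets()
  master <- .drawGroups(config)
  nInd <- config$nIndividuals
  present <- matrix(runif(nrow(master) * nInd) < config$sharingProbability,
                    nrow = nrow(master), ncol = nInd)
  reps <- vector("list", nInd)
  for (i in seq_len(nInd)) {
    sub <- master[present[, i], , drop = FALSE]
    sid <- sprintf("ind%03d", i)
    if (nrow(sub) == 0L) {
      reps[[i]] <- Repertoire(sid, data.frame(
        v_gene = character(), cdr3_nt = character(),
        cdr3_aa = character(), count = numeric(),
        stringsAsFactors = FALSE))
      next
    }
    real <- .realiseClonotypes(sub, config, codonSets)
    reps[[i]] <- Repertoire(sid, real$clonotypes)
  }
  truth <- master
  truth$sharing_count <- as.integer(rowSums(present))
  ord <- order(truth$key, method = "radix")
  truth <- truth[ord, , drop = FALSE]
  rownames(truth) <- NULL
  attr(truth, "presence") <- present[ord, , drop = FALSE]
  cohort <- Cohort(reps)
  out <- list(cohort = cohort, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- vapply(reps, function(r) {
      p <- file.path(dir, paste0(r@sampleId, ".tsv"))
      writeReportTSV(r, p)
      p
    }, character(1))
    truthPath <- file.path(dir, "cohort_truth.tsv")
    .writeTSV(truth[, setdiff(names(truth), "presence")], truthPath)
    out$paths <- c(paths, truth = truthPath)
  }
  out
}

#' Expected enrichment odds ratio of a simulation configuration
#'
#' Closed-form expected 2x2 contingency proportions implied by the
#' generator's Bernoulli label model. Convergent groups are labelled
#' specific with odds \code{specificOddsMultiplier} times the baseline
#' odds, so the expected odds ratio equals the multiplier by construction;
#' used as the target in parameter-recovery tests.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{expected_or}, the convergent-group fraction
#'   \code{p_convergent}, the two label probabilities \code{p_specific_conv}
#'   and \code{p_specific_nonconv}, and the expected cell proportions
#'   \code{cells} (a, b, c, d).
#' @export
expectedEnrichment <- function(config) {
  stopifnot(inherits(config, "tcr_sim_config"))
  spec <- config$spectrum
  d <- as.integer(names(spec))
  pConv <- sum(spec[d >= 2L]) / config$nGroups
  q <- config$specificFraction
  m <- config$specificOddsMultiplier
  pC <- (m * q / (1 - q)) / (1 + m * q / (1 - q))
  cells <- c(a = pConv * pC, b = pConv * (1 - pC),
             c = (1 - pConv) * q, d = (1 - pConv) * (1 - q))
  list(expected_or = m, p_convergent = pConv, p_specific_conv = pC,
       p_specific_nonconv = q, cells = cells)
}

#' Simulate a survival cohort stratified by convergence level
#'
#' Generates per-sample convergence levels (Poisson), stratifies them at
#' the cohort median, and draws exponential survival times whose hazard in
#' the high-convergence group is \code{hazardRatio} times the baseline,
#' with administrative censoring. Neutral covariates (clonality,
#' diversity, sequencing depth, treatment) are included so that the
#' multivariate model of \code{\link{buildSurvivalTable}} can be exercised
#' with known ground truth.
#'
#' @param nSamples cohort size.
#' @param hazardRatio true hazard ratio of the high-convergence group
#'   relative to low (< 1 means high convergence is protective).
#' @param baselineHazard daily hazard of the low-convergence group.
#' @param censorTime administrative censoring time in days.
#' @param levelMean mean of the Poisson convergence levels.
#' @param seed integer seed.
#' @return data.frame with columns \code{sample_id},
#'   \code{convergence_level}, \code{clonality}, \code{diversity},
#'   \code{total_clonotypes}, \code{treatment}, \code{os_days},
#'   \code{os_event}.
#' @export
simulateSurvivalCohort <- function(nSamples = 60L, hazardRatio = 0.3,
                                   baselineHazard = 1 / 150,
                                   censorTime = 720, levelMean = 30,
                                   seed = 1L) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  lvl <- stats::rpois(nSamples, levelMean)
  grp <- stratifyByMedian(setNames(lvl, sprintf("s%03d", seq_len(nSamples))))
  high <- grp$group == "high"
  rate <- baselineHazard * ifelse(high, hazardRatio, 1)
  t <- stats::rexp(nSamples, rate = rate)
  event <- as.integer(t <= censorTime)
  data.frame(sample_id = names(grp$group),
             convergence_level = lvl,
             clonality = pmin(pmax(rnorm(nSamples, 0.2, 0.05), 0.01), 0.9),
             diversity = pmin(pmax(rnorm(nSamples, 0.3, 0.08), 0.01), 1),
             total_clonotypes = stats::rpois(nSamples, 5000),
             treatment = sample(c("mono", "combo"), nSamples, replace = TRUE),
             os_days = pmin(t, censorTime),
             os_event = event,
             stringsAsFactors = FALSE)
}
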