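---
title: "Detecting and validating TCR convergence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and validating TCR convergence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TCRconvergence)
```

## The statistic

A T cell clonotype is a unique V(D)J rearrangement, identified at the
nucleotide level by its CDR3 sequence and V gene. Because the genetic code
is degenerate, several distinct nucleotide rearrangements can encode the
same CDR3 amino-acid sequence. When that happens within one sample — two
or more clonotypes with the identical CDR3 amino-acid sequence and V gene
but different CDR3 nucleotide sequences — the amino-acid-level TCR is
*convergent*. Convergence is interesting because independent recombination
events landing on the same protein suggest antigen-driven selection of
that receptor, a stronger signal than clonal expansion of a single
rearrangement.

The package's core quantity is the *degeneracy* of an amino-acid-level
TCR: the number of distinct CDR3 nucleotide sequences encoding it within
a sample. Degeneracy 1 is non-convergent; degeneracy >= 2 is convergent.
The *convergence level* of a sample is its number of convergent TCRs.

Three deliberate scope decisions shape the grouping:

* **Degeneracy is per-sample.** Pooling samples before grouping would mix
  convergence (within-individual) with publicity (between-individual),
  which are distinct phenomena with distinct modules here.
* **The key is V gene + CDR3 amino acids** (plus the paired alpha chain
  for single-cell data). The J gene is not part of the key; an
  `includeJ` flag exists for sensitivity analyses.
* **No fuzzy clustering.** Similarity-based grouping (one-mismatch
  clusters and the like) is a different method answering a different
  question; convergence requires identity.

V-gene names are normalised by stripping allele suffixes (`TRBV19*01` and
`TRBV19*02` group together) because repertoire exports differ in allele
resolution; grouping at family level is available but not the default.

## Quality control

Before grouping, CDR3 amino-acid sequences are filtered to those between
8 and 23 residues long (inclusive), starting with cysteine, ending with
phenylalanine, and containing only the 20 standard amino acids. The
alphabet rule exists because out-of-frame and ambiguous reads appear in
real exports as `*`, `X` or `_`; such records cannot carry a convergence
signal. A record failing several rules is attributed to the first failing
rule in the fixed order alphabet, length, start, end, so the QC summary
always conserves the input count; filtering is idempotent. The inclusive
reading of the length bounds is pinned by boundary tests (8 and 23 pass,
7 and 24 fail).

## Composition and enrichment statistics

For the amino-acid composition of a degeneracy class, the first and last
three CDR3 residues are stripped — they are templated by the V and J
genes, not by junctional diversity — and the interior residues of all
groups in the class are pooled, each group counted once (unique-TCR
weighting). We chose pooled-residue proportions rather than per-group
means: pooling weights every interior residue equally and makes the exact
binomial test well-defined (k occurrences out of m pooled residues
against the degeneracy-1 baseline proportion). Differences between
classes are tested with the two-sided exact binomial test
(`stats::binom.test`, summing outcome probabilities no larger than the
observed one). QC guarantees length >= 8, so the stripped interior is
never empty.

Association between a TCR set (convergent, or top-k expanded) and a label
set (antigen-specific TCRs, cluster membership) is measured over the
universe of a sample's unique post-QC amino-acid keys with Fisher's exact
test. The p-value is the exact two-sided hypergeometric enumeration (sum
of table probabilities no larger than the observed table's, with the
conventional 1e-7 relative tie tolerance). The reported effect size is
the sample odds ratio (a d)/(b c); when any cell is zero the
Haldane-Anscombe correction adds 0.5 to every cell and flags the result.
We use the sample odds ratio, not the conditional maximum-likelihood
estimate, because it is closed-form, reproducible without iterative
fitting, and the p-value — which carries the inference — is identical
either way. Tests pin both the estimator and the correction, and verify
the p-value against an independent `choose()`-based enumeration oracle
and against `fisher.test`.

The matched expansion comparator selects the k amino-acid groups with the
largest total read counts, with k equal to the sample's number of
convergent TCRs, so convergence and expansion are compared at equal set
size. Ties at the k-th rank are broken deterministically (larger single
largest variant count, then lexicographic key order); random tie-breaking
would make runs irreproducible.

Label matching defaults to the full V gene + CDR3 key, consistent with
the convergence key; a CDR3-only mode can be had by building label keys
accordingly. Publicity uses the same key, which makes the
convergence-publicity overlap well-defined.

## Publicity

A TCR is public when it appears in at least `ceiling(threshold * N)` of
the N individuals of a reference cohort (default threshold 0.05).
The ceiling convention is forced by the reference pairing of 5% with a
minimum of 34 individuals out of 666 (0.05 x 666 = 33.3, and 33 would
correspond to "at least 4.95%"). Presence is amino-acid-level and
count-free; the public fraction of a sample's convergent TCRs is the
overlap divided by the convergent count, and is undefined (an error, not
zero) when the sample has no convergent TCRs.

## Repertoire indices

Clonality is one minus Pielou's evenness,
`1 + sum(p_i log2 p_i) / log2 n`, computed over QC-passed
nucleotide-level clonotype frequencies — the unit the sequencer reports —
not amino-acid groups. It is 0 for a perfectly even repertoire and
approaches 1 under domination by one clone; the implementation clips tiny
negative drift to [0, 1]. For n = 1 the formula is singular (log2 1 = 0)
and the function raises an error rather than returning a silent default
that would bias cohort summaries. Diversity is n/N, unique clonotypes
over total reads. "Reads" here means template/read counts as exported;
no further normalisation is applied.

## The synthetic repertoire generator

Real repertoire data for this analysis live behind controlled-access
archives, so validation rests on a generator whose ground truth is exact.
The generator works top-down by *back-translation*: it draws each
amino-acid-level group (CDR3 starting with C, ending with F, interior
residues from a configurable frequency vector, length from a distribution
on [8, 23]), then back-translates it through configurable codon usage
exactly d times with duplicate rejection, guaranteeing the planted
degeneracy spectrum *by construction*, not in expectation. Forward V(D)J
recombination simulation could not guarantee a spectrum and is a
non-goal. Duplicate rejection is bounded (100 retries), after which the
interior is redrawn — short CDR3s rich in single-codon residues
(methionine, tryptophan) can exhaust their encodings.

Defaults are chosen to emulate the structure of real bulk TCR-beta
repertoires and are not tuned per analysis:

* 5.4% of groups convergent, split 90.65% / 7.16% / remainder across
  degeneracies 2 / 3 / 4 — the roughly 10-fold decay per degeneracy unit
  seen in healthy-donor blood repertoires;
* per-variant read counts from a discrete Pareto with tail exponent 2.5,
  the middle of the power-law range reported for clone-size
  distributions;
* CDR3 lengths from a discretised normal (mean 14.5, sd 2) on [8, 23];
* interior amino-acid weights qualitatively skewed toward serine,
  tyrosine and glutamate, echoing the polar/acidic preference of
  convergent TCRs, with no claim of quantitative realism;
* baseline antigen-specific label probability 0.1 for non-convergent
  groups.

Antigen-specific labels are Bernoulli: a non-convergent group is specific
with probability q, a convergent group with odds m times the baseline
odds, so the expected enrichment odds ratio equals the configured
multiplier m exactly (`expectedEnrichment()` returns the closed form).
Cohorts assign every group to every individual i.i.d. with a sharing
probability; shared groups share the amino-acid key while nucleotide
variants are re-drawn per individual, because sharing is an
amino-acid-level property and convergence must remain per-sample.

What the generator does **not** emulate: germline segment usage and
recombination statistics, thymic selection, sequencing error (a real
confounder of convergence estimates — errors convert one true clonotype
into several apparent ones), PCR amplification bias, and correlation
between clone size and specificity. Passing the planted-truth tests
therefore shows the detection and enrichment machinery is correct, not
that real repertoires will show any particular effect size.

## Survival stratification

Samples are stratified at the cohort median convergence level: above
median is "high", below is "low". The median uses R's midpoint convention
for even cohorts. Samples exactly at the median are assigned "high" and
flagged in a tie report — the high/low wording leaves ties undefined, and
a deterministic, visible rule beats silently dropping samples. A cohort
with all-identical levels cannot be stratified and errors. Kaplan-Meier,
log-rank and Cox fits are delegated to the survival package unmodified;
the multivariate model adjusts for exactly four covariates: clonality,
diversity, treatment, and sequencing depth measured as the total number
of detected clonotypes. The bespoke content is the stratifying statistic,
not the survival machinery.

## Numerical and determinism choices

* All grouping outputs are sorted canonically, so every result is
  invariant to input row order and repeated runs are byte-identical.
* The generator seeds R's Mersenne-Twister explicitly (with the current
  sampling kind pinned), so one seed reproduces files byte-for-byte.
* Fisher tie comparison uses the conventional `p <= p_obs * (1 + 1e-7)`;
  the enumeration oracle in the tests applies the same convention, and
  agreement is asserted to 1e-12.
* Clonality drops zero frequencies (0 log 0 := 0) and requires the input
  to sum to 1 within 1e-9 unless counts are passed explicitly.

## Problem sizes used in validation

The test suite validates at the scales the analyses are designed for:
degeneracy against a brute-force oracle on 200 random repertoires of up
to 100 records; Fisher p-values against exhaustive enumeration on 500
random tables over universes up to 200; planted-spectrum recovery on 20
repertoires of 10,000 groups; enrichment recovery (multipliers 2 and 8)
on 50 repertoires of 5,000 groups each, with the matched-expansion
comparator checked under a label-neutral configuration; and hazard-ratio
recovery on 50 simulated 60-sample cohorts. One caveat found during
design: when labels are strongly enriched in convergent groups, the top-k
expansion comparator picks up a small *genuine* association (convergent
groups aggregate reads over several variants, so they are
over-represented among the most-read TCRs); the comparator's neutrality
is therefore asserted where it holds by construction — when labels are
independent of everything — and under enrichment the assertion is the
directional one, that convergence dominates expansion.

## Known limitations

* Sequencing-error correction is out of scope; upstream error collapse
  (or its absence) will shift absolute degeneracy counts.
* Reading is limited to immunoSEQ-style TSV, AIRR Rearrangement TSV and
  10x contig CSV; other pipelines' exports need column mapping by the
  user.
* Single-cell pairing keeps only cells with exactly one productive beta
  chain and attaches the best-supported alpha; cells with two alpha
  chains (a real biological possibility) contribute only their dominant
  alpha.
* The enrichment universe is the sample's post-QC unique key set;
  sensitivity to universe definition (e.g. restricting to CD8+ cells) is
  the user's responsibility.
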