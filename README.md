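# TCRconvergence

Detection and statistical characterisation of **TCR convergence** in
immune repertoires: T cell receptors whose identical amino-acid form
(same V gene + CDR3 amino-acid sequence) is encoded by two or more
distinct CDR3 nucleotide rearrangements within one sample. Because
independent recombination events converging on the same protein point to
antigen-driven selection, convergent TCRs are a candidate readout of
antigen-specific T cell responses and a prognostic biomarker for
checkpoint-blockade immunotherapy. The package is aimed at
immunogenomics analysts working with bulk TCRβ-seq (immunoSEQ-style or
AIRR Rearrangement tables) or 10x single-cell V(D)J contigs.

## What it computes

For an amino-acid-level TCR *t* in sample *s*, the **degeneracy**
*D(t)* is the number of distinct CDR3 nucleotide sequences encoding *t*
in *s*; *t* is convergent iff *D(t) ≥ 2*. On top of this the package
provides:

- **CDR3 quality control** — length in [8, 23], C…F anchors, standard
  20-letter alphabet, with conserving per-rule bookkeeping;
- **degeneracy spectra**, CDR3-length / V-gene profiles, and interior
  amino-acid composition per degeneracy class with two-sided exact
  binomial tests against the non-convergent baseline;
- **publicity** — public-TCR derivation across a cohort (a key shared by
  ≥ ⌈threshold·N⌉ of N individuals) and the public fraction of each
  sample's convergent set;
- **enrichment** — Fisher's exact test (two-sided, hypergeometric
  enumeration) of a TCR set against an antigen-specific label set over
  the sample's unique-key universe, reporting the sample odds ratio
  *ad/bc* with Haldane–Anscombe zero-cell correction, plus a matched
  **clonal-expansion comparator** (top-*k* TCRs by reads, *k* = number of
  convergent TCRs);
- **repertoire indices** — clonality = 1 − Pielou's evenness
  = 1 + Σᵢ pᵢ log₂ pᵢ / log₂ n, and diversity = n/N;
- **prognosis inputs** — median-split stratification of samples by
  convergence level and assembly of survival tables (Kaplan–Meier,
  log-rank and Cox fits delegated to the survival package);
- a **seed-deterministic synthetic repertoire generator** with exact
  planted degeneracy spectra, power-law clone sizes, controllable label
  enrichment in convergent clones, and cross-individual sharing — the
  ground truth every stage is validated against.

## Worked example

Simulate a repertoire of 2,000 amino-acid-level TCR groups with
antigen-specific labels planted at 4× odds in convergent clones, then run
the full analysis:

```r
library(TCRconvergence)

cfg <- simulationConfig(seed = 42, nGroups = 2000, specificOddsMultiplier = 4)
sim <- simulateRepertoire(cfg, "donor1")

rep    <- filterRepertoire(sim$repertoire)   # CDR3 QC
groups <- convergentGroups(rep)              # degeneracy per (V, CDR3aa) key
groups
#> ConvergentGroups 'donor1' (bulk_beta): 2000 groups, 108 convergent (degeneracy >= 2)

degeneracySpectrum(groups)
#>   degeneracy n_groups convergent_share
#> 1          1     1892               NA
#> 2          2       98       0.90740741
#> 3          3        8       0.07407407
#> 4          4        2       0.01851852

repertoireStats(rep, groups)
#>   sample_id    n    N clonality diversity convergence_level
#> 1    donor1 2120 6113 0.1541735 0.3468019               108
```

2,120 nucleotide-level clonotypes collapse into 2,000 amino-acid TCRs;
108 (5.4%) are convergent, ~91% of them with degeneracy 2 — the
characteristic fast-decaying spectrum. Enrichment of the convergent set
for the planted antigen-specific labels, versus the matched expansion
comparator:

```r
labels <- sim$truth$key[sim$truth$specific]
fisherEnrichment(convergentSet(groups), labels, groupTable(groups)$key)
#> EnrichmentResult: OR = 3.909 (log10 0.592), p = 1.08e-08

expanded <- selectExpanded(groups, convergenceLevel(groups))
fisherEnrichment(expanded, labels, groupTable(groups)$key)
#> EnrichmentResult: OR = 1.45 (log10 0.161), p = 0.167
```

Convergence recovers the planted 4× association (OR 3.9, p ≈ 1e-8) while
equal-sized top-read expansion shows only the weak indirect signal
(OR 1.45, n.s.) — the convergence-beats-expansion pattern the method is
built to expose.

See `vignettes/tcr-convergence-methods.Rmd` for the model, parameter
choices, generator assumptions and numerical conventions.

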