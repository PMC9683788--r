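Package: TCRconvergence
Title: TCR Convergence Detection and Antigen-Specificity Enrichment in
    Immune Repertoires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects convergent T cell receptors (TCRs) in bulk TCR-beta and
    paired single-cell repertoires: amino-acid-level TCRs (V gene + CDR3
    amino-acid sequence) encoded by two or more distinct nucleotide
    rearrangements within one sample. Provides CDR3 quality control,
    degeneracy spectra and amino-acid composition statistics with exact
    binomial tests, public-TCR derivation across cohorts, Fisher's exact
    enrichment of convergent (and matched clonally-expanded) TCR sets for
    antigen-specific labels, repertoire clonality (1 - Pielou's evenness)
    and diversity (n/N) indices, median-split stratification for survival
    analysis, and a seed-deterministic synthetic repertoire generator with
    planted degeneracy spectra, clone-size skew, antigen-specific labels and
    cross-individual sharing for ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    Biostrings,
    survival
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
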