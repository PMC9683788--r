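# Reading and writing the three repertoire table dialects, CDR3
# translation, and TSV report output.

# Column synonym maps per dialect. immunoSEQ exports vary by vintage, so
# several historical spellings are accepted for each logical column.
.DIALECTS <- list(
  immunoseq = list(
    cdr3_nt = c("nucleotide", "rearrangement", "nucleotide_sequence", "cdr3_rearrangement"),
    cdr3_aa = c("aminoAcid", "amino_acid", "aminoacid", "cdr3_amino_acid"),
    v_gene  = c("vGeneName", "v_gene", "vMaxResolved", "v_resolved"),
    j_gene  = c("jGeneName", "j_gene", "jMaxResolved", "j_resolved"),
    count   = c("templates", "count (templates/reads)", "count (reads)",
                "reads", "count", "templates (reads)", "seq_reads")
  ),
  airr = list(
    cdr3_nt = "junction",
    cdr3_aa = "junction_aa",
    v_gene  = "v_call",
    j_gene  = "j_call",
    count   = "duplicate_count"
  )
)

.resolveColumn <- function(cols, synonyms, what, dialect, required = TRUE) {
  hit <- synonyms[synonyms %in% cols]
  if (length(hit) == 0L) {
    if (required)
      stopf("%s file is missing a required %s column (looked for: %s)",
            dialect, what, paste(synonyms, collapse = ", "))
    return(NA_character_)
  }
  hit[1L]
}

#' Read a bulk TCR-beta repertoire table
#'
#' Reads an immunoSEQ-style or AIRR Rearrangement TSV into a
#' \code{\link{Repertoire-class}}. Rows sharing a \code{(v_gene, cdr3_nt)}
#' key are aggregated by summing counts; rows with an empty CDR3 amino-acid
#' sequence are dropped; V/J allele suffixes are stripped (see
#' \code{\link{normalizeVGene}}). Column-name synonyms are resolved per
#' dialect; unknown extra columns are ignored.
#'
#' @param path path to a tab-separated file.
#' @param dialect \code{"immunoseq"} or \code{"airr"}.
#' @param sampleId sample identifier; defaults to the file name without
#'   extension.
#' @param vLevel V-gene resolution for grouping, \code{"gene"} (default) or
#'   \code{"family"}.
#' @return A \code{\link{Repertoire-class}} object (not yet QC-filtered).
#' @seealso \code{\link{filterRepertoire}}, \code{\link{writeReportTSV}}
#' @export
readBulkRepertoire <- function(path, dialect = c("immunoseq", "airr"),
                               sampleId = NULL, vLevel = c("gene", "family")) {
  dialect <- match.arg(dialect)
  vLevel <- match.arg(vLevel)
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  raw <- fread(path, sep = "\t", header = TRUE, data.table = FALSE,
               showProgress = FALSE)
  syn <- .DIALECTS[[dialect]]
  cn <- names(raw)
  nt <- .resolveColumn(cn, syn$cdr3_nt, "CDR3 nucleotide", dialect)
  aa <- .resolveColumn(cn, syn$cdr3_aa, "CDR3 amino-acid", dialect)
  vg <- .resolveColumn(cn, syn$v_gene, "V-gene", dialect)
  ct <- .resolveColumn(cn, syn$count, "count", dialect)
  jg <- .resolveColumn(cn, syn$j_gene, "J-gene", dialect, required = FALSE)
  df <- data.frame(
    v_gene  = normalizeVGene(raw[[vg]], level = vLevel),
    j_gene  = if (is.na(jg)) NA_character_ else normalizeVGene(raw[[jg]]),
    cdr3_nt = toupper(as.character(raw[[nt]])),
    cdr3_aa = as.character(raw[[aa]]),
    count   = as.numeric(raw[[ct]]),
    stringsAsFactors = FALSE)
  Repertoire(sampleId, df)
}

#' Read and pair 10x single-cell V(D)J contigs
#'
#' Reads a 10x-style \code{filtered_contig_annotations.csv}, keeps
#' productive contigs only, and pairs chains per cell barcode: cells with
#' exactly one productive beta (TRB) chain are retained; when one or more
#' productive alpha (TRA) chains are present, the one with the highest
#' supporting read count is attached. Cells with zero or multiple
#' productive beta chains are dropped and counted in the QC report
#' (ambiguous clonotype identity would corrupt degeneracy counts).
#'
#' @param path path to the contig CSV (columns \code{barcode},
#'   \code{chain}, \code{v_gene}, \code{cdr3}, \code{cdr3_nt},
#'   \code{productive}; \code{reads} used for alpha tie-breaks when
#'   present).
#' @return A \code{\link{PairedCells-class}} object. If the file contains
#'   no beta contigs at all, an empty object is returned with a warning.
#' @export
read10xContigs <- function(path) {
  if (!file.exists(path)) stopf("cannot read '%s': no such file", path)
  raw <- fread(path, header = TRUE, data.table = FALSE, showProgress = FALSE)
  need <- c("barcode", "chain", "v_gene", "cdr3", "cdr3_nt", "productive")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stopf("10x contig file is missing required column(s): %s",
          paste(miss, collapse = ", "))
  if (!"reads" %in% names(raw)) raw$reads <- 1
  prod <- tolower(as.character(raw$productive)) %in% c("true", "t", "1")
  raw <- raw[prod & nzchar(raw$cdr3), , drop = FALSE]
  empty <- data.frame(barcode = character(), beta_v = character(),
                      beta_cdr3_nt = character(), beta_cdr3_aa = character(),
                      alpha_v = character(), alpha_cdr3_nt = character(),
                      alpha_cdr3_aa = character(), stringsAsFactors = FALSE)
  beta <- raw[raw$chain == "TRB", , drop = FALSE]
  alpha <- raw[raw$chain == "TRA", , drop = FALSE]
  if (nrow(beta) == 0L) {
    warnf("no productive beta contigs in '%s'; returning empty result", path)
    return(new("PairedCells", cells = empty,
               dropped = list(no_beta = length(unique(raw$barcode)),
                              multi_beta = 0L)))
  }
  nbeta <- table(beta$barcode)
  keep <- names(nbeta)[nbeta == 1L]
  multi <- sum(nbeta > 1L)
  allbc <- unique(raw$barcode)
  nobeta <- length(setdiff(allbc, names(nbeta)))
  beta <- beta[beta$barcode %in% keep, , drop = FALSE]
  # one alpha per cell: highest read support, then canonical order for ties
  if (nrow(alpha)) {
    alpha <- alpha[order(alpha$barcode, -alpha$reads, alpha$v_gene,
                         alpha$cdr3_nt, method = "radix"), , drop = FALSE]
    alpha <- alpha[!duplicated(alpha$barcode), , drop = FALSE]
  }
  m <- match(beta$barcode, alpha$barcode)
  out <- data.frame(
    barcode = beta$barcode,
    beta_v = normalizeVGene(beta$v_gene),
    beta_cdr3_nt = toupper(beta$cdr3_nt),
    beta_cdr3_aa = beta$cdr3,
    alpha_v = ifelse(is.na(m), NA_character_, normalizeVGene(alpha$v_gene[m])),
    alpha_cdr3_nt = ifelse(is.na(m), NA_character_,
                           toupper(alpha$cdr3_nt[m])),
    alpha_cdr3_aa = ifelse(is.na(m), NA_character_, alpha$cdr3[m]),
    stringsAsFactors = FALSE)
  out <- out[order(out$barcode, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  new("PairedCells", cells = out,
      dropped = list(no_beta = nobeta, multi_beta = multi))
}

#' Translate CDR3 nucleotide sequences
#'
#' Standard-genetic-code translation of in-frame CDR3 nucleotide
#' sequences. Sequences containing a stop codon translate to a string
#' containing \code{"*"} and are flagged non-productive.
#'
#' @param cdr3_nt character vector of DNA strings over \code{A,C,G,T};
#'   every length must be divisible by 3.
#' @return character vector of amino-acid sequences, with attribute
#'   \code{"productive"}: logical, \code{FALSE} where a stop codon occurs.
#' @examples
#' translateCDR3("TGTGCCAGCAGC")   # "CASS"
#' attr(translateCDR3("TGA"), "productive")  # FALSE
#' @export
translateCDR3 <- function(cdr3_nt) {
  cdr3_nt <- toupper(as.character(cdr3_nt))
  if (any(nchar(cdr3_nt) %% 3L != 0L))
    stopf("frame error: CDR3 nucleotide length not divisible by 3")
  if (any(grepl("[^ACGT]", cdr3_nt)))
    stopf("CDR3 nucleotide sequences must contain only A, C, G, T")
  aa <- as.character(translate(DNAStringSet(cdr3_nt)))
  structure(aa, productive = !grepl("*", aa, fixed = TRUE))
}

#' Write an analysis result to a TSV report
#'
#' Writes tab-separated reports with a documented column schema and
#' bit-stable row ordering (sorted by key), so that identical inputs give
#' byte-identical files. Methods exist for \code{Repertoire} (immunoSEQ
#' dialect columns \code{nucleotide}, \code{aminoAcid}, \code{vGeneName},
#' \code{jGeneName}, \code{templates} so that
#' \code{\link{readBulkRepertoire}} round-trips), \code{ConvergentGroups}
#' (columns \code{v_gene}, \code{cdr3_aa}, \code{degeneracy},
#' \code{n_variants}, \code{total_count}) and plain data.frames (written
#' as-is, sorted by all columns).
#'
#' @param x object to write.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
setGeneric("writeReportTSV", function(x, path) standardGeneric("writeReportTSV"))

.writeTSV <- function(df, path) {
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stopf("cannot write report to '%s': %s", path,
                         conditionMessage(ok))
  invisible(path)
}

#' @rdname writeReportTSV
#' @export
setMethod("writeReportTSV", "Repertoire", function(x, path) {
  df <- canonicalOrder(x@clonotypes)
  out <- data.frame(nucleotide = df$cdr3_nt, aminoAcid = df$cdr3_aa,
                    vGeneName = df$v_gene, jGeneName = df$j_gene,
                    templates = df$count, stringsAsFactors = FALSE)
  .writeTSV(out, path)
})

#' @rdname writeReportTSV
#' @export
setMethod("writeReportTSV", "ConvergentGroups", function(x, path) {
  g <- x@groups
  g <- g[order(g$key, method = "radix"), , drop = FALSE]
  out <- data.frame(v_gene = g$v_gene, cdr3_aa = g$cdr3_aa,
                    degeneracy = g$degeneracy, n_variants = g$n_variants,
                    total_count = g$total_count, stringsAsFactors = FALSE)
  .writeTSV(out, path)
})

#' @rdname writeReportTSV
#' @export
setMethod("writeReportTSV", "data.frame", function(x, path) {
  if (nrow(x) > 1L)
    x <- x[do.call(order, c(unname(as.list(x)), list(method = "radix"))), ,
           drop = FALSE]
  .writeTSV(x, path)
})
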