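# Internal helpers shared across modules.

.datatable.aware <- TRUE

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Normalize V-gene names
#'
#' Strips allele suffixes (text after \code{"*"}) so that e.g.
#' \code{"TRBV19*01"} and \code{"TRBV19*02"} group together. With
#' \code{level = "family"} the gene-level part after \code{"-"} is also
#' dropped (\code{"TRBV6-2"} becomes \code{"TRBV6"}).
#'
#' @param v character vector of V-gene names.
#' @param level \code{"gene"} (default) or \code{"family"}.
#' @return character vector of normalized names.
#' @examples
#' normalizeVGene(c("TRBV19*01", "TRBV6-2*03"))
#' normalizeVGene("TRBV6-2", level = "family")
#' @export
normalizeVGene <- function(v, level = c("gene", "family")) {
  level <- match.arg(level)
  v <- sub("\\*.*$", "", as.character(v))
  if (level == "family") v <- sub("-.*$", "", v)
  v
}

# Canonical amino-acid-level TCR key: V gene + CDR3 aa (+ alpha chain in
# paired mode). The separator cannot occur in gene names or CDR3s.
tcrKey <- function(v_gene, cdr3_aa, alpha_v = NULL, alpha_aa = NULL) {
  key <- paste(v_gene, cdr3_aa, sep = "|")
  if (!is.null(alpha_v)) {
    key <- paste(key, alpha_v, alpha_aa, sep = "|")
  }
  key
}

# Sort a clonotype table into the package's canonical order so that all
# outputs are invariant to input row order.
canonicalOrder <- function(df) {
  df[order(df$v_gene, df$cdr3_aa, df$cdr3_nt, method = "radix"), ,
     drop = FALSE]
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
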