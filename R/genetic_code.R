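#' @keywords internal
"_PACKAGE"

# Canonical codon order: alphabetical over A < C < G < T, i.e. AAA ... TTT.
# Every count vector, frequency vector and matrix column set in the package
# is indexed in this order.

#' The 64 codons in canonical (alphabetical) order
#'
#' All codon-indexed vectors and matrices produced by cubkit use this order.
#'
#' @format Character vector of length 64 (`"AAA"` ... `"TTT"`).
#' @export
CODONS <- sort(as.vector(outer(
  outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0),
  c("A", "C", "G", "T"), paste0
)))

#' Standard genetic code in canonical codon order
#'
#' One-letter amino-acid codes, `"*"` for the three stop codons.  Taken from
#' the standard nuclear code; alternative codes are deliberately out of scope.
#'
#' @format Named character vector of length 64.
#' @export
GENETIC_CODE_TABLE <- {
  gc <- Biostrings::GENETIC_CODE
  gc[CODONS]
}

#' Stop and sense codon sets
#'
#' @format Character vectors: `STOP_CODONS` has length 3, `SENSE_CODONS` 61.
#' @export
STOP_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == "*"]

#' @rdname STOP_CODONS
#' @export
SENSE_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]

#' Synonymous-codon families of the standard code
#'
#' `AA_FAMILIES` maps each of the 20 amino acids (one-letter code) to its
#' synonymous codon set in canonical order; `FAMILY_SIZE` gives the
#' degeneracy k of each family (1, 2, 3, 4 or 6).  The 18 amino acids with
#' k >= 2 are the degenerate amino acids over which sENC-x is defined.
#'
#' @format `AA_FAMILIES`: named list of character vectors; `FAMILY_SIZE`:
#'   named integer vector.
#' @export
AA_FAMILIES <- split(SENSE_CODONS, GENETIC_CODE_TABLE[SENSE_CODONS])

#' @rdname AA_FAMILIES
#' @export
FAMILY_SIZE <- vapply(AA_FAMILIES, length, integer(1))

#' @rdname AA_FAMILIES
#' @export
DEGENERATE_AAS <- names(FAMILY_SIZE)[FAMILY_SIZE >= 2]

# map codon -> amino acid family size, NA for stops
CODON_FAMILY_SIZE <- {
  k <- FAMILY_SIZE[GENETIC_CODE_TABLE]
  names(k) <- CODONS
  k
}

normalize_nucleotides <- function(x) {
  chartr("acgtuU", "ACGTTT", x)
}

#' Translate codons under the standard genetic code
#'
#' Case-insensitive; `U` is treated as `T`.  Codons containing any other
#' character translate to `NA` so the caller can decide whether to skip or
#' reject ambiguous codons.
#'
#' @param codon Character vector of trinucleotides.
#' @return Character vector of one-letter amino-acid codes, `"*"` for stop,
#'   `NA` for ambiguous codons.
#' @examples
#' translate_codon(c("ATG", "TAA", "TGG", "NNN"))
#' @export
translate_codon <- function(codon) {
  codon <- normalize_nucleotides(toupper(codon))
  bad <- nchar(codon) != 3L
  if (any(bad)) {
    stop("codons must be 3 characters long: ", paste(codon[bad], collapse = ", "))
  }
  out <- unname(GENETIC_CODE_TABLE[codon])
  out
}

#' Census of degeneracy classes
#'
#' Counts amino acids per synonymous-family size.  In the standard code this
#' is 2 amino acids with k = 1 (Met, Trp), 9 with k = 2, 1 with k = 3 (Ile),
#' 5 with k = 4 and 3 with k = 6, so 18 amino acids are degenerate and the
#' family sizes sum to the 61 sense codons.
#'
#' @return Named integer vector, names are family sizes.
#' @export
degeneracy_census <- function() {
  tab <- table(FAMILY_SIZE)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' The 59 informative codons used for clustering
#'
#' All sense codons minus the codons of the two non-degenerate amino acids
#' (ATG for Met, TGG for Trp); stop codons are excluded by construction.
#' These are the codons whose RSCU values carry information about synonymous
#' choice, and the columns of the species RSCU matrix.
#'
#' @return Character vector of length 59 in canonical (alphabetical) order.
#' @export
informative_codons <- function() {
  singles <- unlist(AA_FAMILIES[FAMILY_SIZE == 1L], use.names = FALSE)
  setdiff(SENSE_CODONS, singles)
}
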