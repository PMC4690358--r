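# Codon counting and the primary descriptive statistics: frequencies,
# positional GC content, RSCU.

#' Construct a codon count table
#'
#' A codon count table is the substrate of every statistic in the package:
#' a 64-long non-negative integer vector in canonical codon order with a
#' scope marker (a single gene, or codons pooled over all genes of a
#' species).
#'
#' @param counts Named numeric vector of codon counts; missing codons are
#'   filled with zero.  Names must be codons over ACGT.
#' @param scope `"gene"` or `"species"`.
#' @param n_skipped Number of codons skipped because they contained
#'   non-ACGT characters (bookkeeping only).
#' @return An object of class `codon_count_table`.
#' @export
codon_count_table <- function(counts, scope = c("species", "gene"),
                              n_skipped = 0L) {
  scope <- match.arg(scope)
  counts <- counts[!is.na(names(counts))]
  nm <- normalize_nucleotides(toupper(names(counts)))
  if (!all(nm %in% CODONS)) {
    stop("unknown codons: ", paste(setdiff(nm, CODONS), collapse = ", "))
  }
  if (any(counts < 0)) stop("codon counts must be non-negative")
  full <- stats::setNames(numeric(64), CODONS)
  full[nm] <- full[nm] + as.numeric(counts)
  structure(
    list(counts = full, scope = scope, n_codons = sum(full),
         n_skipped = as.integer(n_skipped)),
    class = "codon_count_table"
  )
}

#' @export
print.codon_count_table <- function(x, ...) {
  cat(sprintf("codon_count_table (%s scope): %g codons, %d skipped\n",
              x$scope, x$n_codons, x$n_skipped))
  used <- x$counts[x$counts > 0]
  cat(sprintf("  %d distinct codons used\n", length(used)))
  invisible(x)
}

as_cds_character <- function(seqs) {
  if (inherits(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (!is.character(seqs)) stop("sequences must be a character vector or XStringSet")
  normalize_nucleotides(toupper(seqs))
}

# Count codons of one or more in-frame CDS as a genes x 64 matrix.
# A terminal stop codon, when present, is excluded by convention: all the
# downstream statistics (RSCU, ENC, CAI) are defined over sense codons.
codon_count_matrix <- function(seqs) {
  seqs <- as_cds_character(seqs)
  if (length(seqs) == 0L) {
    m <- matrix(0, 0, 64, dimnames = list(NULL, CODONS))
    return(m)
  }
  if (any(nchar(seqs) %% 3L != 0L)) {
    stop("sequence length not a multiple of 3; validate_cds() first")
  }
  last <- substring(seqs, nchar(seqs) - 2L, nchar(seqs))
  has_term_stop <- last %in% STOP_CODONS
  seqs[has_term_stop] <- substring(seqs[has_term_stop], 1L,
                                   nchar(seqs[has_term_stop]) - 3L)
  set <- Biostrings::DNAStringSet(seqs)
  m <- Biostrings::oligonucleotideFrequency(set, width = 3L, step = 3L)
  m <- m[, CODONS, drop = FALSE]
  rownames(m) <- names(seqs)
  m
}

#' Count codons of validated coding sequences
#'
#' Counts every non-terminal codon of each sequence; with
#' `scope = "species"` the counts are pooled (summed) over all sequences,
#' which is also how species-level RSCU and ENC are defined here.  A
#' terminal stop codon is excluded; any remaining (internal) stop codon
#' means the input was not validated and is a hard error.  Codons
#' containing non-ACGT characters are skipped and tallied in `n_skipped`.
#'
#' @param seqs Character vector (or `DNAStringSet`) of in-frame CDS, ideally
#'   from [validate_cds_set()].
#' @param scope `"species"` (pooled) or `"gene"` (only valid for a single
#'   sequence).
#' @return A [codon_count_table()].
#' @seealso [codon_frequencies()], [rscu()], [enc()]
#' @examples
#' count_codons("ATGAAATAA")  # terminal TAA not counted
#' @export
count_codons <- function(seqs, scope = c("species", "gene")) {
  scope <- match.arg(scope)
  m <- codon_count_matrix(seqs)
  counts <- colSums(m)
  if (any(counts[STOP_CODONS] > 0)) {
    stop("internal stop codons present; run validate_cds_set() first")
  }
  seqs_chr <- as_cds_character(seqs)
  expected <- sum(nchar(seqs_chr) %/% 3L) -
    sum(substring(seqs_chr, nchar(seqs_chr) - 2L, nchar(seqs_chr)) %in% STOP_CODONS)
  n_skipped <- expected - sum(counts)
  codon_count_table(counts, scope = scope, n_skipped = n_skipped)
}

#' Codon frequencies (within-amino-acid fraction and per-thousand)
#'
#' For each codon, the fraction of its amino acid's usage it accounts for
#' (summing to 1 within each amino acid present) and its frequency per
#' thousand codons overall (summing to 1000 over all codons counted).
#'
#' @param t A [codon_count_table()] with at least one counted codon.
#' @return A `data.frame` with columns `codon`, `amino_acid`, `count`,
#'   `fraction`, `per_thousand`, one row per sense codon in canonical order.
#' @export
codon_frequencies <- function(t) {
  stopifnot(inherits(t, "codon_count_table"))
  if (t$n_codons <= 0) stop("empty table: no codons counted")
  counts <- t$counts[SENSE_CODONS]
  aa <- GENETIC_CODE_TABLE[SENSE_CODONS]
  aa_tot <- tapply(counts, aa, sum)[aa]
  fraction <- ifelse(aa_tot > 0, counts / aa_tot, NA_real_)
  data.frame(
    codon = SENSE_CODONS,
    amino_acid = unname(aa),
    count = unname(counts),
    fraction = unname(fraction),
    per_thousand = unname(1000 * counts / t$n_codons),
    stringsAsFactors = FALSE
  )
}

#' GC content by codon position
#'
#' Count-weighted fraction of G or C at each of the three codon positions,
#' over sense codons only.  GC3 follows the convention of including the
#' non-degenerate codons ATG and TGG, so values are directly comparable to
#' EMBOSS-style outputs.
#'
#' @param t A [codon_count_table()].
#' @return Named numeric vector `c(gc1, gc2, gc3)`, each in \[0, 1\].
#' @export
gc_by_position <- function(t) {
  stopifnot(inherits(t, "codon_count_table"))
  if (t$n_codons <= 0) stop("empty table: no codons counted")
  counts <- t$counts[SENSE_CODONS]
  n <- sum(counts)
  gc <- vapply(1:3, function(p) {
    base <- substring(SENSE_CODONS, p, p)
    sum(counts[base %in% c("G", "C")]) / n
  }, numeric(1))
  stats::setNames(gc, c("gc1", "gc2", "gc3"))
}

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of codon j of amino acid i is `k_i * x_ij / sum_j x_ij`: the
#' observed count relative to the expectation under uniform synonymous
#' usage.  Values above 1 mark codons used more than expected.  Codons of
#' amino acids that never occur are `NA` (reported missing rather than 0,
#' which would fake "avoided" status); the affected amino acids are listed
#' in the `undefined_aas` attribute.
#'
#' @param t A [codon_count_table()].
#' @return Named numeric vector over the 61 sense codons, class
#'   `rscu_vector`, with attribute `undefined_aas`.
#' @export
rscu <- function(t) {
  stopifnot(inherits(t, "codon_count_table"))
  if (t$n_codons <= 0) stop("empty table: no codons counted")
  counts <- t$counts[SENSE_CODONS]
  aa <- GENETIC_CODE_TABLE[SENSE_CODONS]
  aa_tot <- tapply(counts, aa, sum)[aa]
  k <- CODON_FAMILY_SIZE[SENSE_CODONS]
  vals <- ifelse(aa_tot > 0, k * counts / aa_tot, NA_real_)
  undefined <- sort(unique(unname(aa[aa_tot == 0])))
  structure(stats::setNames(as.numeric(vals), SENSE_CODONS),
            undefined_aas = undefined, class = "rscu_vector")
}

#' Read coding sequences from a FASTA file
#'
#' Multi-record FASTA, gzip-transparent.  Sequences are upper-cased and
#' RNA-style `U` is converted to `T` at parse time.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return Named character vector of nucleotide sequences.
#' @export
read_cds_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- normalize_nucleotides(toupper(as.character(set)))
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @param width Line width for wrapping.
#' @export
write_cds_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a cusp-style codon frequency table
#'
#' @param t A [codon_count_table()].
#' @param path Output TSV path.
#' @export
write_codon_freq_tsv <- function(t, path) {
  df <- codon_frequencies(t)
  df$fraction <- signif(df$fraction, 6)
  df$per_thousand <- signif(df$per_thousand, 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write RSCU values, one species per file or a combined matrix
#'
#' `write_rscu_tsv()` writes a single species' RSCU vector as a
#' codon/amino-acid/rscu TSV; `write_rscu_matrix_tsv()` writes a
#' species x codon matrix (species in rows).
#'
#' @param r An `rscu_vector` from [rscu()].
#' @param path Output TSV path.
#' @export
write_rscu_tsv <- function(r, path) {
  df <- data.frame(
    codon = names(r),
    amino_acid = unname(GENETIC_CODE_TABLE[names(r)]),
    rscu = signif(as.numeric(r), 6),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rscu_tsv
#' @param m Species x codon matrix, e.g. from [build_rscu_matrix()].
#' @export
write_rscu_matrix_tsv <- function(m, path) {
  df <- data.frame(species = rownames(m), signif(m, 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
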