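# Input validation and the dataset quality filters: in-frame CDS checks,
# the ORF length filter, the per-species ortholog coverage/length filter,
# and selection of the CAI reference gene set from expression data.

#' Validate a single raw coding sequence
#'
#' Normalizes case and RNA-style U, then accepts the sequence iff its
#' length is a multiple of 3, it contains no internal stop codon and it has
#' at least one sense codon.  A terminal stop codon is allowed and
#' stripped.  Rejections carry a machine-readable reason: `"frame"`,
#' `"internal_stop"` or `"too_short"`.
#'
#' @param seq Nucleotide string.
#' @param id Optional sequence identifier, kept in the result.
#' @return List with `ok` (logical), `seq` (cleaned sequence without the
#'   terminal stop, `NA` on rejection), `length_codons` (sense codons),
#'   `reason` (`NA` when accepted) and `id`.
#' @export
validate_cds <- function(seq, id = NA_character_) {
  s <- normalize_nucleotides(toupper(seq))
  reject <- function(reason) list(ok = FALSE, seq = NA_character_,
                                  length_codons = NA_integer_,
                                  reason = reason, id = id)
  if (nchar(s) %% 3L != 0L) return(reject("frame"))
  if (nchar(s) == 0L) return(reject("too_short"))
  starts <- seq(1L, nchar(s), by = 3L)
  cods <- substring(s, starts, starts + 2L)
  if (cods[length(cods)] %in% STOP_CODONS) {
    cods <- cods[-length(cods)]
    s <- substring(s, 1L, nchar(s) - 3L)
  }
  if (any(cods %in% STOP_CODONS)) return(reject("internal_stop"))
  n_sense <- sum(cods %in% SENSE_CODONS)
  if (n_sense < 1L) return(reject("too_short"))
  list(ok = TRUE, seq = s, length_codons = length(cods),
       reason = NA_character_, id = id)
}

#' Validate a set of coding sequences
#'
#' Vectorized wrapper around the [validate_cds()] rules.
#'
#' @param seqs Named character vector of raw sequences.
#' @return List with `accepted` (named character vector of cleaned
#'   sequences, terminal stops stripped) and `rejected` (`data.frame` with
#'   columns `id`, `reason`).
#' @export
validate_cds_set <- function(seqs) {
  if (is.null(names(seqs))) names(seqs) <- as.character(seq_along(seqs))
  res <- lapply(seq_along(seqs), function(i) validate_cds(seqs[[i]], names(seqs)[i]))
  ok <- vapply(res, `[[`, logical(1), "ok")
  accepted <- vapply(res[ok], `[[`, character(1), "seq")
  names(accepted) <- names(seqs)[ok]
  rejected <- data.frame(
    id = names(seqs)[!ok],
    reason = vapply(res[!ok], `[[`, character(1), "reason"),
    stringsAsFactors = FALSE
  )
  list(accepted = accepted, rejected = rejected)
}

#' Filter ORFs by length
#'
#' Retains sequences strictly longer than `min_codons` sense codons
#' (a 100-codon ORF is dropped under the default).
#'
#' @param seqs Named character vector of validated CDS (terminal stop
#'   already stripped).
#' @param min_codons Length threshold in codons; strict inequality.
#' @return The retained subset of `seqs`.
#' @export
filter_orfs <- function(seqs, min_codons = 100L) {
  if (length(seqs) == 0L) return(seqs)
  seqs[nchar(seqs) %/% 3L > min_codons]
}

#' Read / write the long-format ortholog table
#'
#' Columns: `gene_id`, `species`, `length_nt` — one row per conserved gene
#' recovered in a species, with the recovered length in nucleotides.
#'
#' @param path TSV path.
#' @return `data.frame` with the three columns above.
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "species", "length_nt")
  if (!all(need %in% names(df))) {
    stop("ortholog table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$length_nt <= 0)) stop("ortholog lengths must be positive")
  df[need]
}

#' @rdname read_ortholog_table
#' @param df Ortholog table `data.frame`.
#' @export
write_ortholog_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Species quality filter on ortholog recovery
#'
#' A species passes iff it recovered at least a fraction `min_coverage`
#' (default 25%) of the conserved gene set AND the mean recovered length
#' strictly exceeds `min_avg_len` nucleotides (default 500).
#'
#' @param ortho Long-format ortholog table (`gene_id`, `species`,
#'   `length_nt`).
#' @param conserved_ids Character vector: the full conserved gene set
#'   (the denominator of coverage).
#' @param min_coverage Inclusive coverage threshold.
#' @param min_avg_len Strict mean-length threshold (nt).
#' @return `data.frame` with one row per species: `species`, `n_present`,
#'   `fraction_recovered`, `mean_length_nt`, `passed`, `reasons`
#'   (semicolon-joined, empty when passed).
#' @export
species_quality_filter <- function(ortho, conserved_ids,
                                   min_coverage = 0.25, min_avg_len = 500) {
  if (length(conserved_ids) == 0L) stop("conserved_ids must be nonempty")
  extra <- setdiff(unique(ortho$gene_id), conserved_ids)
  if (length(extra)) {
    stop("ortholog table contains genes outside the conserved set: ",
         paste(utils::head(extra, 3), collapse = ", "))
  }
  species <- sort(unique(ortho$species))
  rows <- lapply(species, function(sp) {
    sub <- ortho[ortho$species == sp, , drop = FALSE]
    n <- length(unique(sub$gene_id))
    frac <- n / length(conserved_ids)
    mlen <- if (n > 0) mean(sub$length_nt) else NA_real_
    reasons <- character(0)
    if (frac < min_coverage) reasons <- c(reasons, "coverage")
    if (is.na(mlen) || mlen <= min_avg_len) reasons <- c(reasons, "length")
    data.frame(species = sp, n_present = n, fraction_recovered = frac,
               mean_length_nt = mlen, passed = length(reasons) == 0L,
               reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read / write the long-format expression table
#'
#' Columns: `gene_id`, `library_id`, `read_count`, `effective_length_nt`.
#'
#' @param path TSV path.
#' @return `data.frame` with the four columns above.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "library_id", "read_count", "effective_length_nt")
  if (!all(need %in% names(df))) {
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  }
  df[need]
}

#' @rdname read_expression_table
#' @param df Expression table `data.frame`.
#' @export
write_expression_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-library TPM and mean TPM from a long expression table
#'
#' @param expr Long expression table (see [read_expression_table()]).
#' @return `data.frame` with one row per gene: `gene_id`, one `tpm_<lib>`
#'   column per library, and `mean_tpm` (unweighted arithmetic mean of the
#'   per-library TPMs).
#' @export
expression_tpm <- function(expr) {
  libs <- sort(unique(expr$library_id))
  genes <- sort(unique(expr$gene_id))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (lib in libs) {
    sub <- expr[expr$library_id == lib, , drop = FALSE]
    sub <- sub[match(genes, sub$gene_id), , drop = FALSE]
    if (any(is.na(sub$read_count))) {
      stop("library ", lib, " is missing genes present in other libraries")
    }
    out[[paste0("tpm_", lib)]] <- tpm(sub$read_count, sub$effective_length_nt)
  }
  out$mean_tpm <- rowMeans(out[, paste0("tpm_", libs), drop = FALSE])
  out
}

#' Select the CAI reference set of highly expressed conserved genes
#'
#' Ranks the genes that belong to the conserved set by mean TPM across the
#' provided libraries and returns the top `n`.  Ties are broken
#' lexicographically by gene id.
#'
#' @param expr Long expression table (see [read_expression_table()]).
#' @param conserved_ids Conserved gene set; only members are eligible.
#' @param n Reference set size.
#' @return Character vector of `n` gene ids.
#' @export
select_reference_set <- function(expr, conserved_ids, n = 50L) {
  tp <- expression_tpm(expr)
  tp <- tp[tp$gene_id %in% conserved_ids, , drop = FALSE]
  if (nrow(tp) < n) {
    stop("only ", nrow(tp), " conserved genes with expression data; need ", n)
  }
  ord <- order(-tp$mean_tpm, tp$gene_id)
  tp$gene_id[ord][seq_len(n)]
}
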