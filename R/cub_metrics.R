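# Codon usage bias metrics: Wright's effective number of codons (ENC),
# per-amino-acid scaled ENC (sENC-x), the codon adaptation index (CAI)
# with an expression-defined reference set, and TPM normalization.

# Family homozygosity F for every degenerate amino acid of a counts matrix
# (rows = genes/tables, cols = 64 codons).  Returns a rows x 18 matrix.
# counts mode applies Wright's small-sample correction
#   F_hat = (n * sum(p^2) - 1) / (n - 1)
# and requires n >= 2; frequencies mode uses F = sum(p^2) directly.
# Unusable families (n < 2, or F_hat <= 0) are NA.
family_homozygosity_matrix <- function(m, mode = c("counts", "frequencies")) {
  mode <- match.arg(mode)
  out <- matrix(NA_real_, nrow(m), length(DEGENERATE_AAS),
                dimnames = list(rownames(m), DEGENERATE_AAS))
  for (aa in DEGENERATE_AAS) {
    cols <- AA_FAMILIES[[aa]]
    x <- m[, cols, drop = FALSE]
    n <- rowSums(x)
    p2 <- rowSums((x / ifelse(n > 0, n, NA_real_))^2)
    if (mode == "counts") {
      f <- (n * p2 - 1) / (n - 1)
      f[n < 2] <- NA_real_
      f[!is.na(f) & f <= 0] <- NA_real_
    } else {
      f <- p2
      f[n <= 0] <- NA_real_
    }
    out[, aa] <- f
  }
  out
}

#' Wright's family homozygosity for one amino acid
#'
#' The homozygosity F of a synonymous family is the probability that two
#' codons of the amino acid drawn from the gene (or pool) are the same.
#' In `counts` mode Wright's small-sample corrected estimator
#' \eqn{\hat F = (n \sum p_i^2 - 1)/(n - 1)} is used, requiring at least
#' two occurrences of the amino acid; in `frequencies` mode the
#' uncorrected \eqn{F = \sum p_i^2}.
#'
#' @param t A [codon_count_table()].
#' @param aa One-letter code of a degenerate amino acid.
#' @param mode `"counts"` (corrected) or `"frequencies"`.
#' @return F in (0, 1\], or `NA` if the family is unusable (fewer than two
#'   occurrences in counts mode, or a non-positive corrected estimate).
#' @export
family_homozygosity <- function(t, aa, mode = c("counts", "frequencies")) {
  mode <- match.arg(mode)
  stopifnot(inherits(t, "codon_count_table"))
  if (!aa %in% DEGENERATE_AAS) stop("amino acid must be degenerate: ", aa)
  m <- matrix(t$counts, 1, 64, dimnames = list(NULL, CODONS))
  unname(family_homozygosity_matrix(m, mode)[1, aa])
}

# ENC from a homozygosity matrix.  Wright's composition
#   ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6
# with Fk the mean homozygosity of family-size class k.  A fully missing
# k = 3 class (Ile) is imputed as mean(F2, F4), Wright's remedy; any other
# fully missing class is imputed with the mean of the available class
# means.  Result capped at 61.
enc_from_homozygosity <- function(fmat, cap = TRUE) {
  classes <- c("2" = 2L, "3" = 3L, "4" = 4L, "6" = 6L)
  n_aa <- c("2" = 9, "3" = 1, "4" = 5, "6" = 3)
  fbar <- vapply(classes, function(k) {
    aas <- DEGENERATE_AAS[FAMILY_SIZE[DEGENERATE_AAS] == k]
    rowMeans(fmat[, aas, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(fmat)))
  if (nrow(fmat) == 1L) fbar <- matrix(fbar, 1, 4, dimnames = list(NULL, names(classes)))
  fbar[is.nan(fbar)] <- NA_real_
  missing <- is.na(fbar)
  # impute Ile class from the 2- and 4-fold class means where possible
  imp3 <- missing[, "3"] & !missing[, "2"] & !missing[, "4"]
  fbar[imp3, "3"] <- (fbar[imp3, "2"] + fbar[imp3, "4"]) / 2
  # any other fully missing class: mean of available class means
  still <- is.na(fbar)
  if (any(still)) {
    rm_ <- rowMeans(fbar, na.rm = TRUE)
    for (j in seq_len(ncol(fbar))) {
      idx <- still[, j] & is.finite(rm_)
      fbar[idx, j] <- rm_[idx]
    }
  }
  enc <- 2 + n_aa["2"] / fbar[, "2"] + n_aa["3"] / fbar[, "3"] +
    n_aa["4"] / fbar[, "4"] + n_aa["6"] / fbar[, "6"]
  if (cap) enc[enc > 61] <- 61
  list(enc = unname(enc), family_means = fbar, missing = missing)
}

#' Effective number of codons (ENC)
#'
#' Wright's ENC measures how far codon usage departs from uniform
#' synonymous usage: 61 when all sense codons are used equally, down to 20
#' when a single codon is used per amino acid (the composition
#' 2 + 9 + 1 + 5 + 3 evaluated at maximal bias; the often-quoted lower
#' bound of 21 does not follow from the formula).  Computed as
#' `2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` with `Fk` the mean homozygosity over
#' amino acids of degeneracy class k.  In `counts` mode the small-sample
#' corrected homozygosity estimator is used (appropriate for single genes;
#' the correction is negligible on pooled species counts); `frequencies`
#' mode uses uncorrected proportions.  Estimates above 61 (possible under
#' the corrected estimator on near-uniform data) are capped at 61.
#'
#' A fully missing Ile class is imputed as the mean of the 2- and 4-fold
#' class means (Wright's remedy); any other fully missing class is imputed
#' with the mean of the available class means.  Imputed classes are
#' reported in `missing_families`.
#'
#' @param t A [codon_count_table()].
#' @param mode `"counts"` or `"frequencies"`.
#' @return An `enc_result` list: `enc` (in \[1, 61\]), `family_means`
#'   (named vector over classes 2, 3, 4, 6), `missing_families`, `mode`.
#' @references Wright F (1990) The 'effective number of codons' used in a
#'   gene. Gene 87:23-29.
#' @export
enc <- function(t, mode = c("counts", "frequencies")) {
  mode <- match.arg(mode)
  stopifnot(inherits(t, "codon_count_table"))
  if (t$n_codons <= 0) stop("empty table: no codons counted")
  m <- matrix(t$counts, 1, 64, dimnames = list(NULL, CODONS))
  fmat <- family_homozygosity_matrix(m, mode)
  if (all(is.na(fmat))) stop("ENC undefined: no usable degenerate family")
  res <- enc_from_homozygosity(fmat)
  structure(
    list(enc = res$enc,
         family_means = stats::setNames(res$family_means[1, ], colnames(res$family_means)),
         missing_families = as.integer(names(which(res$missing[1, ]))),
         mode = mode),
    class = "enc_result"
  )
}

#' @export
print.enc_result <- function(x, ...) {
  cat(sprintf("ENC = %.4f (%s mode)\n", x$enc, x$mode))
  if (length(x$missing_families)) {
    cat("  imputed family classes:", paste(x$missing_families, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-gene ENC and GC3 for a set of sequences
#'
#' Convenience wrapper computing, for each validated CDS, its codon count,
#' length in sense codons, ENC (counts mode) and GC3.
#'
#' Per-gene ENC values are *not* capped at 61 by default: these values
#' feed regression analyses against length and expression, and truncating
#' the estimator at its boundary induces a spurious negative ENC~length
#' correlation in weakly biased genes (the capped shortfall shrinks with
#' gene length).  Under near-uniform usage individual genes can therefore
#' slightly exceed 61; cap at reporting time with `cap = TRUE` if the
#' strict \[1, 61\] range is needed.
#'
#' @param seqs Named character vector of validated CDS.
#' @param mode ENC mode, default `"counts"`.
#' @param cap Cap per-gene ENC at 61 (default `FALSE`; see Details).
#' @return `data.frame` with columns `gene`, `length_codons`, `enc`, `gc3`.
#' @export
gene_metrics <- function(seqs, mode = "counts", cap = FALSE) {
  m <- codon_count_matrix(seqs)
  if (any(m[, STOP_CODONS] > 0)) stop("internal stop codons present")
  m <- m[, , drop = FALSE]
  fmat <- family_homozygosity_matrix(m, mode)
  res <- enc_from_homozygosity(fmat, cap = cap)
  sense <- m[, SENSE_CODONS, drop = FALSE]
  third <- substring(SENSE_CODONS, 3, 3) %in% c("G", "C")
  gc3 <- rowSums(sense[, third, drop = FALSE]) / rowSums(sense)
  data.frame(
    gene = if (is.null(rownames(m))) as.character(seq_len(nrow(m))) else rownames(m),
    length_codons = as.integer(rowSums(sense)),
    enc = res$enc,
    gc3 = gc3,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Scaled per-amino-acid ENC (sENC-x)
#'
#' For each degenerate amino acid, the effective number of its codons
#' `ENC_x = 1/F` is rescaled to `(k - ENC_x)/(k - 1)` so that 0 means no
#' bias (uniform synonymous usage) and 1 means maximal bias (a single
#' codon used), comparably across degeneracy classes.  Values are clamped
#' to \[0, 1\]: under the counts-mode estimator sampling noise can push
#' `ENC_x` slightly outside \[1, k\].
#'
#' @param t A [codon_count_table()].
#' @param mode Homozygosity mode passed to the estimator.
#' @return Named numeric vector over the degenerate amino acids present
#'   (18 when all are usable); unusable families are dropped.
#' @export
senc_x <- function(t, mode = c("counts", "frequencies")) {
  mode <- match.arg(mode)
  stopifnot(inherits(t, "codon_count_table"))
  if (t$n_codons <= 0) stop("empty table: no codons counted")
  m <- matrix(t$counts, 1, 64, dimnames = list(NULL, CODONS))
  f <- family_homozygosity_matrix(m, mode)[1, ]
  k <- FAMILY_SIZE[DEGENERATE_AAS]
  enc_x <- 1 / f
  s <- (k - enc_x) / (k - 1)
  s <- pmin(pmax(s, 0), 1)
  s[!is.na(s)]
}

#' Transcripts per million (TPM)
#'
#' `TPM_i = 1e6 * (c_i/l_i) / sum_j (c_j/l_j)`: read counts are first
#' normalized by effective length, then scaled so each library sums to one
#' million.
#'
#' @param counts Non-negative read counts, one per gene.
#' @param lengths Positive effective lengths (nt), one per gene.
#' @return Numeric vector of TPM values summing to 1e6.
#' @export
tpm <- function(counts, lengths) {
  if (length(counts) != length(lengths)) stop("counts and lengths differ in length")
  if (any(lengths <= 0)) stop("effective lengths must be positive")
  if (all(counts == 0)) stop("all-zero counts: TPM undefined")
  rate <- counts / lengths
  1e6 * rate / sum(rate)
}

#' Relative adaptiveness weights for CAI
#'
#' Weights are per-family-rescaled RSCU of the reference set:
#' `w_ij = RSCU_ij / max_j RSCU_ij`, so the most used codon of every
#' family has weight 1.  Codons with zero count in the reference receive a
#' pseudocount of 0.5 before RSCU so that no weight is zero.  Amino acids
#' entirely absent from the reference get all weights 1, with a warning.
#'
#' @param reference A [codon_count_table()] pooled over the reference
#'   (highly expressed) gene set.
#' @return A `cai_weights` list: `w` (named vector over sense codons, all
#'   in (0, 1\]), `reference_n` (codons in the reference).
#' @references Sharp PM, Li WH (1987) The codon adaptation index. Nucleic
#'   Acids Res 15:1281-1295.
#' @export
cai_weights <- function(reference) {
  stopifnot(inherits(reference, "codon_count_table"))
  if (reference$n_codons <= 0) stop("empty reference table")
  counts <- reference$counts[SENSE_CODONS]
  aa <- GENETIC_CODE_TABLE[SENSE_CODONS]
  w <- stats::setNames(rep(NA_real_, length(SENSE_CODONS)), SENSE_CODONS)
  absent <- character(0)
  for (a in names(AA_FAMILIES)) {
    cols <- AA_FAMILIES[[a]]
    x <- counts[cols]
    if (sum(x) == 0) {
      w[cols] <- 1
      absent <- c(absent, a)
      next
    }
    x[x == 0] <- 0.5
    r <- x / sum(x)          # proportional to RSCU within the family
    w[cols] <- r / max(r)
  }
  if (length(absent)) {
    warning("amino acids absent from reference, weights set to 1: ",
            paste(absent, collapse = ", "))
  }
  structure(list(w = w, reference_n = reference$n_codons,
                 absent_aas = absent),
            class = "cai_weights")
}

#' Codon adaptation index (CAI)
#'
#' Geometric mean of the relative adaptiveness weights over a gene's
#' codons, excluding ATG, TGG and stops (non-degenerate codons carry no
#' information about synonymous choice):
#' `CAI = exp(sum_c x_c log w_c / sum_c x_c)`.
#'
#' @param gene A [codon_count_table()] for one gene.
#' @param w A [cai_weights()] object.
#' @return CAI in (0, 1\].
#' @export
cai <- function(gene, w) {
  stopifnot(inherits(gene, "codon_count_table"), inherits(w, "cai_weights"))
  countable <- informative_codons()
  x <- gene$counts[countable]
  n <- sum(x)
  if (n <= 0) stop("no countable codons for CAI")
  exp(sum(x * log(w$w[countable])) / n)
}

#' Per-gene CAI for a set of sequences
#'
#' @param seqs Named character vector of validated CDS.
#' @param w A [cai_weights()] object.
#' @return Named numeric vector of CAI values.
#' @export
cai_by_gene <- function(seqs, w) {
  m <- codon_count_matrix(seqs)
  countable <- informative_codons()
  x <- m[, countable, drop = FALSE]
  n <- rowSums(x)
  if (any(n <= 0)) stop("gene(s) with no countable codons for CAI")
  out <- exp(as.vector(x %*% log(w$w[countable])) / n)
  stats::setNames(out, rownames(m))
}

#' Preferred and avoided codons from an RSCU vector
#'
#' Codons used more often than expected under uniform synonymous usage
#' (RSCU > 1) are preferred; codons with RSCU < 1 are avoided; RSCU
#' exactly 1 is neither.
#'
#' @param r An `rscu_vector` from [rscu()].
#' @return List with character vectors `preferred` and `avoided`.
#' @export
preferred_codons <- function(r) {
  v <- as.numeric(r)
  names(v) <- names(r)
  list(
    preferred = names(v)[!is.na(v) & v > 1],
    avoided = names(v)[!is.na(v) & v < 1]
  )
}
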