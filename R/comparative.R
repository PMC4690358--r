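# Cross-species analyses: RSCU matrix assembly and hierarchical
# clustering, preferred-codon tallies, and the correlation / regression
# analyses relating codon usage to GC3, expression and protein length.

#' Assemble the species x informative-codon RSCU matrix
#'
#' Rows are species, columns the 59 informative codons in canonical order.
#' Missing RSCU values (amino acids absent from a species) are imputed
#' with the codon's column mean and recorded in the `mask` attribute;
#' species missing more than `max_missing` of their codons are excluded
#' with a warning rather than imputed wholesale.
#'
#' @param profiles Named list of `rscu_vector`s (one per species).
#' @param max_missing Maximum tolerated fraction of missing codons per
#'   species.
#' @return Numeric matrix (class `rscu_matrix`) with attributes `mask`
#'   (logical matrix of imputed cells) and `excluded` (character vector).
#' @export
build_rscu_matrix <- function(profiles, max_missing = 0.2) {
  if (length(profiles) < 2L) stop("need at least 2 species")
  if (is.null(names(profiles))) stop("profiles must be named by species")
  cods <- informative_codons()
  m <- t(vapply(profiles, function(r) as.numeric(r)[match(cods, names(r))],
                numeric(length(cods))))
  dimnames(m) <- list(names(profiles), cods)
  frac_missing <- rowMeans(is.na(m))
  excluded <- rownames(m)[frac_missing > max_missing]
  if (length(excluded)) {
    warning("species excluded (> ", max_missing * 100, "% missing codons): ",
            paste(excluded, collapse = ", "))
    m <- m[frac_missing <= max_missing, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("fewer than 2 species remain after exclusion")
  mask <- is.na(m)
  if (any(mask)) {
    cm <- colMeans(m, na.rm = TRUE)
    for (j in which(colSums(mask) > 0)) m[mask[, j], j] <- cm[j]
  }
  structure(m, mask = mask, excluded = excluded, class = c("rscu_matrix", "matrix"))
}

#' Hierarchical clustering of species on RSCU profiles
#'
#' Agglomerative clustering of the rows of an RSCU matrix under Euclidean
#' distance.  The default linkage is complete; average linkage (UPGMA) is
#' available via `linkage`.  Deterministic for a fixed input: distance ties
#' are broken by `stats::hclust`'s documented lowest-index rule.
#'
#' @param m Matrix from [build_rscu_matrix()] (any numeric matrix with row
#'   names works).
#' @param metric Distance metric passed to [stats::dist()].
#' @param linkage `"complete"` or `"average"`.
#' @return A `cub_dendrogram` list: `hclust`, `linkage`, `metric`,
#'   `dist` (the distance object).
#' @export
hierarchical_cluster <- function(m, metric = "euclidean",
                                 linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  if (nrow(m) < 2L) stop("need at least 2 rows to cluster")
  d <- stats::dist(m, method = metric)
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, linkage = linkage, metric = metric, dist = d),
            class = "cub_dendrogram")
}

#' @export
print.cub_dendrogram <- function(x, ...) {
  cat(sprintf("cub_dendrogram: %d leaves, %s linkage, %s distance\n",
              length(x$hclust$labels), x$linkage, x$metric))
  invisible(x)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths derive from the merge heights (ultrametric tree: the
#' cophenetic distance between two leaves equals their merge height).
#'
#' @param d A `cub_dendrogram`.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned instead.
#' @return The Newick string (invisibly when written to a file).
#' @export
dendrogram_newick <- function(d, path = NULL) {
  phy <- ape::as.phylo(d$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Top bipartition of a dendrogram
#'
#' Membership of the two clusters obtained by cutting the tree below its
#' last merge.
#'
#' @param d A `cub_dendrogram`.
#' @return Named integer vector of cluster labels (1 or 2) per leaf.
#' @export
top_split <- function(d) {
  stats::cutree(d$hclust, k = 2)
}

#' Tally of species preferring each codon
#'
#' For each informative codon, the number of species in which it is a
#' preferred codon (RSCU > 1).
#'
#' @param profiles Named list of `rscu_vector`s.
#' @return Named integer vector over the 59 informative codons.
#' @export
preferred_codon_tally <- function(profiles) {
  if (length(profiles) < 1L) stop("need at least 1 species")
  cods <- informative_codons()
  counts <- vapply(cods, function(cc) {
    sum(vapply(profiles, function(r) {
      v <- as.numeric(r)[match(cc, names(r))]
      isTRUE(v > 1)
    }, logical(1)))
  }, integer(1))
  counts
}

#' Pearson correlation with ordinary least-squares fit
#'
#' Fits `y ~ x` by OLS and reports the Pearson correlation, slope,
#' intercept, R squared and the two-sided F-test p-value of the
#' regression.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, each with nonzero
#'   variance.
#' @return A `regression_result` list: `pearson_r`, `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
pearson_regression <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("degenerate: need at least 3 complete observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("degenerate: zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  structure(
    list(pearson_r = unname(stats::cor(x, y)),
         slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = unname(sm$r.squared),
         p_value = unname(p),
         n = n),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("r = %.4f, slope = %.4g, intercept = %.4g, R2 = %.4f, p = %.3g, n = %d\n",
              x$pearson_r, x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

# run pearson_regression, returning an all-NA row instead of an error for
# degenerate inputs (flagged non-significant)
safe_regression <- function(x, y) {
  res <- tryCatch(pearson_regression(x, y), error = function(e) NULL)
  if (is.null(res)) {
    return(data.frame(pearson_r = NA_real_, slope = NA_real_, r_squared = NA_real_,
                      p_value = NA_real_, n = sum(is.finite(x) & is.finite(y))))
  }
  data.frame(pearson_r = res$pearson_r, slope = res$slope,
             r_squared = res$r_squared, p_value = res$p_value, n = res$n)
}

#' Per-codon correlation between codon frequency and overall CUB
#'
#' Regresses each informative codon's overall frequency (fraction of all
#' sense codons) on the species' negative ENC, so a positive correlation
#' means the codon is used more in more biased species.  Degenerate inputs
#' (a codon with constant frequency) are flagged non-significant.
#'
#' @param freq Species x codon matrix of overall codon fractions (rows sum
#'   to 1 over the 61 sense codons; only the 59 informative columns are
#'   used).
#' @param enc Numeric vector of species ENC values (same row order).
#' @param alpha Significance level for the `significant` flag.
#' @return `data.frame` with one row per informative codon: `codon`,
#'   `pearson_r`, `slope`, `r_squared`, `p_value`, `significant`.
#' @export
codon_cub_correlations <- function(freq, enc, alpha = 0.05) {
  if (length(enc) != nrow(freq)) stop("enc length must match rows of freq")
  if (nrow(freq) < 3L) stop("need at least 3 species")
  cods <- informative_codons()
  rows <- lapply(cods, function(cc) {
    res <- safe_regression(-enc, freq[, cc])
    cbind(data.frame(codon = cc, stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}

#' Per-amino-acid regression of sENC-x on ENC
#'
#' For each degenerate amino acid, regresses its sENC-x value on species
#' ENC across species; a negative slope means the amino acid's codon
#' usage grows more biased as overall bias increases.
#'
#' @param senc Species x amino-acid matrix of sENC-x values (18 columns
#'   when all degenerate amino acids are usable).
#' @param enc Numeric vector of species ENC values (same row order).
#' @param alpha Significance level for the `significant` flag.
#' @return `data.frame` with one row per amino acid: `amino_acid`,
#'   `mean_senc`, `pearson_r`, `slope`, `r_squared`, `p_value`,
#'   `significant`.
#' @export
senc_enc_regressions <- function(senc, enc, alpha = 0.05) {
  if (length(enc) != nrow(senc)) stop("enc length must match rows of senc")
  if (nrow(senc) < 3L) stop("need at least 3 species")
  rows <- lapply(colnames(senc), function(aa) {
    res <- safe_regression(enc, senc[, aa])
    cbind(data.frame(amino_acid = aa, mean_senc = mean(senc[, aa], na.rm = TRUE),
                     stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}

#' Species-level summary regressions
#'
#' The two figure-level summaries: the cross-species regression of ENC on
#' GC3, and the within-species gene-level Pearson correlation between CAI
#' and ENC (one correlation per species).
#'
#' @param species_metrics `data.frame` with columns `species`, `enc`,
#'   `gc3` (one row per species).
#' @param gene_metrics Optional `data.frame` with columns `species`,
#'   `cai`, `enc` (one row per gene) for the CAI~ENC part.
#' @return List with `enc_vs_gc3` (a `regression_result`) and
#'   `cai_vs_enc` (`data.frame` species, pearson_r, p_value, n; `NULL`
#'   when `gene_metrics` is absent).
#' @export
species_summary_regressions <- function(species_metrics, gene_metrics = NULL) {
  res <- list(
    enc_vs_gc3 = pearson_regression(species_metrics$gc3, species_metrics$enc),
    cai_vs_enc = NULL
  )
  if (!is.null(gene_metrics)) {
    rows <- lapply(sort(unique(gene_metrics$species)), function(sp) {
      sub <- gene_metrics[gene_metrics$species == sp, , drop = FALSE]
      r <- safe_regression(sub$cai, sub$enc)
      cbind(data.frame(species = sp, stringsAsFactors = FALSE),
            r[c("pearson_r", "p_value", "n")])
    })
    res$cai_vs_enc <- do.call(rbind, rows)
  }
  res
}

#' Gene-level correlates of codon usage bias
#'
#' The within-species analyses relating per-gene codon usage to protein
#' length and expression: Pearson correlation (with OLS p-value) of
#' negative ENC vs length, GC3 vs length, negative ENC vs TPM per
#' library, GC3 vs TPM per library, and negative ENC vs GC3.  Negative
#' ENC is used so that a positive correlation reads "more biased".
#' Expression analyses are reported only for the libraries present;
#' missing expression yields no row rather than a zero.
#'
#' @param genes `data.frame` with columns `gene`, `enc`, `gc3`,
#'   `length_codons`, and optionally one or more `tpm_<library>` columns.
#' @param species Label recorded in the output rows.
#' @param alpha Significance level for the `significant` flag.
#' @return `data.frame` with columns `analysis`, `species`, `pearson_r`,
#'   `p_value`, `n`, `significant`.
#' @export
gene_level_correlates <- function(genes, species = NA_character_, alpha = 0.05) {
  tpm_cols <- grep("^tpm_", names(genes), value = TRUE)
  analyses <- list(
    neg_enc_vs_length = list(x = genes$length_codons, y = -genes$enc),
    gc3_vs_length = list(x = genes$length_codons, y = genes$gc3),
    neg_enc_vs_gc3 = list(x = genes$gc3, y = -genes$enc)
  )
  for (col in tpm_cols) {
    lib <- sub("^tpm_", "", col)
    analyses[[paste0("neg_enc_vs_expression_", lib)]] <-
      list(x = genes[[col]], y = -genes$enc)
    analyses[[paste0("gc3_vs_expression_", lib)]] <-
      list(x = genes[[col]], y = genes$gc3)
  }
  rows <- lapply(names(analyses), function(an) {
    a <- analyses[[an]]
    r <- safe_regression(a$x, a$y)
    cbind(data.frame(analysis = an, species = species, stringsAsFactors = FALSE),
          r[c("pearson_r", "p_value", "n")])
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_value) & out$p_value < alpha
  out
}

#' Scatter plot with fitted regression line
#'
#' Minimal base-graphics export for the figure-style summaries.
#'
#' @param x,y Numeric vectors.
#' @param xlab,ylab,main Plot annotation.
#' @param path Optional PNG path; plots to the active device when `NULL`.
#' @return The `regression_result`, invisibly.
#' @export
plot_regression <- function(x, y, xlab = "x", ylab = "y", main = "", path = NULL) {
  res <- pearson_regression(x, y)
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(x, y, pch = 19, cex = 0.6, xlab = xlab, ylab = ylab, main = main)
  graphics::abline(res$intercept, res$slope, col = "red")
  graphics::mtext(sprintf("R2 = %.3f, p = %.2g", res$r_squared, res$p_value),
                  side = 3, line = 0, cex = 0.8)
  invisible(res)
}
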