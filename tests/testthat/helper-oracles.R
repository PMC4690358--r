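# Independent brute-force transcriptions of the defining formulas, kept
# deliberately separate from the package implementations so they can act
# as oracles: plain loops, no shared helpers.

# standard code lookup assembled by hand from the package's public table
# (the table itself is checked against hard-coded facts in
# test-genetic-code.R)
oracle_families <- function() {
  aa <- GENETIC_CODE_TABLE[GENETIC_CODE_TABLE != "*"]
  fams <- list()
  for (codon in names(aa)) fams[[aa[[codon]]]] <- c(fams[[aa[[codon]]]], codon)
  fams
}

oracle_rscu <- function(counts) {
  fams <- oracle_families()
  out <- c()
  for (aa in names(fams)) {
    fam <- fams[[aa]]
    tot <- 0
    for (codon in fam) tot <- tot + counts[[codon]]
    for (codon in fam) {
      out[[codon]] <- if (tot > 0) length(fam) * counts[[codon]] / tot else NA_real_
    }
  }
  out
}

oracle_enc <- function(counts, mode = "counts") {
  fams <- oracle_families()
  f_by_class <- list("2" = c(), "3" = c(), "4" = c(), "6" = c())
  for (aa in names(fams)) {
    fam <- fams[[aa]]
    k <- length(fam)
    if (k < 2) next
    n <- 0
    for (codon in fam) n <- n + counts[[codon]]
    if (n == 0) next
    sp2 <- 0
    for (codon in fam) sp2 <- sp2 + (counts[[codon]] / n)^2
    if (mode == "counts") {
      if (n < 2) next
      f <- (n * sp2 - 1) / (n - 1)
      if (f <= 0) next
    } else {
      f <- sp2
    }
    f_by_class[[as.character(k)]] <- c(f_by_class[[as.character(k)]], f)
  }
  fbar <- sapply(f_by_class, function(v) if (length(v)) mean(v) else NA_real_)
  if (is.na(fbar[["3"]]) && !is.na(fbar[["2"]]) && !is.na(fbar[["4"]])) {
    fbar[["3"]] <- (fbar[["2"]] + fbar[["4"]]) / 2
  }
  if (any(is.na(fbar))) {
    m <- mean(fbar, na.rm = TRUE)
    fbar[is.na(fbar)] <- m
  }
  e <- 2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] + 3 / fbar[["6"]]
  min(e, 61)
}

oracle_cai <- function(counts, w) {
  keep <- setdiff(names(counts), c("ATG", "TGG", "TAA", "TAG", "TGA"))
  logsum <- 0
  n <- 0
  for (codon in keep) {
    logsum <- logsum + counts[[codon]] * log(w[[codon]])
    n <- n + counts[[codon]]
  }
  exp(logsum / n)
}

# closed-form OLS / Pearson from the sum formulas, p from the F statistic
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  r <- (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  r2 <- r^2
  fstat <- r2 * (n - 2) / (1 - r2)
  p <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
  list(slope = slope, intercept = intercept, r = r, r2 = r2, p = p)
}

oracle_tpm <- function(counts, lengths) {
  rate <- c()
  for (i in seq_along(counts)) rate[i] <- counts[i] / lengths[i]
  out <- c()
  for (i in seq_along(rate)) out[i] <- 1e6 * rate[i] / sum(rate)
  out
}

# random codon count table over the sense codons (sparse allowed)
random_count_table <- function(lambda = 5, zero_frac = 0.2) {
  counts <- stats::rpois(61, lambda)
  counts[stats::runif(61) < zero_frac] <- 0L
  stats::setNames(counts, SENSE_CODONS)
}

# random in-frame CDS with a terminal stop and no internal stop
random_cds <- function(n_codons = 50) {
  paste0(paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = ""),
         sample(STOP_CODONS, 1))
}
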