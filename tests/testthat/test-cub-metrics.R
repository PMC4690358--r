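test_that("family homozygosity matches Wright's estimator by hand", {
  t <- codon_count_table(c(TTT = 3, TTC = 1))
  # counts mode: (4 * 0.625 - 1) / 3 = 0.5
  expect_equal(family_homozygosity(t, "F", mode = "counts"), 0.5)
  # frequencies mode, equal usage -> 0.5; single codon -> 1
  expect_equal(family_homozygosity(codon_count_table(c(TTT = 5, TTC = 5)),
                                   "F", mode = "frequencies"), 0.5)
  expect_equal(family_homozygosity(codon_count_table(c(TTT = 9)),
                                   "F", mode = "frequencies"), 1)
  # counts mode needs n >= 2
  expect_true(is.na(family_homozygosity(codon_count_table(c(TTT = 1)),
                                        "F", mode = "counts")))
})

test_that("ENC hits its theoretical extremes", {
  uniform <- codon_count_table(setNames(rep(10, 61), SENSE_CODONS))
  expect_equal(enc(uniform, mode = "frequencies")$enc, 61)

  one_per_aa <- setNames(rep(0, 61), SENSE_CODONS)
  for (aa in names(AA_FAMILIES)) one_per_aa[AA_FAMILIES[[aa]][1]] <- 50
  # Wright's composition at maximal bias: 2 + 9 + 1 + 5 + 3 = 20
  expect_equal(enc(codon_count_table(one_per_aa), mode = "frequencies")$enc, 20)

  # all class means 0.5 -> 2 + 18 + 2 + 10 + 6 = 38
  res <- enc(uniform, mode = "frequencies")
  fake <- c("2" = 0.5, "3" = 0.5, "4" = 0.5, "6" = 0.5)
  expect_equal(2 + 9 / fake[["2"]] + 1 / fake[["3"]] + 5 / fake[["4"]] +
                 3 / fake[["6"]], 38)
  expect_equal(unname(res$family_means),
               c(1 / 2, 1 / 3, 1 / 4, 1 / 6), tolerance = 1e-12)
})

test_that("ENC is scale-invariant in frequencies mode and capped at 61", {
  set.seed(7)
  for (i in 1:10) {
    counts <- random_count_table(lambda = 20, zero_frac = 0)
    e1 <- enc(codon_count_table(counts), mode = "frequencies")$enc
    e2 <- enc(codon_count_table(counts * 17), mode = "frequencies")$enc
    expect_equal(e1, e2, tolerance = 1e-12)
    expect_lte(e1, 61)
    expect_gte(e1, 1)
  }
})

test_that("ENC decreases as usage concentrates within families", {
  # interpolate between uniform and single-codon usage
  mix <- function(alpha) {
    counts <- setNames(rep(0, 61), SENSE_CODONS)
    for (aa in names(AA_FAMILIES)) {
      fam <- AA_FAMILIES[[aa]]
      k <- length(fam)
      p <- rep((1 - alpha) / k, k)
      p[1] <- p[1] + alpha
      counts[fam] <- 1000 * p
    }
    enc(codon_count_table(counts), mode = "frequencies")$enc
  }
  vals <- vapply(seq(0, 1, by = 0.1), mix, numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_equal(vals[1], 61)
  expect_equal(vals[length(vals)], 20)
})

test_that("senc_x scales bias to [0,1] with the documented endpoints", {
  uniform <- codon_count_table(setNames(rep(10, 61), SENSE_CODONS))
  s <- senc_x(uniform, mode = "frequencies")
  expect_length(s, 18)
  expect_equal(unname(s), rep(0, 18))

  one_per_aa <- setNames(rep(0, 61), SENSE_CODONS)
  for (aa in names(AA_FAMILIES)) one_per_aa[AA_FAMILIES[[aa]][1]] <- 50
  s1 <- senc_x(codon_count_table(one_per_aa), mode = "frequencies")
  expect_equal(unname(s1), rep(1, 18))

  # 2-fold family with F = 0.625: ENC_x = 1.6, sENC-x = 0.4
  t <- codon_count_table(c(TTT = 3, TTC = 1))
  expect_equal(senc_x(t, mode = "frequencies")[["F"]], 0.4)

  set.seed(11)
  for (i in 1:10) {
    s <- senc_x(codon_count_table(random_count_table()), mode = "counts")
    expect_true(all(s >= 0 & s <= 1))
  }
})

test_that("tpm normalizes by length then to one million", {
  expect_equal(tpm(c(10, 10), c(1000, 2000)),
               c(2e6 / 3, 1e6 / 3))
  expect_equal(tpm(c(5, 5, 5, 5), c(700, 700, 700, 700)), rep(250000, 4))
  set.seed(12)
  for (i in 1:10) {
    v <- tpm(rpois(20, 50), runif(20, 200, 3000))
    expect_equal(sum(v), 1e6)
  }
  expect_error(tpm(c(0, 0), c(100, 100)), "all-zero")
  expect_error(tpm(c(1, 1), c(100, 0)), "positive")
})

test_that("cai_weights rescale reference RSCU with family max 1", {
  # uniform reference -> all weights 1
  u <- cai_weights(codon_count_table(setNames(rep(4, 61), SENSE_CODONS)))
  expect_equal(unname(u$w), rep(1, 61))

  w <- suppressWarnings(cai_weights(codon_count_table(c(TTT = 30, TTC = 10, ATG = 5))))
  expect_equal(w$w[["TTT"]], 1)
  expect_equal(w$w[["TTC"]], 1 / 3)

  # zero-count codon within a present family gets the 0.5 pseudocount
  expect_gt(w$w[["TTC"]], 0)
  w2 <- suppressWarnings(cai_weights(codon_count_table(c(TTT = 10))))
  expect_equal(w2$w[["TTC"]], 0.5 / 10.5 / (10 / 10.5))
  expect_true(all(w2$w > 0 & w2$w <= 1))
  # absent amino acids -> weight 1 with warning
  expect_warning(cai_weights(codon_count_table(c(TTT = 10))), "absent")
})

test_that("cai is the geometric mean of weights over countable codons", {
  ref <- codon_count_table(setNames(rep(4, 61), SENSE_CODONS))
  w <- cai_weights(ref)
  gene <- codon_count_table(c(TTT = 10, GCT = 5, ATG = 3))
  expect_equal(cai(gene, w), 1)  # all weights 1

  # two codons with weights 0.5 and 0.125 -> sqrt(0.0625) = 0.25
  w2 <- w
  w2$w[["TTT"]] <- 0.5
  w2$w[["GCT"]] <- 0.125
  g2 <- codon_count_table(c(TTT = 1, GCT = 1))
  expect_equal(cai(g2, w2), 0.25)

  # ATG/TGG/stops are excluded from the geometric mean
  g3 <- codon_count_table(c(TTT = 1, GCT = 1, ATG = 50, TGG = 50))
  expect_equal(cai(g3, w2), 0.25)
  expect_error(cai(codon_count_table(c(ATG = 5)), w), "countable")

  # determinism
  expect_identical(cai(g2, w2), cai(g2, w2))
})

test_that("cai of the reference pool is at least that of random genes", {
  set.seed(13)
  biased <- setNames(rep(0.5, 61), SENSE_CODONS)
  for (aa in names(AA_FAMILIES)) {
    biased[AA_FAMILIES[[aa]][1]] <- 50
  }
  ref <- codon_count_table(biased)
  w <- cai_weights(ref)
  cai_ref <- cai(ref, w)
  for (i in 1:10) {
    g <- codon_count_table(random_count_table(zero_frac = 0))
    expect_gte(cai_ref, cai(g, w))
    expect_lte(cai(g, w), 1)
  }
})

test_that("preferred_codons applies strict RSCU thresholds", {
  r <- rscu(codon_count_table(c(TTT = 30, TTC = 10)))
  pc <- preferred_codons(r)
  expect_equal(pc$preferred, "TTT")
  expect_equal(pc$avoided, "TTC")

  u <- rscu(codon_count_table(setNames(rep(2, 61), SENSE_CODONS)))
  pcu <- preferred_codons(u)
  # RSCU exactly 1 everywhere: neither preferred nor avoided, except that
  # the two single-codon families always sit exactly at 1
  expect_length(setdiff(pcu$preferred, c("ATG", "TGG")), 0)
  expect_length(pcu$avoided, 0)

  r4 <- rscu(codon_count_table(c(GCT = 8)))
  pc4 <- preferred_codons(r4)
  expect_equal(pc4$preferred, "GCT")
  expect_setequal(pc4$avoided, c("GCA", "GCC", "GCG"))
})

test_that("gene_metrics reports per-gene length, ENC and GC3", {
  set.seed(14)
  genes <- setNames(replicate(5, random_cds(120)), paste0("g", 1:5))
  gm <- gene_metrics(genes, cap = TRUE)
  expect_equal(gm$gene, paste0("g", 1:5))
  expect_equal(gm$length_codons, rep(120L, 5))
  expect_true(all(gm$enc >= 1 & gm$enc <= 61))
  expect_true(all(gm$gc3 >= 0 & gm$gc3 <= 1))
  # per-gene values agree with the single-table entry points
  t1 <- count_codons(genes[[1]])
  expect_equal(gm$enc[1], enc(t1, mode = "counts")$enc)
  expect_equal(gm$gc3[1], gc_by_position(t1)[["gc3"]])
  # uncapped variant only differs where the estimator exceeds the cap
  gu <- gene_metrics(genes)
  expect_true(all(gu$enc[gu$enc <= 61] == gm$enc[gu$enc <= 61]))
  expect_true(all(gm$enc[gu$enc > 61] == 61))
})
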