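make_profiles <- function(counts_list) {
  lapply(counts_list, function(cc) rscu(codon_count_table(cc)))
}

test_that("build_rscu_matrix assembles 59 informative-codon columns", {
  set.seed(31)
  profiles <- make_profiles(list(
    sp1 = random_count_table(zero_frac = 0),
    sp2 = random_count_table(zero_frac = 0),
    sp3 = random_count_table(zero_frac = 0)
  ))
  m <- build_rscu_matrix(profiles)
  expect_equal(dim(m), c(3L, 59L))
  expect_equal(colnames(m), informative_codons())
  expect_false(anyNA(m))
  expect_false(any(attr(m, "mask")))

  # identical profiles give identical rows
  p2 <- profiles[c(1, 1, 2)]
  names(p2) <- c("a", "b", "c")
  m2 <- build_rscu_matrix(p2)
  expect_equal(unname(m2["a", ]), unname(m2["b", ]))
})

test_that("missing amino acids are imputed with column means and masked", {
  set.seed(32)
  counts <- random_count_table(zero_frac = 0)
  no_cys <- counts
  no_cys[AA_FAMILIES[["C"]]] <- 0   # Cys absent: TGT/TGC undefined
  profiles <- make_profiles(list(sp1 = counts, sp2 = counts, sp3 = no_cys))
  m <- build_rscu_matrix(profiles)
  mask <- attr(m, "mask")
  expect_equal(sum(mask["sp3", ]), 2L)
  expect_equal(m["sp3", "TGT"], mean(m[c("sp1", "sp2"), "TGT"]))

  # a species missing too many codons is excluded with a warning
  sparse <- counts
  for (aa in names(AA_FAMILIES)[1:10]) sparse[AA_FAMILIES[[aa]]] <- 0
  expect_warning(
    m3 <- build_rscu_matrix(make_profiles(list(sp1 = counts, sp2 = counts,
                                               sp3 = sparse))),
    "excluded")
  expect_equal(rownames(m3), c("sp1", "sp2"))
})

test_that("hierarchical clustering merges by Euclidean distance", {
  m <- matrix(0, 3, 59, dimnames = list(c("a", "b", "c"), informative_codons()))
  m["c", 1:2] <- c(3, 4)   # distance 5 from the identical pair
  d <- hierarchical_cluster(m)
  hc <- d$hclust
  # first merge joins the identical pair at height 0
  expect_equal(hc$height[1], 0)
  expect_equal(hc$height[2], 5)

  # permuting rows leaves the topology unchanged
  d2 <- hierarchical_cluster(m[c(3, 1, 2), ])
  expect_equal(sort(as.integer(table(top_split(d)))),
               sort(as.integer(table(top_split(d2)))))
  expect_equal(d2$hclust$height, hc$height)

  # two rows: single merge at their distance
  m2 <- m[c("a", "c"), ]
  d3 <- hierarchical_cluster(m2)
  expect_equal(d3$hclust$height, 5)

  # all-identical rows collapse at height 0
  d4 <- hierarchical_cluster(m[c("a", "b"), ][c(1, 2), ])
  expect_equal(d4$hclust$height, 0)
})

test_that("Newick export round-trips topology and heights", {
  set.seed(33)
  m <- matrix(rnorm(6 * 59), 6, 59,
              dimnames = list(paste0("sp", 1:6), informative_codons()))
  d <- hierarchical_cluster(m)
  tmp <- withr::local_tempfile(fileext = ".nwk")
  dendrogram_newick(d, tmp)
  tr <- ape::read.tree(tmp)
  expect_setequal(tr$tip.label, rownames(m))
  # cophenetic distances on the tree equal the merge heights
  coph_tree <- ape::cophenetic.phylo(tr)[rownames(m), rownames(m)]
  coph_hc <- as.matrix(stats::cophenetic(d$hclust))[rownames(m), rownames(m)]
  expect_equal(coph_tree, coph_hc, tolerance = 1e-8)
})

test_that("preferred_codon_tally counts species with RSCU > 1", {
  biased <- setNames(rep(1, 61), SENSE_CODONS)
  biased["GCT"] <- 50   # Ala family now dominated by GCT
  profiles <- make_profiles(list(s1 = biased, s2 = biased, s3 = biased))
  tally <- preferred_codon_tally(profiles)
  expect_length(tally, 59)
  expect_equal(tally[["GCT"]], 3L)
  expect_equal(tally[["GCA"]], 0L)   # avoided everywhere
  expect_true(all(tally <= 3L))
})

test_that("pearson_regression matches the closed-form normal equations", {
  r <- suppressWarnings(pearson_regression(c(0, 1, 2), c(0, 1, 2)))
  expect_equal(r$pearson_r, 1)
  expect_equal(r$slope, 1)

  r2 <- suppressWarnings(pearson_regression(c(0, 0.5, 1), c(1, 0.5, 0)))
  expect_equal(r2$pearson_r, -1)

  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 9)
  res <- pearson_regression(x, y)
  o <- oracle_ols(x, y)
  expect_equal(res$slope, o$slope, tolerance = 1e-12)
  expect_equal(res$intercept, o$intercept, tolerance = 1e-12)
  expect_equal(res$pearson_r, o$r, tolerance = 1e-12)
  expect_equal(res$r_squared, res$pearson_r^2, tolerance = 1e-12)
  expect_equal(res$p_value, o$p, tolerance = 1e-12)

  expect_error(pearson_regression(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(pearson_regression(c(1, 2), c(1, 2)), "degenerate")
})

test_that("codon_cub_correlations returns one row per informative codon", {
  set.seed(34)
  n_sp <- 8
  enc_vec <- seq(40, 61, length.out = n_sp)
  freq <- matrix(1 / 61, n_sp, 61, dimnames = list(NULL, SENSE_CODONS))
  # an A-ending codon rises as ENC falls (more biased species use it more)
  freq[, "AAA"] <- 1 / 61 + (61 - enc_vec) / 1000
  freq[, "AAG"] <- 1 / 61 - (61 - enc_vec) / 1000
  freq[, setdiff(SENSE_CODONS, c("AAA", "AAG"))] <-
    freq[, setdiff(SENSE_CODONS, c("AAA", "AAG"))] +
    matrix(rnorm(n_sp * 59, 0, 1e-4), n_sp, 59)
  res <- suppressWarnings(codon_cub_correlations(freq, enc_vec))
  expect_equal(nrow(res), 59)
  expect_gt(res$pearson_r[res$codon == "AAA"], 0.99)
  expect_lt(res$pearson_r[res$codon == "AAG"], -0.99)
  expect_true(res$significant[res$codon == "AAA"])
})

test_that("degenerate codon frequencies are flagged non-significant", {
  enc_vec <- c(40, 50, 60)
  freq <- matrix(1 / 61, 3, 61, dimnames = list(NULL, SENSE_CODONS))
  res <- codon_cub_correlations(freq, enc_vec)
  expect_true(all(!res$significant))
  expect_true(all(is.na(res$pearson_r)))
})

test_that("senc_enc_regressions reports one row per degenerate amino acid", {
  set.seed(35)
  n_sp <- 10
  enc_vec <- seq(40, 60, length.out = n_sp)
  senc <- matrix(runif(n_sp * 18, 0, 0.05), n_sp, 18,
                 dimnames = list(NULL, DEGENERATE_AAS))
  # Arg bias grows as ENC falls
  senc[, "R"] <- (61 - enc_vec) / 40
  res <- suppressWarnings(senc_enc_regressions(senc, enc_vec))
  expect_equal(nrow(res), 18)
  expect_lt(res$slope[res$amino_acid == "R"], 0)
  expect_true(res$significant[res$amino_acid == "R"])
  expect_equal(res$amino_acid[which.max(res$mean_senc)], "R")
})

test_that("species_summary_regressions covers ENC~GC3 and per-species CAI~ENC", {
  set.seed(36)
  sp <- data.frame(species = paste0("s", 1:6),
                   gc3 = seq(0.25, 0.5, length.out = 6))
  sp$enc <- 30 + 50 * sp$gc3 + rnorm(6, 0, 0.5)
  genes <- do.call(rbind, lapply(sp$species, function(s) {
    cai <- runif(30, 0.4, 0.9)
    data.frame(species = s, cai = cai, enc = 61 - 20 * cai + rnorm(30, 0, 1))
  }))
  res <- species_summary_regressions(sp, genes)
  expect_gt(res$enc_vs_gc3$pearson_r, 0.9)
  expect_equal(nrow(res$cai_vs_enc), 6)
  expect_true(all(res$cai_vs_enc$pearson_r < 0))

  expect_error(species_summary_regressions(
    data.frame(species = "a", gc3 = c(0.4, 0.4, 0.4), enc = c(50, 50, 50))),
    "degenerate")
})

test_that("gene_level_correlates reports the length/expression analyses", {
  set.seed(37)
  n <- 200
  len <- round(runif(n, 101, 1000))
  tpm_g <- rlnorm(n, 3, 1)
  gc3 <- 0.3 + 0.1 * scale(log(tpm_g))[, 1] + rnorm(n, 0, 0.02)
  genes <- data.frame(gene = paste0("g", 1:n), enc = runif(n, 45, 61),
                      gc3 = gc3, length_codons = len, tpm_gill = tpm_g)
  res <- gene_level_correlates(genes, species = "spX")
  expect_setequal(res$analysis,
                  c("neg_enc_vs_length", "gc3_vs_length", "neg_enc_vs_gc3",
                    "neg_enc_vs_expression_gill", "gc3_vs_expression_gill"))
  expect_gt(res$pearson_r[res$analysis == "gc3_vs_expression_gill"], 0.5)
  expect_true(res$significant[res$analysis == "gc3_vs_expression_gill"])

  # no expression columns -> no expression rows, not zeros
  res2 <- gene_level_correlates(genes[setdiff(names(genes), "tpm_gill")])
  expect_false(any(grepl("expression", res2$analysis)))
})
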