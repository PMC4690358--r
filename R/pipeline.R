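# End-to-end orchestration: validate -> filter -> per-species statistics
# -> RSCU matrix / clustering -> correlation analyses, with TSV/Newick
# outputs and a provenance log.

#' Pipeline run configuration
#'
#' @param fasta_dir Directory with one `<species>.fasta` CDS file per
#'   species.
#' @param ortholog_tsv Long-format ortholog table (see
#'   [read_ortholog_table()]).
#' @param expression_tsv Optional long-format expression table of the
#'   reference species (see [read_expression_table()]); drives CAI
#'   reference-set selection and the expression correlations.
#' @param reference_species Species whose expression table
#'   `expression_tsv` is; per-gene TPM columns are attached to this
#'   species' gene metrics.
#' @param out_dir Output directory.
#' @param min_codons ORF length filter (strict, codons).
#' @param min_coverage,min_avg_len Species quality thresholds.
#' @param reference_n CAI reference set size.
#' @param alpha Significance level for NS flags.
#' @param enc_mode ENC estimator mode for species-level statistics.
#' @param linkage Clustering linkage (`"complete"` or `"average"`).
#' @param seed Integer seed recorded in the provenance log (the pipeline
#'   itself is deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(fasta_dir, ortholog_tsv, out_dir,
                       expression_tsv = NULL, reference_species = NULL,
                       min_codons = 100L, min_coverage = 0.25,
                       min_avg_len = 500, reference_n = 50L, alpha = 0.05,
                       enc_mode = "counts",
                       linkage = "complete", seed = 1L) {
  stopifnot(min_codons > 0, min_coverage > 0, min_avg_len > 0, reference_n > 0)
  structure(
    list(fasta_dir = fasta_dir, ortholog_tsv = ortholog_tsv,
         expression_tsv = expression_tsv,
         reference_species = reference_species, out_dir = out_dir,
         min_codons = as.integer(min_codons), min_coverage = min_coverage,
         min_avg_len = min_avg_len, reference_n = as.integer(reference_n),
         alpha = alpha, enc_mode = enc_mode, linkage = linkage,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

#' Per-species codon usage profile
#'
#' Pools the codon counts of a species' validated CDS set and derives the
#' species-level statistics: codon frequencies, GC by position, RSCU,
#' ENC and sENC-x.  Species-level values are computed from the pooled
#' count table, not averaged over genes.
#'
#' @param seqs Named character vector of validated, length-filtered CDS.
#' @param enc_mode ENC estimator mode.
#' @return A `species_profile` list: `counts`, `rscu`, `enc` (an
#'   `enc_result`), `gc` (gc1/gc2/gc3), `senc`, `n_genes`, `n_codons`.
#' @export
species_profile <- function(seqs, enc_mode = "counts") {
  counts <- count_codons(seqs, scope = "species")
  structure(
    list(counts = counts,
         rscu = rscu(counts),
         enc = enc(counts, mode = enc_mode),
         gc = gc_by_position(counts),
         senc = senc_x(counts, mode = enc_mode),
         n_genes = length(seqs),
         n_codons = counts$n_codons),
    class = "species_profile"
  )
}

# rbind data.frames whose column sets differ; absent columns become NA
rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (cc in setdiff(cols, names(d))) d[[cc]] <- NA
    d[cols]
  })
  out <- do.call(rbind, dfs)
  rownames(out) <- NULL
  out
}

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full comparative codon-usage pipeline
#'
#' Executes validation, the ORF and species quality filters, per-species
#' and per-gene statistics, CAI against an expression-defined reference
#' set (when expression data are configured), RSCU-matrix clustering and
#' the correlation analyses.  All tabular outputs are TSV (6 significant
#' digits), the dendrogram is Newick, and a provenance log echoes the
#' configuration and the record counts at every filter step.  Reruns with
#' the same configuration overwrite deterministically.
#'
#' @param cfg A [run_config()].
#' @return Invisible list with the in-memory results (`quality`,
#'   `profiles`, `gene_metrics`, `cluster`, `correlations`, ...).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("cubkit pipeline run", format(Sys.time()),
                 "config:", utils::capture.output(utils::str(unclass(cfg))))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  ortho <- read_ortholog_table(cfg$ortholog_tsv)
  conserved_ids <- sort(unique(ortho$gene_id))
  quality <- species_quality_filter(ortho, conserved_ids,
                                    min_coverage = cfg$min_coverage,
                                    min_avg_len = cfg$min_avg_len)
  write_tsv(quality, file.path(cfg$out_dir, "species_quality.tsv"))
  passing <- quality$species[quality$passed]
  note("species in ortholog table: %d; passing quality filter: %d",
       nrow(quality), length(passing))

  fasta_files <- file.path(cfg$fasta_dir, paste0(passing, ".fasta"))
  missing <- !file.exists(fasta_files)
  if (any(missing)) {
    stop("stage prepare: missing FASTA for species: ",
         paste(passing[missing], collapse = ", "))
  }

  reference_ids <- NULL
  expr_tpm <- NULL
  if (!is.null(cfg$expression_tsv)) {
    expr <- read_expression_table(cfg$expression_tsv)
    expr_tpm <- expression_tpm(expr)
    reference_ids <- select_reference_set(expr, conserved_ids,
                                          n = cfg$reference_n)
    writeLines(reference_ids, file.path(cfg$out_dir, "cai_reference_genes.txt"))
    note("CAI reference set: %d genes", length(reference_ids))
  }

  profiles <- list()
  gene_rows <- list()
  for (i in seq_along(passing)) {
    sp <- passing[i]
    raw <- read_cds_fasta(fasta_files[i])
    val <- validate_cds_set(raw)
    kept <- filter_orfs(val$accepted, min_codons = cfg$min_codons)
    note("%s: %d sequences read, %d rejected (%s), %d pass ORF filter",
         sp, length(raw), nrow(val$rejected),
         paste(unique(val$rejected$reason), collapse = ","), length(kept))
    if (length(kept) == 0L) {
      note("%s: no usable sequences, skipped", sp)
      next
    }
    prof <- species_profile(kept, enc_mode = cfg$enc_mode)
    profiles[[sp]] <- prof
    write_codon_freq_tsv(prof$counts,
                         file.path(cfg$out_dir, paste0("codon_freq_", sp, ".tsv")))
    write_rscu_tsv(prof$rscu, file.path(cfg$out_dir, paste0("rscu_", sp, ".tsv")))
    gm <- gene_metrics(kept)
    gm$species <- sp
    if (!is.null(reference_ids)) {
      ref_seqs <- kept[intersect(names(kept), reference_ids)]
      if (length(ref_seqs) >= 2L) {
        w <- cai_weights(count_codons(ref_seqs, scope = "species"))
        gm$cai <- unname(cai_by_gene(kept, w))
      } else {
        note("%s: <2 reference genes recovered, CAI skipped", sp)
      }
    }
    if (!is.null(expr_tpm) && !is.null(cfg$reference_species) &&
        identical(sp, cfg$reference_species)) {
      idx <- match(gm$gene, expr_tpm$gene_id)
      for (col in setdiff(names(expr_tpm), "gene_id")) {
        gm[[col]] <- expr_tpm[[col]][idx]
      }
    }
    gene_rows[[sp]] <- gm
  }
  if (length(profiles) < 2L) stop("stage stats: fewer than 2 usable species")

  species_tab <- data.frame(
    species = names(profiles),
    enc = vapply(profiles, function(p) p$enc$enc, numeric(1)),
    gc1 = vapply(profiles, function(p) p$gc[["gc1"]], numeric(1)),
    gc2 = vapply(profiles, function(p) p$gc[["gc2"]], numeric(1)),
    gc3 = vapply(profiles, function(p) p$gc[["gc3"]], numeric(1)),
    n_genes = vapply(profiles, function(p) p$n_genes, numeric(1)),
    n_codons = vapply(profiles, function(p) p$n_codons, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  write_tsv(species_tab, file.path(cfg$out_dir, "species_metrics.tsv"))

  senc_mat <- t(vapply(profiles,
                       function(p) p$senc[match(DEGENERATE_AAS, names(p$senc))],
                       numeric(length(DEGENERATE_AAS))))
  colnames(senc_mat) <- DEGENERATE_AAS
  write_tsv(data.frame(species = rownames(senc_mat), senc_mat,
                       check.names = FALSE),
            file.path(cfg$out_dir, "senc_x.tsv"))

  gene_tab <- rbind_fill(gene_rows)
  write_tsv(gene_tab, file.path(cfg$out_dir, "gene_metrics.tsv"))

  rscu_profiles <- lapply(profiles, `[[`, "rscu")
  rmat <- build_rscu_matrix(rscu_profiles)
  write_rscu_matrix_tsv(rmat, file.path(cfg$out_dir, "rscu_matrix.tsv"))
  dend <- hierarchical_cluster(rmat, linkage = cfg$linkage)
  dendrogram_newick(dend, file.path(cfg$out_dir, "dendrogram.nwk"))
  dm <- as.matrix(dend$dist)
  write_tsv(data.frame(species = rownames(dm), dm, check.names = FALSE),
            file.path(cfg$out_dir, "distance_matrix.tsv"))
  note("clustering: %d species, %s linkage", nrow(rmat), dend$linkage)

  freq_mat <- t(vapply(profiles, function(p) {
    fr <- codon_frequencies(p$counts)
    stats::setNames(fr$per_thousand / 1000, fr$codon)
  }, numeric(length(SENSE_CODONS))))
  tally <- preferred_codon_tally(rscu_profiles)
  cub_cor <- codon_cub_correlations(freq_mat, species_tab$enc, alpha = cfg$alpha)
  fig3 <- cbind(data.frame(codon = names(tally),
                           n_species_preferred = as.integer(tally),
                           stringsAsFactors = FALSE),
                cub_cor[match(names(tally), cub_cor$codon),
                        c("pearson_r", "p_value", "significant")])
  write_tsv(fig3, file.path(cfg$out_dir, "preferred_codons.tsv"))

  senc_reg <- senc_enc_regressions(senc_mat, species_tab$enc, alpha = cfg$alpha)
  write_tsv(senc_reg, file.path(cfg$out_dir, "senc_enc_regressions.tsv"))

  summary_reg <- species_summary_regressions(
    species_tab,
    if ("cai" %in% names(gene_tab)) gene_tab else NULL
  )
  enc_gc3 <- summary_reg$enc_vs_gc3
  write_tsv(data.frame(analysis = "enc_vs_gc3",
                       pearson_r = enc_gc3$pearson_r, slope = enc_gc3$slope,
                       intercept = enc_gc3$intercept,
                       r_squared = enc_gc3$r_squared,
                       p_value = enc_gc3$p_value, n = enc_gc3$n),
            file.path(cfg$out_dir, "enc_vs_gc3.tsv"))
  if (!is.null(summary_reg$cai_vs_enc)) {
    write_tsv(summary_reg$cai_vs_enc, file.path(cfg$out_dir, "cai_vs_enc.tsv"))
  }

  corr_rows <- lapply(names(gene_rows), function(sp) {
    gene_level_correlates(gene_rows[[sp]], species = sp, alpha = cfg$alpha)
  })
  table2 <- do.call(rbind, corr_rows)
  write_tsv(table2, file.path(cfg$out_dir, "gene_level_correlates.tsv"))

  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  invisible(list(quality = quality, profiles = profiles,
                 species_metrics = species_tab, gene_metrics = gene_tab,
                 cluster = dend, rscu_matrix = rmat,
                 preferred = fig3, senc_regressions = senc_reg,
                 summary_regressions = summary_reg,
                 gene_level = table2,
                 reference_ids = reference_ids))
}
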