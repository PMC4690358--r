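# Seeded simulator of multi-species CDS cohorts with known mutational
# bias (GC3 target) and translational selection (expression-coupled
# "speed" and length-coupled "accuracy" codon preference), plus matching
# ortholog and expression tables.  The generator exists so that every
# pipeline stage can be exercised end-to-end with known ground truth.

# Average amino-acid composition of well-annotated proteomes (UniProt
# global frequencies, normalized); order = names(AA_FAMILIES).
DEFAULT_AA_COMPOSITION <- local({
  p <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93,
         E = 6.75, G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84,
         M = 2.42, F = 3.86, P = 4.70, S = 6.56, T = 5.34, W = 1.08,
         Y = 2.92, V = 6.87)
  p <- p / sum(p)
  p[names(AA_FAMILIES)]
})

# per-amino-acid split of each family into G/C-ending vs A/T-ending
# codons; with a log-linear weight on the third-position nucleotide all
# codons within a split share the same weight, so codon sampling reduces
# to a Bernoulli split choice plus a uniform pick within the split.
third_position_split <- local({
  aas <- names(AA_FAMILIES)
  gc_members <- matrix(NA_character_, length(aas), 3, dimnames = list(aas, NULL))
  at_members <- matrix(NA_character_, length(aas), 3, dimnames = list(aas, NULL))
  n_gc <- stats::setNames(integer(length(aas)), aas)
  n_at <- stats::setNames(integer(length(aas)), aas)
  for (aa in aas) {
    fam <- AA_FAMILIES[[aa]]
    third_gc <- substring(fam, 3, 3) %in% c("G", "C")
    g <- fam[third_gc]; a <- fam[!third_gc]
    n_gc[aa] <- length(g); n_at[aa] <- length(a)
    if (length(g)) gc_members[aa, seq_along(g)] <- g
    if (length(a)) at_members[aa, seq_along(a)] <- a
  }
  list(gc = gc_members, at = at_members, n_gc = n_gc, n_at = n_at)
})

# expected species GC3 (over all sense codons, incl. Met/Trp) under the
# log-linear third-position weight beta and amino-acid composition pi
expected_gc3 <- function(beta, aa_composition) {
  sp <- third_position_split
  aas <- names(AA_FAMILIES)
  q <- sp$n_gc[aas] * exp(beta) / (sp$n_at[aas] + sp$n_gc[aas] * exp(beta))
  q[sp$n_at[aas] == 0] <- 1   # Met, Trp always G-ending
  sum(aa_composition[aas] * q)
}

#' Calibrate the third-position bias weight for a GC3 target
#'
#' The codon-choice model weights each codon by `exp(beta)` when its third
#' position is G or C.  This solves for the `beta` whose expected species
#' GC3 (under the given amino-acid composition, no selection) equals
#' `gc3_target`, by 1-D root finding.
#'
#' @param gc3_target Target GC3 in (0, 1); must be achievable given that
#'   Met and Trp always contribute G-ending codons.
#' @param aa_composition Named 20-simplex over one-letter amino acids.
#' @return The calibrated `beta` (scalar).
#' @export
calibrate_gc3_beta <- function(gc3_target, aa_composition = DEFAULT_AA_COMPOSITION) {
  lo <- expected_gc3(-25, aa_composition)
  hi <- expected_gc3(25, aa_composition)
  if (gc3_target <= lo || gc3_target >= hi) {
    stop(sprintf("gc3_target %.3f infeasible: achievable range (%.3f, %.3f)",
                 gc3_target, lo, hi))
  }
  stats::uniroot(function(b) expected_gc3(b, aa_composition) - gc3_target,
                 interval = c(-25, 25), tol = 1e-8)$root
}

#' Simulation parameters for one species
#'
#' Bundles the generative knobs of the simulator.  `gc3_target` is the
#' mutational-bias dial (expected species GC3 with no selection; `NULL`
#' means uniform synonymous usage, i.e. no third-position bias at all).
#' `speed_s` couples codon choice to standardized log-expression and
#' `accuracy_a` to standardized log-length, each pushing codon choice
#' towards `speed_dir` / `accuracy_dir` (`"GC"` or `"AT"`) endings in
#' highly expressed / long genes respectively.
#'
#' @param species_id Species label.
#' @param n_genes Number of genes.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal law of gene
#'   length in codons (truncated below at `min_length_codons`).
#' @param min_length_codons Minimum gene length (codons).
#' @param aa_composition Named 20-simplex of amino-acid frequencies.
#' @param gc3_target Expected no-selection GC3, or `NULL` for none.
#' @param speed_s,accuracy_a Selection strengths (0 disables).
#' @param speed_dir,accuracy_dir `"GC"` or `"AT"`.
#' @param expr_meanlog,expr_sdlog Log-normal law of true expression.
#' @param library_sd Log-normal sd of per-library expression noise.
#' @param total_reads Sequencing depth per library.
#' @param seed Integer RNG seed for this species.
#' @return A `species_sim_params` list.
#' @export
species_sim_params <- function(species_id,
                               n_genes = 2000L,
                               gene_length_meanlog = log(300),
                               gene_length_sdlog = 0.35,
                               min_length_codons = 101L,
                               aa_composition = DEFAULT_AA_COMPOSITION,
                               gc3_target = 0.4,
                               speed_s = 0, speed_dir = c("GC", "AT"),
                               accuracy_a = 0, accuracy_dir = c("AT", "GC"),
                               expr_meanlog = log(20), expr_sdlog = 1.5,
                               library_sd = 0.15,
                               total_reads = 2e6,
                               seed = 1L) {
  speed_dir <- match.arg(speed_dir)
  accuracy_dir <- match.arg(accuracy_dir)
  stopifnot(n_genes >= 1L, is.null(gc3_target) ||
              (gc3_target > 0 && gc3_target < 1))
  aa_composition <- aa_composition / sum(aa_composition)
  if (!setequal(names(aa_composition), names(AA_FAMILIES))) {
    stop("aa_composition must be named by the 20 one-letter amino acids")
  }
  structure(
    list(species_id = species_id, n_genes = as.integer(n_genes),
         gene_length_meanlog = gene_length_meanlog,
         gene_length_sdlog = gene_length_sdlog,
         min_length_codons = as.integer(min_length_codons),
         aa_composition = aa_composition[names(AA_FAMILIES)],
         gc3_target = gc3_target,
         speed_s = speed_s, speed_dir = speed_dir,
         accuracy_a = accuracy_a, accuracy_dir = accuracy_dir,
         expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
         library_sd = library_sd, total_reads = total_reads,
         seed = as.integer(seed)),
    class = "species_sim_params"
  )
}

#' Generate one synthetic species
#'
#' For each gene, draws a length and a true expression level, then an
#' i.i.d. amino-acid sequence, and finally each codon from its synonymous
#' family with log-linear weight
#' `exp((beta + s*z_expr*d_s + a*z_len*d_a) * [third position is G/C])`,
#' where `beta` is calibrated so the no-selection species GC3 matches
#' `gc3_target`, `z_expr`/`z_len` are the standardized log-expression and
#' log-length of the gene, and `d` is +1 for GC-directed and -1 for
#' AT-directed selection.  Sequences get a terminal TAA stop.  Read
#' counts for three libraries (`dg`, `gill`, `hemo`) are Poisson draws
#' around length-weighted expression with per-library log-normal noise.
#' Fully reproducible from the seed.
#'
#' @param p A [species_sim_params()] object.
#' @return List with `sequences` (named character vector of CDS),
#'   `expression` (long-format table as in [read_expression_table()]),
#'   `gene_lengths_nt` (named, sense nucleotides), `truth` (the
#'   parameters plus the calibrated `beta` and true per-gene expression).
#' @export
generate_species <- function(p) {
  stopifnot(inherits(p, "species_sim_params"))
  set.seed(p$seed)
  beta <- if (is.null(p$gc3_target)) 0 else
    calibrate_gc3_beta(p$gc3_target, p$aa_composition)
  L <- pmax(p$min_length_codons,
            round(stats::rlnorm(p$n_genes, p$gene_length_meanlog,
                                p$gene_length_sdlog)))
  expr_true <- stats::rlnorm(p$n_genes, p$expr_meanlog, p$expr_sdlog)
  z_expr <- as.numeric(scale(log(expr_true)))
  z_len <- as.numeric(scale(log(L)))
  d_s <- if (p$speed_dir == "GC") 1 else -1
  d_a <- if (p$accuracy_dir == "GC") 1 else -1
  eta_gene <- beta + p$speed_s * d_s * z_expr + p$accuracy_a * d_a * z_len

  sp <- third_position_split
  aas <- names(AA_FAMILIES)
  aa_int <- stats::setNames(seq_along(aas), aas)
  gene_of_pos <- rep.int(seq_len(p$n_genes), L)
  n_pos <- length(gene_of_pos)
  aa_pos <- sample.int(length(aas), n_pos, replace = TRUE,
                       prob = p$aa_composition[aas])
  n_gc <- sp$n_gc[aas][aa_pos]
  n_at <- sp$n_at[aas][aa_pos]
  e_eta <- exp(eta_gene)[gene_of_pos]
  q_gc <- n_gc * e_eta / (n_at + n_gc * e_eta)
  is_gc <- stats::runif(n_pos) < q_gc
  codons <- character(n_pos)
  slot_gc <- ceiling(stats::runif(n_pos) * n_gc)
  slot_at <- ceiling(stats::runif(n_pos) * n_at)
  codons[is_gc] <- sp$gc[cbind(aa_pos[is_gc], slot_gc[is_gc])]
  codons[!is_gc] <- sp$at[cbind(aa_pos[!is_gc], slot_at[!is_gc])]
  seqs <- vapply(split(codons, gene_of_pos), paste, character(1), collapse = "")
  seqs <- paste0(seqs, "TAA")
  gene_ids <- sprintf("g%05d", seq_len(p$n_genes))
  names(seqs) <- gene_ids

  len_nt <- 3L * L
  libs <- c("dg", "gill", "hemo")
  expr_rows <- lapply(libs, function(lib) {
    noisy <- expr_true * stats::rlnorm(p$n_genes, 0, p$library_sd)
    lambda <- p$total_reads * (noisy * len_nt) / sum(noisy * len_nt)
    data.frame(gene_id = gene_ids, library_id = lib,
               read_count = stats::rpois(p$n_genes, lambda),
               effective_length_nt = len_nt, stringsAsFactors = FALSE)
  })
  expression <- do.call(rbind, expr_rows)

  truth <- c(unclass(p), list(beta = beta))
  truth$expr_true <- stats::setNames(expr_true, gene_ids)
  list(sequences = seqs, expression = expression,
       gene_lengths_nt = stats::setNames(len_nt, gene_ids), truth = truth)
}

#' Generate a multi-species cohort
#'
#' Generates each species from its own parameters (seeds derived
#' deterministically from the cohort seed via one `sample.int` draw),
#' shares conserved gene ids across species, and applies an optional
#' per-species dropout of genes to exercise the coverage filter.
#'
#' @param params_list List of [species_sim_params()]; species ids must be
#'   unique.  The `seed` field of each entry is overwritten from
#'   `cohort_seed`.
#' @param cohort_seed Integer master seed.
#' @param dropout Named numeric vector (species id -> fraction of genes
#'   dropped) or a single number applied to all; default 0.
#' @return A `cub_cohort` list: `species` (named list of
#'   [generate_species()] results), `ortholog_table` (long format),
#'   `conserved_ids`, `truth` (named list of per-species truth records).
#' @export
generate_cohort <- function(params_list, cohort_seed = 1L, dropout = 0) {
  ids <- vapply(params_list, `[[`, character(1), "species_id")
  if (anyDuplicated(ids)) stop("duplicate species ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  set.seed(cohort_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, length(params_list))
  if (length(dropout) == 1L && is.null(names(dropout))) {
    dropout <- stats::setNames(rep(dropout, length(ids)), ids)
  }
  species <- vector("list", length(params_list))
  names(species) <- ids
  ortho_rows <- list()
  all_gene_ids <- character(0)
  for (i in seq_along(params_list)) {
    p <- params_list[[i]]
    p$seed <- seeds[i]
    sp <- generate_species(p)
    dr <- if (ids[i] %in% names(dropout)) dropout[[ids[i]]] else 0
    if (dr > 0) {
      keep <- stats::runif(length(sp$sequences)) >= dr
      sp$sequences <- sp$sequences[keep]
      sp$gene_lengths_nt <- sp$gene_lengths_nt[keep]
      sp$expression <- sp$expression[sp$expression$gene_id %in% names(sp$sequences), ]
    }
    species[[i]] <- sp
    all_gene_ids <- union(all_gene_ids, names(sp$sequences))
    ortho_rows[[i]] <- data.frame(
      gene_id = names(sp$gene_lengths_nt), species = ids[i],
      length_nt = unname(sp$gene_lengths_nt), stringsAsFactors = FALSE)
  }
  conserved_ids <- sprintf("g%05d", seq_len(max(vapply(params_list, `[[`,
                                                       integer(1), "n_genes"))))
  structure(
    list(species = species,
         ortholog_table = do.call(rbind, ortho_rows),
         conserved_ids = conserved_ids,
         truth = lapply(species, `[[`, "truth")),
    class = "cub_cohort"
  )
}

#' Write a cohort to disk as pipeline inputs
#'
#' Writes one FASTA per species under `dir/fasta/`, the ortholog table,
#' one expression table per species under `dir/expression/`, and the
#' ground-truth parameter record as YAML.
#'
#' @param cohort A `cub_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "fasta"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "expression"), recursive = TRUE, showWarnings = FALSE)
  for (sp in names(cohort$species)) {
    write_cds_fasta(cohort$species[[sp]]$sequences,
                    file.path(dir, "fasta", paste0(sp, ".fasta")))
    write_expression_table(cohort$species[[sp]]$expression,
                           file.path(dir, "expression", paste0(sp, ".tsv")))
  }
  write_ortholog_table(cohort$ortholog_table, file.path(dir, "orthologs.tsv"))
  truth <- lapply(cohort$truth, function(t) {
    t$aa_composition <- as.list(t$aa_composition)
    t$expr_true <- NULL  # bulky; regenerable from the seed
    t
  })
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
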