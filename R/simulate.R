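# Synthetic two-group FPKM-like data with planted effects.
#
# Generation is copula-style: per-gene log2 abundances are drawn from a
# multivariate normal whose mean encodes the baseline plus any planted log2
# fold change (cancer group only) and whose correlation encodes the planted
# per-group gene-pair correlations (identity elsewhere); abundances are then
# 2^z minus the pseudocount, truncated at zero to mimic FPKM zeros.
# Correlations are therefore exact on the log2 scale and only approximate in
# raw space (the lognormal transform shrinks them slightly).
#
# Planted correlation blocks are strict 2x2 blocks embedded in an identity
# background; a gene may belong to at most one block so the ground truth
# stays unambiguous.

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror a 41-control / 471-tumor FPKM cohort with log2-scale
#' noise sd 0.5 around a baseline log2 mean of 5 (~32 FPKM).
#'
#' @param n_control,n_cancer Group sizes (each >= 3).
#' @param n_genes Total genes simulated.
#' @param planted_degs `NULL` or data frame with columns `gene`, `delta`
#'   (log2 fold change planted in the cancer group) and optionally
#'   `baseline` (per-gene control-side log2 mean; useful for strongly
#'   downregulated genes, which need a high baseline for the fold change to
#'   be recoverable above the pseudocount floor).
#' @param planted_pairs `NULL` or data frame with columns `gene_a`,
#'   `gene_b`, `rho_control`, `rho_cancer` (each `|rho| < 1`; a gene may
#'   appear in only one pair).
#' @param baseline_log2_mean Default log2-scale mean abundance.
#' @param noise_sd Log2-scale standard deviation (> 0).
#' @param pathways Named list of character vectors: pathway gene sets to
#'   emit alongside the matrix.
#' @param pseudocount Subtracted after exponentiation (with truncation at
#'   0); matches the analysis-side pseudocount so planted fold changes are
#'   recovered.
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   dataset exactly.
#' @param gene_ids Optional explicit gene IDs (length `n_genes`).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_control = 41, n_cancer = 471,
                              n_genes = 2000, planted_degs = NULL,
                              planted_pairs = NULL,
                              baseline_log2_mean = 5, noise_sd = 0.5,
                              pathways = list(), pseudocount = 1.0,
                              seed = 1L, gene_ids = NULL) {
  stopifnot(n_control >= 3, n_cancer >= 3, n_genes >= 1, noise_sd > 0,
            pseudocount >= 0, is.numeric(seed))
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("G%04d", seq_len(n_genes))
  }
  stopifnot(length(gene_ids) == n_genes, !anyDuplicated(gene_ids))
  if (!is.null(planted_degs)) {
    stopifnot(all(c("gene", "delta") %in% colnames(planted_degs)))
    bad <- setdiff(planted_degs$gene, gene_ids)
    if (length(bad)) stop("planted DEG gene(s) not in gene universe: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (anyDuplicated(planted_degs$gene)) {
      stop("duplicate planted DEG genes", call. = FALSE)
    }
    if (is.null(planted_degs$baseline)) {
      planted_degs$baseline <- NA_real_
    }
  }
  if (!is.null(planted_pairs)) {
    stopifnot(all(c("gene_a", "gene_b", "rho_control", "rho_cancer") %in%
                    colnames(planted_pairs)))
    bad <- setdiff(c(planted_pairs$gene_a, planted_pairs$gene_b), gene_ids)
    if (length(bad)) stop("planted pair gene(s) not in gene universe: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    rho <- c(planted_pairs$rho_control, planted_pairs$rho_cancer)
    if (any(abs(rho) >= 1)) {
      i <- which(abs(planted_pairs$rho_control) >= 1 |
                   abs(planted_pairs$rho_cancer) >= 1)[1]
      stop("planted correlation block ", planted_pairs$gene_a[i], "-",
           planted_pairs$gene_b[i],
           " is not positive definite (|rho| must be < 1)", call. = FALSE)
    }
    members <- c(planted_pairs$gene_a, planted_pairs$gene_b)
    dup <- unique(members[duplicated(members)])
    if (length(dup)) {
      stop("overlapping planted correlation blocks at gene(s): ",
           paste(dup, collapse = ", "),
           " (a gene may appear in only one planted pair)", call. = FALSE)
    }
  }
  miss <- setdiff(unique(unlist(pathways)), gene_ids)
  if (length(miss)) stop("pathway member(s) not in gene universe: ",
                         paste(head(miss, 5), collapse = ", "),
                         call. = FALSE)
  structure(list(n_control = as.integer(n_control),
                 n_cancer = as.integer(n_cancer),
                 n_genes = as.integer(n_genes),
                 planted_degs = planted_degs,
                 planted_pairs = planted_pairs,
                 baseline_log2_mean = baseline_log2_mean,
                 noise_sd = noise_sd, pathways = pathways,
                 pseudocount = pseudocount, seed = as.integer(seed),
                 gene_ids = gene_ids),
            class = "simulation_config")
}

#' Simulate a two-group FPKM-like dataset
#'
#' @param config A [simulation_config()].
#' @return List with `matrix` (genes x samples, non-negative), `groups`
#'   (named group assignment, controls first), `pathways` (named list of
#'   gene sets), and `ground_truth` (list with `log2fc` per gene — zero for
#'   unplanted genes — and `pairs`, the planted-pair table with
#'   `delta_rho = rho_cancer - rho_control`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_genes
  nc <- config$n_control
  nt <- config$n_cancer
  gene_ids <- config$gene_ids
  sample_ids <- c(sprintf("control_%03d", seq_len(nc)),
                  sprintf("cancer_%03d", seq_len(nt)))
  groups <- setNames(rep(c("control", "cancer"), c(nc, nt)), sample_ids)
  ctl_cols <- seq_len(nc)
  can_cols <- nc + seq_len(nt)

  e <- matrix(rnorm(n * (nc + nt)), nrow = n,
              dimnames = list(gene_ids, sample_ids))
  pp <- config$planted_pairs
  if (!is.null(pp) && nrow(pp)) {
    for (i in seq_len(nrow(pp))) {
      ia <- match(pp$gene_a[i], gene_ids)
      ib <- match(pp$gene_b[i], gene_ids)
      for (side in 1:2) {
        cols <- if (side == 1) ctl_cols else can_cols
        rho <- if (side == 1) pp$rho_control[i] else pp$rho_cancer[i]
        e[ib, cols] <- rho * e[ia, cols] +
          sqrt(1 - rho^2) * e[ib, cols]
      }
    }
  }

  baseline <- rep(config$baseline_log2_mean, n)
  delta <- rep(0, n)
  pd <- config$planted_degs
  if (!is.null(pd) && nrow(pd)) {
    idx <- match(pd$gene, gene_ids)
    delta[idx] <- pd$delta
    has_base <- !is.na(pd$baseline)
    baseline[idx[has_base]] <- pd$baseline[has_base]
  }
  z <- baseline + config$noise_sd * e
  z[, can_cols] <- z[, can_cols] + delta
  x <- pmax(2^z - config$pseudocount, 0)

  truth <- list(
    log2fc = setNames(delta, gene_ids),
    pairs = if (is.null(pp)) NULL else
      cbind(pp, delta_rho = pp$rho_cancer - pp$rho_control),
    groups = groups
  )
  list(matrix = x, groups = groups, pathways = config$pathways,
       ground_truth = truth, config = config)
}

#' Write a simulated dataset to disk
#'
#' Emits `expression.tsv`, `samples.tsv`, `sets.gmt` and
#' `ground_truth.tsv` under `out_dir`.
#'
#' @param sim Result of [simulate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(sim$matrix, file.path(out_dir, "expression.tsv"))
  write_sample_sheet(sim$groups, file.path(out_dir, "samples.tsv"))
  if (length(sim$pathways)) {
    write_gmt(sim$pathways, file.path(out_dir, "sets.gmt"))
  }
  gt <- data.frame(gene = names(sim$ground_truth$log2fc),
                   true_log2fc = unname(sim$ground_truth$log2fc))
  write.table(gt, file.path(out_dir, "ground_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

# Pathway names and sizes emulating a published top-10 KEGG table for a
# colon-cancer DEG set: (name, total genes in pathway, DEG members).
paper_shape <- function() {
  data.frame(
    name = c("neuroactive ligand-receptor interaction",
             "systemic lupus erythematosus",
             "cytokine-cytokine receptor interaction",
             "pathways in cancer", "bile secretion",
             "Wnt signaling pathway", "cell adhesion molecules",
             "metabolism of xenobiotics by cytochrome P450",
             "drug metabolism", "tight junction"),
    total = c(275L, 126L, 258L, 329L, 72L, 140L, 144L, 73L, 67L, 135L),
    uploaded = c(29L, 28L, 27L, 19L, 18L, 17L, 17L, 16L, 14L, 14L),
    stringsAsFactors = FALSE
  )
}

#' Generate the standard demonstration dataset
#'
#' A fully synthetic cohort shaped like the motivating study: 41 controls
#' and 471 tumors, 2000 genes, and ten pathway gene sets with realistic
#' sizes (275, 126, 258, 329, 72, 140, 144, 73, 67, 135 members). Planted
#' effects:
#' * per-pathway DEG members matching realistic uploaded counts
#'   (29, 28, 27, 19, 18, 17, 17, 16, 14, 14), each with `|log2FC| >= 2.6`;
#' * 20 strongly upregulated and 20 strongly downregulated background genes
#'   (`|log2FC|` in 5.5-11.8), outside all pathways;
#' * 12 correlation-shifted gene pairs (`|delta rho| = 1.0`: control rho
#'   +/-0.8 flipping to -/+0.2) inside six of the pathways, among planted
#'   DEG members.
#'
#' @param seed Integer seed driving all randomness.
#' @return A simulated dataset (see [simulate_dataset()]).
#' @export
make_paper_shaped_fixture <- function(seed = 1L) {
  shape <- paper_shape()
  n_genes <- 2000L
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  # disjoint pathway membership from the front of the gene list
  stopifnot(sum(shape$total) + 40 <= n_genes)
  offsets <- cumsum(c(0L, shape$total[-nrow(shape)]))
  pathways <- setNames(lapply(seq_len(nrow(shape)), function(i) {
    gene_ids[offsets[i] + seq_len(shape$total[i])]
  }), shape$name)

  set.seed(seed)
  # pathway DEG members: first `uploaded` genes of each set, alternating
  # direction, |delta| in [2.6, 5]
  pw_deg <- do.call(rbind, lapply(seq_len(nrow(shape)), function(i) {
    g <- pathways[[i]][seq_len(shape$uploaded[i])]
    sign <- rep(c(1, -1), length.out = length(g))
    data.frame(gene = g,
               delta = sign * stats::runif(length(g), 2.6, 5),
               stringsAsFactors = FALSE)
  }))
  bg <- gene_ids[sum(shape$total) + seq_len(40L)]
  top_up <- data.frame(gene = bg[1:20],
                       delta = seq(11.8, 8.5, length.out = 20))
  top_down <- data.frame(gene = bg[21:40],
                         delta = -seq(8.1, 5.5, length.out = 20))
  planted_degs <- rbind(pw_deg, top_up, top_down)
  # strongly downregulated genes sit on a high control-side baseline so the
  # planted fold change is not flattened by the pseudocount floor
  planted_degs$baseline <- ifelse(planted_degs$delta < 0,
                                  3.5 - planted_degs$delta, 5)

  # 12 shifted pairs in six pathways, two per pathway, among planted DEGs;
  # half flip +0.8 -> -0.2 (delta -1), half -0.2 -> +0.8 (delta +1)
  pair_pw <- c("bile secretion",
               "metabolism of xenobiotics by cytochrome P450",
               "drug metabolism", "Wnt signaling pathway",
               "cell adhesion molecules", "tight junction")
  planted_pairs <- do.call(rbind, lapply(seq_along(pair_pw), function(i) {
    members <- pathways[[pair_pw[i]]][1:4]  # planted DEG members
    flip <- i %% 2 == 0
    data.frame(gene_a = members[c(1, 3)], gene_b = members[c(2, 4)],
               rho_control = if (flip) c(-0.2, -0.2) else c(0.8, 0.8),
               rho_cancer = if (flip) c(0.8, 0.8) else c(-0.2, -0.2),
               stringsAsFactors = FALSE)
  }))

  cfg <- simulation_config(
    n_control = 41, n_cancer = 471, n_genes = n_genes,
    planted_degs = planted_degs, planted_pairs = planted_pairs,
    baseline_log2_mean = 5, noise_sd = 0.5, pathways = pathways,
    pseudocount = 1.0, seed = seed + 7919L, gene_ids = gene_ids
  )
  simulate_dataset(cfg)
}
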