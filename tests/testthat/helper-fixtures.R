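# Shared fixtures: published top-40 DEG table, pathway gene lists, and
# small matrix builders. All fixtures are built in code at test time.

# Top 20 up- and downregulated genes of the motivating colon-cancer cohort
# (gene symbol, log2 fold change cancer/control, p-value).
table1_records <- function() {
  up <- data.frame(
    gene_id = c("MAGEA3", "MAGEA6", "IGFL1", "PRSS56", "MAGEA12", "KLK6",
                "PAEP", "NOTUM", "PRR9", "KLK8", "SPRR2E", "PPBP",
                "SPRR1A", "MAGEA1", "FEZF1", "DKK4", "ZIC5", "KLK7",
                "CST1", "SPRR2D"),
    log2fc = c(11.81, 10.71, 10.60, 10.55, 10.16, 9.74, 9.67, 9.65, 9.51,
               9.28, 9.21, 9.21, 9.10, 9.07, 8.99, 8.93, 8.91, 8.87,
               8.58, 8.52),
    p_value = c(rep(0, 13), 1.58e-10, rep(0, 2), 3.71e-13, rep(0, 3)),
    stringsAsFactors = FALSE
  )
  down <- data.frame(
    gene_id = c("APOA4", "OTOP2", "APOC3", "SLC10A2", "APOA1", "MS4A10",
                "AQP8", "CA1", "APOB", "INSL5", "TMIGD1", "GUCA2B",
                "G6PC", "CPO", "KRTAP13-2", "PYY", "OTOP3", "BEST4",
                "SLC30A10", "CLDN8"),
    log2fc = -c(8.12, 7.95, 7.84, 7.16, 7.10, 7.07, 6.86, 6.58, 6.41,
                6.14, 6.07, 6.06, 6.02, 5.83, 5.75, 5.74, 5.73, 5.70,
                5.57, 5.55),
    p_value = 0,
    stringsAsFactors = FALSE
  )
  rbind(up, down)
}

# 17 Wnt-pathway DEGs of the motivating cohort
wnt_deg_genes <- function() {
  c("AXIN2", "DKK1", "DKK4", "FOSL1", "FZD10", "MMP7", "NKD1", "NKD2",
    "PRKCG", "SFRP1", "SFRP4", "SFRP5", "WIF1", "WNT11", "WNT2", "WNT3",
    "WNT7B")
}

# 11 correlation-shifted pairs of the xenobiotics-metabolism pathway,
# with their signed delta-CC values
xenobiotics_pairs <- function() {
  data.frame(
    gene_a = c("AKR1C4", "AKR1C4", "AKR1C4", "AKR1C4", "AKR1C4", "CYP3A4",
               "CYP3A4", "GSTA1", "GSTA2", "GSTA2", "SULT2A1"),
    gene_b = c("CYP3A4", "GSTA1", "GSTA2", "SULT2A1", "UGT1A1", "GSTA2",
               "SULT2A1", "UGT1A1", "UGT1A1", "SULT2A1", "UGT1A1"),
    cc_control = 0,  # per-group coefficients not printed; deltas are
    cc_cancer = 0,
    delta_cc = c(-0.97, -0.95, -0.93, -0.87, -0.72, -0.99, -0.96, -0.80,
                 -0.80, -0.99, -0.78),
    pathways = "metabolism of xenobiotics by cytochrome P450",
    stringsAsFactors = FALSE
  )
}

# published top-10 pathway table shape: names, total sizes, DEG counts
pathway_shape <- function() {
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

# small expression matrix with named genes/samples
toy_matrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

# 3-gene x 6-sample fixture with a frozen hand-computed Pearson oracle
pearson_fixture <- function() {
  mat <- toy_matrix(
    c(2, 4, 4, 6, 9, 11,
      1, 2, 2, 5, 4, 6,
      10, 8, 7, 6, 4, 1),
    c("gA", "gB", "gC"), paste0("s", 1:6)
  )
  expected <- matrix(
    c(1, 0.89588834874252266, -0.98418529233837471,
      0.89588834874252266, 1, -0.90057452926374770,
      -0.98418529233837471, -0.90057452926374770, 1),
    nrow = 3, dimnames = list(rownames(mat), rownames(mat))
  )
  list(mat = mat, expected = expected)
}

# textbook product-moment formula, written out (independent of stats::cor)
pearson_hand <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# exhaustive hypergeometric upper-tail oracle: enumerate all draws of
# deg_count genes from a universe of universe_size and count overlaps
hyper_enum <- function(deg_count, pathway_size, overlap, universe_size) {
  draws <- utils::combn(universe_size, deg_count)
  in_pathway <- seq_len(pathway_size)  # wlog the first genes
  hits <- colSums(matrix(draws %in% in_pathway, nrow = deg_count))
  mean(hits >= overlap)
}

# build a synthetic corr_matrix_pair directly from two matrices
fake_pair <- function(cc_control, cc_cancer, genes, pathway = "pw",
                      mask = NULL) {
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(cc_control), ncol(cc_control))
  }
  dimnames(cc_control) <- dimnames(cc_cancer) <- dimnames(mask) <-
    list(genes, genes)
  structure(list(pathway = pathway, genes = genes,
                 cc_control = cc_control, cc_cancer = cc_cancer,
                 mask = mask, space = "raw", method = "pearson"),
            class = "corr_matrix_pair")
}

# small two-group dataset for fast pipeline runs
small_sim <- function(seed = 1, n_control = 10, n_cancer = 30) {
  pathways <- list(pwA = sprintf("G%04d", 1:10),
                   pwB = sprintf("G%04d", 11:20))
  cfg <- simulation_config(
    n_control = n_control, n_cancer = n_cancer, n_genes = 30,
    planted_degs = data.frame(gene = sprintf("G%04d", c(1:6, 11:14)),
                              delta = c(3, -3, 4, -4, 3.5, 3, 5, -5, 3, 3),
                              baseline = c(5, 9, 5, 10, 5, 5, 5, 11, 5, 5)),
    planted_pairs = data.frame(gene_a = c("G0001", "G0011"),
                               gene_b = c("G0003", "G0013"),
                               rho_control = c(0.9, -0.3),
                               rho_cancer = c(-0.3, 0.9)),
    pathways = pathways, seed = seed
  )
  simulate_dataset(cfg)
}
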