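# End-to-end pipeline: DEG -> pathway overrepresentation (top 10) ->
# per-pathway delta-CC -> pair dedupe -> panel -> heatmaps. All thresholds,
# counts and input checksums are recorded in run_summary.json; TSV outputs
# are deterministic byte-for-byte for identical inputs and settings.

#' Run the full biomarker-discovery pipeline
#'
#' Accepts either in-memory objects or file paths for the three inputs.
#' Stages run in order: differential expression, pathway
#' overrepresentation of the pooled DEGs, per-pathway correlation-shift
#' analysis over the top pathways, pair deduplication, and panel assembly.
#'
#' @param expr Expression matrix, or path to its TSV.
#' @param groups Named group assignment, or path to the sample sheet TSV.
#' @param gene_sets Named list of pathway sets, or path to a GMT file.
#' @param out_dir Output directory (created if needed). Receives
#'   `degs.tsv`, `enrichment.tsv`, `pairs.tsv`, `panel.tsv`,
#'   `run_summary.json` and, when `make_plots`, `plots/<pathway>.{svg,png}`.
#' @param fc_cutoff,p_cutoff,top_n,pseudocount See [deg_config()].
#' @param top_pathways Number of top-ranked pathways carried into the
#'   correlation stage.
#' @param delta_cc_cutoff `|delta CC|` selection threshold.
#' @param corr_space,corr_method Correlation value space and method (see
#'   [correlation_matrix()]).
#' @param universe Enrichment universe policy (see [enrich_pathways()]).
#' @param make_plots Render per-pathway heatmaps (default `TRUE`).
#' @param seed Optional integer recorded in the run summary (the pipeline
#'   itself is deterministic; the seed matters when the inputs were
#'   simulated).
#' @return Invisibly, a list with every stage result: `degs`, `up`, `down`,
#'   `top_up`, `top_down`, `enrichment`, `top_pathway_names`, `pair_records`
#'   (pre-dedupe), `pairs` (deduplicated), `pair_genes`, `panel`,
#'   `matrices`, `summary`.
#' @export
run_pipeline <- function(expr, groups, gene_sets, out_dir,
                         fc_cutoff = 2.5, p_cutoff = 0.001, top_n = 20,
                         pseudocount = 1.0, top_pathways = 10,
                         delta_cc_cutoff = 0.70,
                         corr_space = c("raw", "log2"),
                         corr_method = c("pearson", "spearman"),
                         universe = c("intersection", "matrix"),
                         make_plots = TRUE, seed = NULL) {
  corr_space <- match.arg(corr_space)
  corr_method <- match.arg(corr_method)
  universe <- match.arg(universe)
  checksums <- list()
  if (is.character(expr)) {
    checksums$expression <- unname(tools::md5sum(expr))
    expr <- read_expression_matrix(expr)
  }
  if (is.character(groups) && length(groups) == 1 &&
      is.null(names(groups))) {
    checksums$sample_sheet <- unname(tools::md5sum(groups))
    groups <- read_sample_sheet(groups, expr)
  }
  if (is.character(gene_sets)) {
    checksums$gmt <- unname(tools::md5sum(gene_sets))
    gene_sets <- read_gmt(gene_sets)
  }
  validate_expression_matrix(expr)
  validate_sample_groups(groups, min_per_group = 3)
  if (!setequal(names(groups), colnames(expr))) {
    stop("sample sheet and matrix disagree on sample IDs", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg <- deg_config(fc_cutoff, p_cutoff, top_n, pseudocount)
  degs <- deg_table(expr, groups, cfg)
  sets <- filter_degs(degs, cfg)
  top_up <- top_n_by_fold(sets$up, cfg$top_n)
  top_down <- top_n_by_fold(sets$down, cfg$top_n)
  deg_genes <- c(sets$up$gene_id, sets$down$gene_id)

  enr <- enrich_pathways(gene_sets, deg_genes, rownames(expr),
                         universe = universe)
  top_enr <- rank_pathways(enr, top_pathways)
  top_sets <- gene_sets[top_enr$pathway]

  dc <- diffcorr_pathways(expr, groups, top_sets, deg_genes,
                          cutoff = delta_cc_cutoff, space = corr_space,
                          method = corr_method)
  pairs <- dedupe_pairs(dc$records)
  pair_genes <- genes_from_pairs(pairs)
  panel <- assemble_panel(top_up, top_down, pair_genes,
                          deg_records = degs, pair_records = pairs)

  write_tsv <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  write_tsv(degs, "degs.tsv")
  write_tsv(top_enr, "enrichment.tsv")
  write_tsv(pairs, "pairs.tsv")
  write_tsv(panel, "panel.tsv")

  if (make_plots && length(dc$matrices)) {
    plot_dir <- file.path(out_dir, "plots")
    dir.create(plot_dir, showWarnings = FALSE)
    for (nm in names(dc$matrices)) {
      plot_correlation_pair(dc$matrices[[nm]],
                            file.path(plot_dir, sanitize_filename(nm)))
    }
  }

  summary <- list(
    parameters = list(
      fc_cutoff = fc_cutoff, p_cutoff = p_cutoff, top_n = cfg$top_n,
      pseudocount = pseudocount, top_pathways = top_pathways,
      delta_cc_cutoff = delta_cc_cutoff, corr_space = corr_space,
      corr_method = corr_method, universe = universe, seed = seed
    ),
    inputs = list(
      n_genes = nrow(expr), n_samples = ncol(expr),
      n_control = sum(groups == "control"),
      n_cancer = sum(groups == "cancer"),
      n_gene_sets = length(gene_sets), checksums = checksums
    ),
    counts = list(
      n_up = nrow(sets$up), n_down = nrow(sets$down),
      n_top_up = length(top_up), n_top_down = length(top_down),
      n_pathways_tested = nrow(enr),
      n_pathways_corr = length(dc$matrices),
      n_pairs_raw = nrow(dc$records), n_pairs = nrow(pairs),
      n_pair_genes = length(pair_genes), panel_size = nrow(panel)
    )
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  invisible(list(degs = degs, up = sets$up, down = sets$down,
                 top_up = top_up, top_down = top_down, enrichment = enr,
                 top_pathway_names = top_enr$pathway,
                 pair_records = dc$records, pairs = pairs,
                 pair_genes = pair_genes, panel = panel,
                 matrices = dc$matrices, summary = summary))
}

sanitize_filename <- function(x) {
  gsub("_+", "_", gsub("[^A-Za-z0-9.-]+", "_", x))
}
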