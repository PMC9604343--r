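# Differential expression between cancer and control groups.
#
# Fold change is computed on raw group means with a pseudocount; the test is
# a per-gene Welch (unequal-variance) two-sample comparison on
# log2(value + pseudocount). This is a deliberately simple, fully specified
# stand-in for package-specific DE machinery: the cutoffs, not the test
# internals, drive the downstream correlation analysis.

#' Configuration for the differential-expression stage
#'
#' Defaults are the conventional significance criteria for this analysis:
#' `|log2FC| >= 2.50` (boundary inclusive) and `p < 0.001` (strict), with the
#' top 20 genes per direction reported.
#'
#' @param fc_cutoff Positive log2 fold-change cutoff (inclusive).
#' @param p_cutoff p-value cutoff in (0, 1) (exclusive).
#' @param top_n Number of genes per direction for the top lists.
#' @param pseudocount Positive value added before ratios and logs to guard
#'   against zero FPKM.
#' @return A list of class `deg_config`.
#' @export
deg_config <- function(fc_cutoff = 2.5, p_cutoff = 0.001, top_n = 20,
                       pseudocount = 1.0) {
  stopifnot(is.numeric(fc_cutoff), length(fc_cutoff) == 1, fc_cutoff > 0,
            is.numeric(p_cutoff), length(p_cutoff) == 1,
            p_cutoff > 0, p_cutoff < 1,
            is.numeric(top_n), length(top_n) == 1, top_n >= 1,
            is.numeric(pseudocount), length(pseudocount) == 1,
            pseudocount > 0)
  structure(list(fc_cutoff = fc_cutoff, p_cutoff = p_cutoff,
                 top_n = as.integer(top_n), pseudocount = pseudocount),
            class = "deg_config")
}

#' Per-gene log2 fold change (cancer over control)
#'
#' `log2((mean_cancer + pseudocount) / (mean_control + pseudocount))`,
#' computed on raw abundances. Always finite for valid input.
#'
#' @param mat Expression matrix (genes x samples).
#' @param groups Named group assignment covering the matrix samples.
#' @param pseudocount Positive pseudocount.
#' @return Named numeric vector, one log2FC per gene.
#' @export
compute_log2fc <- function(mat, groups, pseudocount = 1.0) {
  validate_expression_matrix(mat)
  gs <- group_samples(groups)
  if (!length(gs$control) || !length(gs$cancer)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  stopifnot(pseudocount > 0)
  m_cancer <- rowMeans(mat[, gs$cancer, drop = FALSE])
  m_control <- rowMeans(mat[, gs$control, drop = FALSE])
  log2((m_cancer + pseudocount) / (m_control + pseudocount))
}

# vectorised row variances (avoids a matrixStats dependency)
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

#' Per-gene Welch test p-values on the log2 scale
#'
#' A two-sided unequal-variance two-sample t test per gene on
#' `log2(value + pseudocount)`, with the Welch-Satterthwaite degrees of
#' freedom. Degenerate genes (zero variance in both groups) get `p = 1` when
#' the group means are equal and `p = 0` when they differ (perfect
#' separation).
#'
#' @inheritParams compute_log2fc
#' @return Named numeric vector of p-values in `[0, 1]`.
#' @export
compute_pvalues <- function(mat, groups, pseudocount = 1.0) {
  validate_expression_matrix(mat)
  gs <- group_samples(groups)
  n1 <- length(gs$cancer); n0 <- length(gs$control)
  if (n1 < 2 || n0 < 2) {
    stop("each group needs >= 2 samples for the test (control: ", n0,
         ", cancer: ", n1, ")", call. = FALSE)
  }
  y <- log2(mat + pseudocount)
  y1 <- y[, gs$cancer, drop = FALSE]
  y0 <- y[, gs$control, drop = FALSE]
  m1 <- rowMeans(y1); m0 <- rowMeans(y0)
  v1 <- row_vars(y1); v0 <- row_vars(y0)
  se2 <- v1 / n1 + v0 / n0
  tstat <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m0[degenerate], 1, 0)
  setNames(pmin(pmax(p, 0), 1), rownames(mat))
}

#' Full differential-expression table
#'
#' Combines fold change, p-value and the direction call. Direction is `up`
#' iff `log2fc >= fc_cutoff` and `p < p_cutoff`, `down` iff
#' `log2fc <= -fc_cutoff` and `p < p_cutoff`, otherwise `none`. An optional
#' Benjamini-Hochberg correction (off by default, matching the raw-p
#' convention of this analysis) replaces the p-value used for the call.
#'
#' @inheritParams compute_log2fc
#' @param config A [deg_config()].
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Data frame with columns `gene_id`, `log2fc`, `p_value`,
#'   (`p_adj` if requested) and `direction`.
#' @export
deg_table <- function(mat, groups, config = deg_config(),
                      p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  lfc <- compute_log2fc(mat, groups, config$pseudocount)
  p <- compute_pvalues(mat, groups, config$pseudocount)
  out <- data.frame(gene_id = rownames(mat), log2fc = unname(lfc),
                    p_value = unname(p), stringsAsFactors = FALSE)
  p_call <- out$p_value
  if (p_adjust == "BH") {
    out$p_adj <- p.adjust(out$p_value, method = "BH")
    p_call <- out$p_adj
  }
  out$direction <- call_direction(out$log2fc, p_call, config)
  out
}

call_direction <- function(log2fc, p_value, config) {
  ifelse(p_value < config$p_cutoff & log2fc >= config$fc_cutoff, "up",
  ifelse(p_value < config$p_cutoff & log2fc <= -config$fc_cutoff, "down",
         "none"))
}

#' Split DEG records into up- and downregulated sets
#'
#' Boundary semantics follow the stated criteria: the fold-change cutoff is
#' inclusive (`log2fc = 2.50` passes at cutoff 2.50), the p cutoff strict
#' (`p = 0.001` fails at cutoff 0.001). The two sets are disjoint by
#' construction.
#'
#' @param records Data frame with `gene_id`, `log2fc`, `p_value` columns.
#' @param config A [deg_config()].
#' @return List with data frames `up` and `down`.
#' @export
filter_degs <- function(records, config = deg_config()) {
  stopifnot(all(c("gene_id", "log2fc", "p_value") %in% colnames(records)))
  direction <- call_direction(records$log2fc, records$p_value, config)
  list(up = records[direction == "up", , drop = FALSE],
       down = records[direction == "down", , drop = FALSE])
}

#' Top-N genes ranked by absolute fold change
#'
#' Sorts by `|log2fc|` descending, ties broken by gene symbol ascending, and
#' returns at most `n` gene IDs.
#'
#' @param records Data frame of DEG records already filtered to one
#'   direction.
#' @param n Number of genes to return.
#' @param direction Optional `"up"`/`"down"` filter applied to `records`
#'   (sign of `log2fc`) before ranking.
#' @return Character vector of gene IDs, best first.
#' @export
top_n_by_fold <- function(records, n, direction = NULL) {
  stopifnot(all(c("gene_id", "log2fc") %in% colnames(records)))
  if (!is.null(direction)) {
    direction <- match.arg(direction, c("up", "down"))
    keep <- if (direction == "up") records$log2fc > 0 else records$log2fc < 0
    records <- records[keep, , drop = FALSE]
  }
  ord <- order(-abs(records$log2fc), records$gene_id)
  head(records$gene_id[ord], n)
}

#' Linear fold change from a log2 fold change
#'
#' @param log2fc Finite numeric vector.
#' @return `2^log2fc`.
#' @export
fold_change <- function(log2fc) {
  stopifnot(all(is.finite(log2fc)))
  2^log2fc
}
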