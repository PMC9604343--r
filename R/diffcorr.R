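# Differential gene-pair correlation (delta-CC). For each pathway the
# DEG members measured in the matrix are correlated pairwise within each
# group; delta CC = CC_cancer - CC_control, and pairs with |delta CC| at or
# above the cutoff (default 0.70) are called correlation-shifted.
#
# Correlation is Pearson on raw abundances by default; Spearman and the
# log2(x + 1) value space are available because raw-space Pearson is
# sensitive to the heavy right tail of FPKM data.

#' Pathway genes eligible for the correlation stage
#'
#' The lexically sorted intersection of the pathway's members, the DEG set,
#' and the genes measured in the matrix.
#'
#' @param gene_set A pathway set (list with `genes`) or character vector.
#' @param degs Character vector of DEG symbols.
#' @param mat Expression matrix.
#' @return Sorted character vector (possibly length < 2; callers skip such
#'   pathways).
#' @export
pathway_gene_subset <- function(gene_set, degs, mat) {
  genes <- if (is.character(gene_set)) gene_set else gene_set$genes
  sort(intersect(intersect(genes, degs), rownames(mat)))
}

#' Within-group gene-gene correlation matrix with validity mask
#'
#' Pearson (or Spearman) correlation of each gene pair over the given
#' samples, in raw or log2(x + 1) space. Any pair involving a zero-variance
#' gene is masked invalid (`NA` in the matrix, `FALSE` in the mask) rather
#' than silently dropped.
#'
#' @param mat Expression matrix.
#' @param genes Genes to correlate (rows of `mat`).
#' @param sample_ids Samples of one group (>= 3 required).
#' @param space `"raw"` (default) or `"log2"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `cc` (symmetric matrix, unit diagonal where defined)
#'   and `mask` (logical matrix, `TRUE` where the entry is valid).
#' @export
correlation_matrix <- function(mat, genes, sample_ids,
                               space = c("raw", "log2"),
                               method = c("pearson", "spearman")) {
  space <- match.arg(space)
  method <- match.arg(method)
  if (length(sample_ids) < 3) {
    stop("need >= 3 samples to estimate correlations (got ",
         length(sample_ids), ")", call. = FALSE)
  }
  missing <- setdiff(genes, rownames(mat))
  if (length(missing)) {
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- mat[genes, sample_ids, drop = FALSE]
  if (space == "log2") x <- log2(x + 1)
  ok <- row_vars(x) > 0
  cc <- suppressWarnings(cor(t(x), method = method))
  mask <- outer(ok, ok, "&")
  cc[!mask] <- NA_real_
  dimnames(cc) <- dimnames(mask) <- list(genes, genes)
  list(cc = cc, mask = mask)
}

#' Paired control/cancer correlation matrices for one pathway
#'
#' @param mat Expression matrix.
#' @param groups Group assignment.
#' @param genes Ordered gene list (typically [pathway_gene_subset()]).
#' @param pathway Pathway name carried into downstream records.
#' @inheritParams correlation_matrix
#' @return Object of class `corr_matrix_pair`: list with `pathway`, `genes`,
#'   `cc_control`, `cc_cancer`, `mask` (valid in both groups), `space`,
#'   `method`.
#' @export
corr_matrix_pair <- function(mat, groups, genes, pathway = "",
                             space = c("raw", "log2"),
                             method = c("pearson", "spearman")) {
  space <- match.arg(space)
  method <- match.arg(method)
  gs <- group_samples(groups)
  ctl <- correlation_matrix(mat, genes, gs$control, space, method)
  can <- correlation_matrix(mat, genes, gs$cancer, space, method)
  structure(list(pathway = pathway, genes = genes,
                 cc_control = ctl$cc, cc_cancer = can$cc,
                 mask = ctl$mask & can$mask,
                 space = space, method = method),
            class = "corr_matrix_pair")
}

#' Delta-CC matrix for a correlation pair
#'
#' Elementwise `cc_cancer - cc_control`; entries masked in either group are
#' `NA`. Values are bounded in `[-2, 2]`.
#'
#' @param pair A `corr_matrix_pair`.
#' @return List with `delta` (matrix) and `mask` (logical matrix).
#' @export
delta_cc_matrix <- function(pair) {
  stopifnot(inherits(pair, "corr_matrix_pair"))
  if (!identical(dim(pair$cc_control), dim(pair$cc_cancer))) {
    stop("control and cancer correlation matrices differ in shape",
         call. = FALSE)
  }
  delta <- pair$cc_cancer - pair$cc_control
  delta[!pair$mask] <- NA_real_
  list(delta = delta, mask = pair$mask)
}

#' Select correlation-shifted gene pairs
#'
#' Returns exactly the unordered, unmasked pairs with
#' `|delta_cc| >= cutoff` (boundary inclusive). Each record keeps the signed
#' per-group coefficients and the source pathway.
#'
#' @param pair A `corr_matrix_pair`.
#' @param cutoff Non-negative threshold on `|delta_cc|` (default 0.70).
#' @return Data frame with columns `gene_a`, `gene_b` (lexically ordered
#'   within each row), `cc_control`, `cc_cancer`, `delta_cc`, `pathways`.
#' @export
select_shifted_pairs <- function(pair, cutoff = 0.70) {
  stopifnot(inherits(pair, "corr_matrix_pair"), cutoff >= 0)
  d <- delta_cc_matrix(pair)
  idx <- which(upper.tri(d$delta) & d$mask & !is.na(d$delta) &
                 abs(d$delta) >= cutoff, arr.ind = TRUE)
  if (!nrow(idx)) return(empty_pair_records())
  g1 <- pair$genes[idx[, 1]]
  g2 <- pair$genes[idx[, 2]]
  rec <- data.frame(
    gene_a = pmin(g1, g2), gene_b = pmax(g1, g2),
    cc_control = pair$cc_control[idx],
    cc_cancer = pair$cc_cancer[idx],
    delta_cc = d$delta[idx],
    pathways = pair$pathway,
    stringsAsFactors = FALSE
  )
  rec[order(rec$gene_a, rec$gene_b), , drop = FALSE]
}

empty_pair_records <- function() {
  data.frame(gene_a = character(0), gene_b = character(0),
             cc_control = numeric(0), cc_cancer = numeric(0),
             delta_cc = numeric(0), pathways = character(0),
             stringsAsFactors = FALSE)
}

#' Run the correlation-shift stage over a list of pathways
#'
#' For each pathway, restricts to DEG members measured in the matrix, skips
#' pathways with fewer than two eligible genes (with a warning), computes
#' the paired correlation matrices, and collects the shifted pairs. A pair
#' may appear under several pathways; deduplication is deferred to the panel
#' stage.
#'
#' @param mat Expression matrix.
#' @param groups Group assignment (each group >= 3 samples).
#' @param gene_sets Named list of pathway sets.
#' @param degs Character vector of DEG symbols.
#' @param cutoff `|delta_cc|` selection threshold.
#' @inheritParams correlation_matrix
#' @return List with `records` (row-bound shifted-pair data frame) and
#'   `matrices` (named list of `corr_matrix_pair`, one per retained
#'   pathway).
#' @export
diffcorr_pathways <- function(mat, groups, gene_sets, degs, cutoff = 0.70,
                              space = c("raw", "log2"),
                              method = c("pearson", "spearman")) {
  space <- match.arg(space)
  method <- match.arg(method)
  matrices <- list()
  records <- list()
  for (i in seq_along(gene_sets)) {
    name <- if (!is.null(names(gene_sets))) names(gene_sets)[[i]] else
      as.character(i)
    genes <- pathway_gene_subset(gene_sets[[i]], degs, mat)
    if (length(genes) < 2) {
      warning("pathway '", name, "' has ", length(genes),
              " eligible gene(s); skipping (no pairs possible)",
              call. = FALSE)
      next
    }
    cmp <- corr_matrix_pair(mat, groups, genes, pathway = name,
                            space = space, method = method)
    matrices[[name]] <- cmp
    records[[name]] <- select_shifted_pairs(cmp, cutoff)
  }
  recs <- if (length(records)) do.call(rbind, c(records,
                                                make.row.names = FALSE))
          else empty_pair_records()
  list(records = recs, matrices = matrices)
}
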