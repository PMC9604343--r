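# Pathway overrepresentation of the pooled DEG set: one-sided hypergeometric
# (Fisher exact upper tail) against a gene universe. The default universe is
# the genes measured in the matrix that belong to at least one pathway set,
# which avoids inflating significance with unmeasured genes.

#' One-sided hypergeometric overrepresentation p-value
#'
#' `P(X >= overlap)` for `X ~ Hypergeom(universe_size, pathway_size,
#' deg_count)`: the probability of drawing at least `overlap` pathway genes
#' when `deg_count` genes are sampled without replacement from a universe of
#' `universe_size` genes of which `pathway_size` are in the pathway.
#'
#' @param deg_count Number of query (DEG) genes in the universe.
#' @param pathway_size Number of pathway genes in the universe.
#' @param overlap Observed intersection size.
#' @param universe_size Total genes in the universe.
#' @return p-value in (0, 1]; `overlap = 0` always gives 1.
#' @export
overrepresentation_p <- function(deg_count, pathway_size, overlap,
                                 universe_size) {
  counts <- c(deg_count = deg_count, pathway_size = pathway_size,
              overlap = overlap, universe_size = universe_size)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("all counts must be non-negative integers", call. = FALSE)
  }
  if (overlap > min(deg_count, pathway_size) ||
      max(deg_count, pathway_size) > universe_size) {
    stop(sprintf(
      "inconsistent counts: overlap %d, deg_count %d, pathway_size %d, universe_size %d",
      overlap, deg_count, pathway_size, universe_size), call. = FALSE)
  }
  phyper(overlap - 1, pathway_size, universe_size - pathway_size, deg_count,
         lower.tail = FALSE)
}

#' Score overrepresentation of a DEG set in each pathway
#'
#' Counts are taken after restricting every set to the gene universe, so
#' `uploaded_count <= min(pathway_size, deg_count)` by construction. Up- and
#' downregulated DEGs are expected to be pooled into one query set.
#'
#' @param gene_sets Named list of pathway sets (see [read_gmt()]).
#' @param degs Character vector of DEG symbols (the pooled query set).
#' @param matrix_genes Character vector of genes measured in the expression
#'   matrix.
#' @param universe `"intersection"` (default): matrix genes belonging to at
#'   least one pathway set; `"matrix"`: all matrix genes.
#' @param p_adjust `"none"` (default) or `"BH"` for an extra `p_adj` column.
#' @return Data frame with one row per pathway: `pathway`, `uploaded_count`,
#'   `pathway_size`, `universe_size`, `deg_count`, `p_value`.
#' @export
enrich_pathways <- function(gene_sets, degs, matrix_genes,
                            universe = c("intersection", "matrix"),
                            p_adjust = c("none", "BH")) {
  universe <- match.arg(universe)
  p_adjust <- match.arg(p_adjust)
  degs <- unique(degs)
  set_genes <- lapply(gene_sets, function(s) {
    if (is.character(s)) unique(s) else unique(s$genes)
  })
  univ <- switch(universe,
    intersection = intersect(matrix_genes, unique(unlist(set_genes))),
    matrix = unique(matrix_genes)
  )
  if (!length(univ)) stop("empty gene universe", call. = FALSE)
  q <- intersect(degs, univ)
  res <- lapply(seq_along(set_genes), function(i) {
    pw <- intersect(set_genes[[i]], univ)
    ov <- intersect(pw, q)
    data.frame(
      pathway = if (!is.null(names(gene_sets))) names(gene_sets)[[i]] else
        as.character(i),
      uploaded_count = length(ov),
      pathway_size = length(pw),
      universe_size = length(univ),
      deg_count = length(q),
      p_value = overrepresentation_p(length(q), length(pw), length(ov),
                                     length(univ)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  if (p_adjust == "BH") out$p_adj <- p.adjust(out$p_value, method = "BH")
  out
}

#' Rank enrichment results and keep the top k
#'
#' Ascending p-value; ties broken by larger uploaded count, then pathway
#' name.
#'
#' @param results Data frame from [enrich_pathways()].
#' @param top_k Number of pathways to keep.
#' @return The top `top_k` rows in rank order.
#' @export
rank_pathways <- function(results, top_k = 10) {
  stopifnot(all(c("pathway", "uploaded_count", "p_value") %in%
                  colnames(results)))
  ord <- order(results$p_value, -results$uploaded_count, results$pathway)
  head(results[ord, , drop = FALSE], top_k)
}
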