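# Panel assembly: deduplicate shifted pairs across pathways, pull out the
# genes they involve, and take the union with the top up- and downregulated
# gene lists. Genes are never double-counted; source tags record where each
# gene came from.

#' Deduplicate shifted pairs across pathways
#'
#' One record per unordered gene pair. Pathway tags are merged
#' (semicolon-joined, sorted). If the same pair was selected with different
#' delta values under different pathways (possible when masking differs),
#' the record keeps the coefficients of the maximum-`|delta_cc|` occurrence
#' and the observed range is reported in a message.
#'
#' @param records Data frame of shifted-pair records
#'   (see [select_shifted_pairs()]).
#' @return Deduplicated data frame, sorted by `gene_a`, `gene_b`, with an
#'   extra `n_pathways` column. Idempotent.
#' @export
dedupe_pairs <- function(records) {
  if (!nrow(records)) {
    out <- empty_pair_records()
    out$n_pathways <- integer(0)
    return(out)
  }
  a <- pmin(records$gene_a, records$gene_b)
  b <- pmax(records$gene_a, records$gene_b)
  key <- paste(a, b, sep = "\r")
  rows <- lapply(split(seq_len(nrow(records)), key), function(ii) {
    sub <- records[ii, , drop = FALSE]
    pw <- sort(unique(unlist(strsplit(sub$pathways, ";", fixed = TRUE))))
    best <- which.max(abs(sub$delta_cc))
    deltas <- unique(sub$delta_cc)
    if (length(deltas) > 1) {
      message(sprintf("pair %s-%s has differing delta_cc across pathways [%s]; keeping %.4g",
                      a[ii[1]], b[ii[1]],
                      paste(format(range(deltas)), collapse = ", "),
                      sub$delta_cc[best]))
    }
    data.frame(gene_a = a[ii[1]], gene_b = b[ii[1]],
               cc_control = sub$cc_control[best],
               cc_cancer = sub$cc_cancer[best],
               delta_cc = sub$delta_cc[best],
               pathways = paste(pw, collapse = ";"),
               n_pathways = length(pw),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Genes involved in a set of pair records
#'
#' @param records Data frame with `gene_a`, `gene_b` columns.
#' @return Sorted unique character vector of the union of both members.
#' @export
genes_from_pairs <- function(records) {
  sort(unique(c(records$gene_a, records$gene_b)))
}

#' Assemble the diagnostic gene panel
#'
#' The union of the top upregulated genes, top downregulated genes, and the
#' genes involved in correlation-shifted pairs. A gene present in several
#' inputs appears once, with merged source tags. Output is sorted by number
#' of sources (descending), then `|log2fc|` (descending, missing last),
#' then symbol.
#'
#' @param top_up,top_down Character vectors of gene IDs (must be disjoint).
#' @param pair_genes Character vector, typically [genes_from_pairs()] of the
#'   deduplicated records.
#' @param deg_records Optional DEG table ([deg_table()]) supplying `log2fc`
#'   and `p_value` per gene.
#' @param pair_records Optional deduplicated pair records supplying
#'   per-gene partner evidence.
#' @return Data frame with one row per panel gene: `gene_id`, `sources`
#'   (semicolon-joined subset of `top_up`/`top_down`/`corr_shift`),
#'   `n_sources`, `log2fc`, `p_value`, `partners`, `delta_cc`, `pathways`.
#' @export
assemble_panel <- function(top_up, top_down, pair_genes,
                           deg_records = NULL, pair_records = NULL) {
  clash <- intersect(top_up, top_down)
  if (length(clash)) {
    stop("gene(s) in both top-up and top-down lists: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  genes <- sort(unique(c(top_up, top_down, pair_genes)))
  if (!length(genes)) {
    return(data.frame(gene_id = character(0), sources = character(0),
                      n_sources = integer(0), log2fc = numeric(0),
                      p_value = numeric(0), partners = character(0),
                      delta_cc = character(0), pathways = character(0),
                      stringsAsFactors = FALSE))
  }
  src <- lapply(genes, function(g) {
    c("top_up", "top_down", "corr_shift")[c(g %in% top_up, g %in% top_down,
                                            g %in% pair_genes)]
  })
  lfc <- rep(NA_real_, length(genes))
  pval <- rep(NA_real_, length(genes))
  if (!is.null(deg_records)) {
    m <- match(genes, deg_records$gene_id)
    lfc <- deg_records$log2fc[m]
    pval <- deg_records$p_value[m]
  }
  partners <- delta <- pw <- rep("", length(genes))
  if (!is.null(pair_records) && nrow(pair_records)) {
    for (i in seq_along(genes)) {
      g <- genes[i]
      hit <- pair_records$gene_a == g | pair_records$gene_b == g
      if (!any(hit)) next
      sub <- pair_records[hit, , drop = FALSE]
      other <- ifelse(sub$gene_a == g, sub$gene_b, sub$gene_a)
      ord <- order(other)
      partners[i] <- paste(other[ord], collapse = ";")
      delta[i] <- paste(sprintf("%.4f", sub$delta_cc[ord]), collapse = ";")
      pw[i] <- paste(sort(unique(unlist(
        strsplit(sub$pathways, ";", fixed = TRUE)))), collapse = ";")
    }
  }
  out <- data.frame(
    gene_id = genes,
    sources = vapply(src, paste, character(1), collapse = ";"),
    n_sources = lengths(src),
    log2fc = lfc, p_value = pval,
    partners = partners, delta_cc = delta, pathways = pw,
    stringsAsFactors = FALSE
  )
  key_lfc <- ifelse(is.na(out$log2fc), -Inf, abs(out$log2fc))
  out <- out[order(-out$n_sources, -key_lfc, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
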