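# Tabular IO: expression matrix (TSV, genes x samples), sample sheet
# (sample_id <TAB> group), and GMT gene sets. All readers validate hard and
# name the offending record; all writers round-trip exactly through the
# matching reader.

GROUP_LEVELS <- c("control", "cancer")

#' Validate a genes-by-samples expression matrix
#'
#' Checks the invariants every downstream stage relies on: unique gene and
#' sample identifiers, a dense numeric body, and non-negative finite values
#' (FPKM-like abundances).
#'
#' @param mat Numeric matrix, genes in rows (rownames = gene IDs), samples in
#'   columns (colnames = sample IDs).
#' @return The matrix, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix must carry gene rownames and sample colnames",
         call. = FALSE)
  }
  dup_g <- unique(rownames(mat)[duplicated(rownames(mat))])
  if (length(dup_g)) {
    stop("duplicate gene ID(s): ", paste(dup_g, collapse = ", "),
         call. = FALSE)
  }
  dup_s <- unique(colnames(mat)[duplicated(colnames(mat))])
  if (length(dup_s)) {
    stop("duplicate sample ID(s): ", paste(dup_s, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "invalid value %s at gene '%s', sample '%s' (values must be finite and >= 0)",
      format(mat[bad[1, 1], bad[1, 2]]),
      rownames(mat)[bad[1, 1]], colnames(mat)[bad[1, 2]]
    ), call. = FALSE)
  }
  invisible(mat)
}

#' Read an expression matrix from TSV
#'
#' Expects one header row of sample IDs, a first column of gene IDs, and a
#' dense numeric body of non-negative abundances. Row and column order are
#' preserved.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "A\t1\t2", "B\t0\t4.5"), tsv)
#' read_expression_matrix(tsv)
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
               colClasses = "character"),
    error = function(e) stop("cannot parse expression matrix '", path,
                             "': ", conditionMessage(e), call. = FALSE)
  )
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("empty or malformed expression matrix: ", path, call. = FALSE)
  }
  gene_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  body <- df[, -1, drop = FALSE]
  num <- suppressWarnings(
    vapply(body, as.numeric, numeric(nrow(body)), USE.NAMES = FALSE)
  )
  num <- matrix(num, nrow = nrow(body), ncol = ncol(body))
  bad <- which(is.na(num) & !is.na(as.matrix(body)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                 body[bad[1, 1], bad[1, 2]],
                 gene_ids[bad[1, 1]], sample_ids[bad[1, 2]]), call. = FALSE)
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix to TSV
#'
#' @param mat Validated expression matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  validate_expression_matrix(mat)
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet and check it against an expression matrix
#'
#' The sheet is a two-column TSV with header `sample_id<TAB>group`; group
#' labels must be `control` or `cancer`. When `mat` is supplied, every matrix
#' sample must be present (samples in the sheet but not the matrix are
#' dropped with a warning).
#'
#' @param path Path to the TSV sample sheet.
#' @param mat Optional expression matrix to validate against.
#' @return Named character vector mapping sample ID to group label, ordered
#'   like the matrix columns when `mat` is given.
#' @export
read_sample_sheet <- function(path, mat = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (!all(c("sample_id", "group") %in% colnames(df))) {
    stop("sample sheet must have columns 'sample_id' and 'group'",
         call. = FALSE)
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) {
    stop("duplicate sample ID(s) in sheet: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(df$group), GROUP_LEVELS)
  if (length(unknown)) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         "; expected one of: ", paste(GROUP_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  groups <- setNames(df$group, df$sample_id)
  if (!is.null(mat)) {
    missing <- setdiff(colnames(mat), names(groups))
    if (length(missing)) {
      stop("sample sheet is missing matrix sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(names(groups), colnames(mat))
    if (length(extra)) {
      warning("dropping ", length(extra),
              " sheet sample(s) absent from the matrix: ",
              paste(extra, collapse = ", "), call. = FALSE)
    }
    groups <- groups[colnames(mat)]
  }
  validate_sample_groups(groups)
  groups
}

#' Validate a sample-to-group assignment
#'
#' @param groups Named character vector, values in `control`/`cancer`.
#' @param min_per_group Minimum group size (correlation stages need >= 3).
#' @return `groups`, invisibly.
#' @export
validate_sample_groups <- function(groups, min_per_group = 1) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("group assignment must be named by sample ID", call. = FALSE)
  }
  unknown <- setdiff(unique(groups), GROUP_LEVELS)
  if (length(unknown)) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  n <- table(factor(groups, levels = GROUP_LEVELS))
  if (any(n < min_per_group)) {
    stop("each group needs >= ", min_per_group, " samples (control: ",
         n[["control"]], ", cancer: ", n[["cancer"]], ")", call. = FALSE)
  }
  invisible(groups)
}

#' Write a sample sheet to TSV
#'
#' @param groups Named character vector of group labels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(groups, path) {
  validate_sample_groups(groups)
  write.table(
    data.frame(sample_id = names(groups), group = unname(groups)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated member symbols.
#' Duplicate members within a line are collapsed with a warning; a line with
#' fewer than three fields is a hard error naming the line number.
#'
#' @param path Path to a GMT file.
#' @return Named list of pathway sets; each element is a list with `name`,
#'   `source_id` (the description field) and `genes` (unique character
#'   vector). List order follows file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT line ", i, " has ", length(fields),
           " field(s); need name, description and >= 1 member",
           call. = FALSE)
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("GMT set '", fields[[1]], "' (line ", i,
              ") has duplicate members; collapsing", call. = FALSE)
      genes <- unique(genes)
    }
    if (!length(genes)) {
      stop("GMT line ", i, " ('", fields[[1]], "') has no members",
           call. = FALSE)
    }
    sets[[i]] <- list(name = fields[[1]], source_id = fields[[2]],
                      genes = genes)
  }
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of pathway sets as returned by [read_gmt()], or a
#'   named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (is.character(s)) {
      s <- list(name = names(sets)[[i]], source_id = "", genes = s)
    }
    paste(c(s$name, s$source_id, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# split a validated group assignment into sample-ID vectors
group_samples <- function(groups) {
  validate_sample_groups(groups)
  list(control = names(groups)[groups == "control"],
       cancer  = names(groups)[groups == "cancer"])
}
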