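#' Two-group expression matrix
#'
#' Container for a log2-scale gene-by-sample expression matrix with a
#' two-group (control vs case) design. Values are validated to be finite,
#' gene symbols unique, and both groups non-empty.
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample names).
#' @param groups character or factor of length `ncol(values)` (or a named
#'   vector keyed by sample name) with levels `"control"` and `"case"`.
#' @param scale `"log2"` if `values` are already log2, `"linear"` to apply
#'   `log2(x + pseudocount)`.
#' @param pseudocount offset added before log2 transformation of
#'   linear-scale input. Default 1.
#' @param drop_incomplete drop genes with any non-finite value (with a
#'   warning) instead of erroring. Default `TRUE`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (log2 matrix) and `groups` (named character vector).
#' @export
expression_matrix <- function(values, groups, scale = c("log2", "linear"),
                              pseudocount = 1, drop_incomplete = TRUE) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbols in expression matrix")
  groups <- as.character(groups)
  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(values), names(groups))
    if (length(missing))
      stop("samples without group assignment: ", paste(missing, collapse = ", "))
    groups <- groups[colnames(values)]
  } else {
    if (length(groups) != ncol(values))
      stop("groups must have one entry per sample")
    names(groups) <- colnames(values)
  }
  if (!all(groups %in% c("control", "case")))
    stop("groups must be 'control' or 'case'")
  if (!all(c("control", "case") %in% groups))
    stop("empty group")
  if (scale == "linear") {
    if (any(values + pseudocount <= 0, na.rm = TRUE))
      stop("linear values + pseudocount must be positive")
    values <- log2(values + pseudocount)
  }
  bad <- !is.finite(values)
  if (any(bad)) {
    if (!drop_incomplete) stop("non-finite expression values")
    drop <- rowSums(bad) > 0
    warning(sprintf("dropping %d gene(s) with missing values", sum(drop)))
    values <- values[!drop, , drop = FALSE]
  }
  if (nrow(values) == 0) stop("no genes left after filtering")
  structure(list(values = values, groups = groups),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d control, %d case)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "control"), sum(x$groups == "case")))
  invisible(x)
}

#' Read an expression matrix and group file from TSV
#'
#' The matrix file has gene symbols in the first column and a header of
#' sample names; the group file has two columns, `sample<TAB>group`, with
#' groups named `control` / `case`.
#'
#' @param matrix_path path to the expression TSV.
#' @param groups_path path to the sample-group TSV.
#' @inheritParams expression_matrix
#' @return An `expression_matrix`.
#' @export
read_expression <- function(matrix_path, groups_path,
                            scale = c("log2", "linear"), pseudocount = 1) {
  scale <- match.arg(scale)
  df <- utils::read.delim(matrix_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- as.character(df[[1]])
  g <- utils::read.delim(groups_path, header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(g) < 2) stop("group file needs two columns: sample, group")
  # tolerate an optional header row
  if (identical(tolower(g[1, 1]), "sample")) g <- g[-1, , drop = FALSE]
  groups <- stats::setNames(as.character(g[[2]]), as.character(g[[1]]))
  expression_matrix(vals, groups, scale = scale, pseudocount = pseudocount)
}

#' Write an expression matrix (and its groups) to TSV
#'
#' @param x an `expression_matrix`.
#' @param matrix_path output path for the matrix TSV.
#' @param groups_path output path for the sample-group TSV.
#' @return Invisibly, `x`.
#' @export
write_expression <- function(x, matrix_path, groups_path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(x$groups), group = unname(x$groups)),
    groups_path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  invisible(x)
}
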