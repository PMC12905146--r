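#' Expression matrices
#'
#' Genes-by-samples normalized log2 expression, keyed by the sample
#' reference names used in `Sample$expsample_reference_name` (GEO GSM-style
#' ids), with a per-sample batch flag.  Batch-flagged samples are the ones
#' removed (not adjusted) before the stimulated-gene statistic.
#'
#' @param values Numeric matrix, rownames = gene symbols, colnames = sample
#'   reference names.
#' @param batch_flag Logical vector named by sample reference name; defaults
#'   to all `FALSE`.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, batch_flag = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)) || nrow(values) == 0)
  if (is.null(colnames(values))) {
    if (ncol(values) > 0)
      stop("expression matrix columns must carry sample reference names")
    dimnames(values) <- list(rownames(values), character(0))
  }
  if (anyDuplicated(colnames(values)))
    stop("sample reference names must be unique")
  if (is.null(batch_flag)) {
    batch_flag <- stats::setNames(rep(FALSE, ncol(values)), colnames(values))
  } else {
    if (is.null(names(batch_flag))) names(batch_flag) <- colnames(values)
    batch_flag <- batch_flag[colnames(values)]
    batch_flag[is.na(batch_flag)] <- FALSE
    names(batch_flag) <- colnames(values)
  }
  structure(list(genes = rownames(values), samples = colnames(values),
                 values = values, batch_flag = batch_flag),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples (%d batch-flagged)\n",
              length(x$genes), length(x$samples), sum(x$batch_flag)))
  invisible(x)
}

#' Write an expression matrix as CSV (genes in rows, first column `gene`)
#' @param matrix An `expression_matrix`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_expression_matrix <- function(matrix, path) {
  df <- data.frame(gene = matrix$genes, matrix$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_csv_plain(df, path)
  invisible(path)
}

#' Read an expression matrix from CSV
#' @param path CSV with a `gene` first column and one column per sample.
#' @param batch_flag Optional logical vector named by sample reference.
#' @return An `expression_matrix`.
#' @export
read_expression_matrix <- function(path, batch_flag = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df))
    stop("expression CSV must have a 'gene' first column: ", path)
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$gene
  expression_matrix(m, batch_flag = batch_flag)
}
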