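#' Construct an expression set (genes x samples + sample metadata)
#'
#' Values are stored as a genes-by-samples numeric matrix of normalized
#' log-scale expression; per-sample metadata records the study, growth-plate
#' zone, treatment and replicate (empty strings are allowed but the keys are
#' always present).
#'
#' @param values Numeric matrix, genes in rows (rownames required), samples
#'   in columns.
#' @param metadata Optional data frame with one row per sample and columns
#'   among `sample_id`, `study`, `zone`, `treatment`, `replicate`; missing
#'   columns are filled with empty strings / 1.
#' @return An object of class `expression_set`.
#' @export
expression_set <- function(values, metadata = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || any(!nzchar(rownames(values)))) {
    stop("expression matrix needs gene names as rownames")
  }
  if (any(!is.finite(values))) stop("expression values must be finite")
  rownames(values) <- canonical_gene_names(rownames(values))
  if (anyDuplicated(rownames(values))) stop("duplicate gene names")
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("sample_%02d", seq_len(ncol(values)))
  }
  if (is.null(metadata)) metadata <- tibble(sample_id = colnames(values))
  metadata <- as_tibble(metadata)
  if (!"sample_id" %in% names(metadata)) metadata$sample_id <- colnames(values)
  stopifnot(nrow(metadata) == ncol(values))
  for (col in c("study", "zone", "treatment")) {
    if (!col %in% names(metadata)) metadata[[col]] <- ""
  }
  if (!"replicate" %in% names(metadata)) metadata$replicate <- 1L
  metadata <- metadata[, c("sample_id", "study", "zone", "treatment", "replicate")]
  structure(list(values = values, samples = metadata), class = "expression_set")
}

#' @exportS3Method base::print
print.expression_set <- function(x, ...) {
  cat(sprintf("<expression_set> %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  st <- unique(x$samples$study)
  cat("  studies:", paste(st[nzchar(st)], collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.expression_set <- function(x, ...) {
  as_tibble(x$values, rownames = "gene") |>
    pivot_longer(-"gene", names_to = "sample_id", values_to = "expression") |>
    left_join(x$samples, by = "sample_id")
}

expr_matrix <- function(expr) {
  if (inherits(expr, "expression_set")) return(expr$values)
  m <- as.matrix(expr)
  stopifnot(!is.null(rownames(m)))
  m
}

#' Read / write expression data as TSV
#'
#' The expression TSV has genes in rows (first column = gene name) and
#' samples in columns; the optional metadata TSV has one row per sample.
#'
#' @param path Expression TSV path.
#' @param metadata_path Optional metadata TSV path.
#' @return `read_expression()` returns an [expression_set()].
#' @export
read_expression <- function(path, metadata_path = NULL) {
  m <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  meta <- NULL
  if (!is.null(metadata_path)) {
    meta <- as_tibble(read.delim(metadata_path, check.names = FALSE,
                                 colClasses = "character"))
    if ("replicate" %in% names(meta)) meta$replicate <- as.integer(meta$replicate)
  }
  expression_set(m, meta)
}

#' @rdname read_expression
#' @param expr An [expression_set()].
#' @param digits Significant digits used when writing values.
#' @export
write_expression <- function(expr, path, metadata_path = NULL, digits = 6) {
  vals <- expr_matrix(expr)
  out <- format(signif(vals, digits), trim = TRUE, scientific = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(metadata_path) && inherits(expr, "expression_set")) {
    write.table(expr$samples, metadata_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
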