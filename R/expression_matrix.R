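#' Expression matrix container
#'
#' An `expression_matrix` holds non-negative gene-by-sample expression
#' values together with gene identifiers, sample identifiers and an
#' optional class label per sample. It is the common currency of every
#' analysis function in the package: the chi-square metric underlying
#' correspondence analysis treats entries as non-negative mass, so the
#' constructor enforces non-negativity and positive row/column margins.
#'
#' @param values numeric matrix, k genes x p samples, all entries finite
#'   and >= 0 after the negative-value policy is applied.
#' @param gene_ids character vector of length k; must be unique after
#'   case-folding.
#' @param sample_ids character vector of length p; must be unique.
#'   Defaults to the column names of `values`.
#' @param sample_class character vector of length p of class labels, or
#'   `NULL`, in which case every sample is labelled `"unknown"`.
#' @param clip_negative if `TRUE` (default), negative entries (possible in
#'   log-scale microarray data) are clipped to 0 and the number of clipped
#'   entries is reported via a message; if `FALSE`, any negative entry is
#'   an error. The chi-square metric requires non-negative mass.
#' @param drop_zero_margins if `TRUE` (default), rows and columns whose
#'   sum is zero are dropped (with a message); otherwise they are an
#'   error.
#'
#' @return an object of class `expression_matrix` with fields `values`,
#'   `gene_ids`, `sample_ids`, `sample_class`.
#' @export
expression_matrix <- function(values, gene_ids, sample_ids = colnames(values),
                              sample_class = NULL, clip_negative = TRUE,
                              drop_zero_margins = TRUE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (any(!is.finite(values))) {
    stop("'values' contains non-finite entries; drop or impute them first")
  }
  if (length(gene_ids) != nrow(values)) {
    stop("length(gene_ids) must equal nrow(values)")
  }
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(casefold(gene_ids))) {
    stop("gene_ids must be unique after case-folding; collapse duplicates first")
  }
  if (is.null(sample_ids)) {
    sample_ids <- paste0("sample", seq_len(ncol(values)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != ncol(values)) {
    stop("length(sample_ids) must equal ncol(values)")
  }
  if (anyDuplicated(sample_ids)) {
    stop("sample_ids must be unique")
  }
  if (ncol(values) == 0L) {
    stop("expression matrix has zero samples")
  }
  if (is.null(sample_class)) {
    sample_class <- rep("unknown", ncol(values))
  }
  sample_class <- as.character(sample_class)
  if (length(sample_class) != ncol(values)) {
    stop("length(sample_class) must equal ncol(values)")
  }

  n_neg <- sum(values < 0)
  if (n_neg > 0) {
    if (!clip_negative) {
      stop(n_neg, " negative entries found and clip_negative = FALSE")
    }
    message(n_neg, " negative entries clipped to 0")
    values[values < 0] <- 0
  }

  zero_rows <- rowSums(values) == 0
  zero_cols <- colSums(values) == 0
  if (any(zero_rows) || any(zero_cols)) {
    if (!drop_zero_margins) {
      stop("matrix has zero-sum rows or columns")
    }
    if (any(zero_rows)) {
      message(sum(zero_rows), " zero-sum gene rows dropped")
      values <- values[!zero_rows, , drop = FALSE]
      gene_ids <- gene_ids[!zero_rows]
    }
    if (any(zero_cols)) {
      message(sum(zero_cols), " zero-sum sample columns dropped")
      values <- values[, !zero_cols, drop = FALSE]
      sample_ids <- sample_ids[!zero_cols]
      sample_class <- sample_class[!zero_cols]
    }
    if (nrow(values) == 0L || ncol(values) == 0L) {
      stop("no genes or samples left after dropping zero margins")
    }
  }

  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         sample_class = sample_class),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  cls <- table(x$sample_class)
  cat("classes:", paste(names(cls), cls, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by genes and/or samples
#'
#' @param x an `expression_matrix`.
#' @param genes gene identifiers or row indices to keep (in the given order).
#' @param samples sample identifiers or column indices to keep.
#' @return a new `expression_matrix`.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  gi <- if (is.null(genes)) seq_along(x$gene_ids) else {
    if (is.character(genes)) match(casefold(genes), casefold(x$gene_ids))
    else genes
  }
  if (anyNA(gi)) stop("unknown gene identifiers in 'genes'")
  si <- if (is.null(samples)) seq_along(x$sample_ids) else {
    if (is.character(samples)) match(samples, x$sample_ids) else samples
  }
  if (anyNA(si)) stop("unknown sample identifiers in 'samples'")
  expression_matrix(x$values[gi, si, drop = FALSE],
                    gene_ids = x$gene_ids[gi],
                    sample_ids = x$sample_ids[si],
                    sample_class = x$sample_class[si])
}
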