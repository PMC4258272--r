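#' Read an expression matrix from a delimited file
#'
#' Reads a gene-by-sample expression table. The first column holds gene
#' identifiers; all remaining columns are numeric sample columns. Two
#' formats are supported: plain TSV and the GEO series-matrix flat format
#' (header/metadata lines starting with `!` are skipped and the table
#' between `!series_matrix_table_begin`/`_end` markers, when present, is
#' used).
#'
#' Duplicate gene rows (after case-folding) are collapsed by their mean;
#' rows containing missing values are dropped. Row order otherwise
#' follows the file.
#'
#' @param path path to the file.
#' @param format `"tsv"` (default) or `"geo_series_matrix"`.
#' @param class_file optional path to a two-column TSV mapping
#'   `sample_id` to class label.
#' @param clip_negative negative-value policy, see
#'   [expression_matrix()].
#' @return an [expression_matrix()].
#' @export
load_expression_matrix <- function(path, format = c("tsv", "geo_series_matrix"),
                                   class_file = NULL, clip_negative = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "geo_series_matrix") {
    begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
    end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
    if (length(begin) == 1 && length(end) == 1 && end > begin) {
      lines <- lines[(begin + 1):(end - 1)]
    } else {
      lines <- lines[!startsWith(lines, "!")]
    }
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("unparseable or empty expression file: ", path)
  tab <- tryCatch(
    utils::read.delim(text = lines, header = TRUE, sep = "\t",
                      check.names = FALSE, quote = "\""),
    error = function(e) stop("unparseable expression file: ", path, " (",
                             conditionMessage(e), ")")
  )
  if (ncol(tab) < 2) stop("expression file has zero sample columns: ", path)
  gene_ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    suppressWarnings(storage.mode(vals) <- "double")
    if (all(is.na(vals))) stop("sample columns are not numeric in ", path)
  }

  keep <- !apply(vals, 1L, anyNA)
  if (any(!keep)) message(sum(!keep), " rows with missing values dropped")
  vals <- vals[keep, , drop = FALSE]
  gene_ids <- gene_ids[keep]

  key <- casefold(gene_ids)
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    agg <- rowsum(vals, group = key, reorder = FALSE) /
      as.vector(table(factor(key, levels = unique(key))))
    vals <- agg
    gene_ids <- gene_ids[first]
    message("collapsed duplicate gene rows to ", nrow(vals), " unique genes")
  }

  classes <- NULL
  if (!is.null(class_file)) {
    cl <- utils::read.delim(class_file, header = TRUE, sep = "\t",
                            check.names = FALSE)
    idx <- match(colnames(vals), as.character(cl[[1]]))
    classes <- ifelse(is.na(idx), "unknown", as.character(cl[[2]])[idx])
  }
  expression_matrix(vals, gene_ids = gene_ids, sample_ids = colnames(vals),
                    sample_class = classes, clip_negative = clip_negative)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [load_expression_matrix()]: first column `gene_id`,
#' remaining columns the samples. Values are written in full precision so
#' a load/write/load cycle is bit-identical.
#'
#' @param x an [expression_matrix()].
#' @param path output file path.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene_id = x$gene_ids, x$values, check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Log2 transform of RPKM values
#'
#' Computes `log2(values + pseudocount)`. The pseudocount must be at
#' least 1 so that RPKM 0 maps to a non-negative value and the result
#' remains a valid non-negative expression matrix.
#'
#' @param values non-negative numeric matrix of RPKM values, or an
#'   [expression_matrix()].
#' @param pseudocount added before taking logs; must be >= 1.
#' @return object of the same type as the input, log2 transformed.
#' @export
log2_rpkm_transform <- function(values, pseudocount = 1) {
  if (pseudocount < 1) {
    stop("pseudocount must be >= 1 (smaller values create negative log2 output)")
  }
  if (inherits(values, "expression_matrix")) {
    out <- values
    out$values <- log2(values$values + pseudocount)
    # log2(x + c) with c >= 1 and x >= 0 is >= 0; margins can still collapse
    # to zero if a whole row/column was zero, so revalidate
    return(expression_matrix(out$values, out$gene_ids, out$sample_ids,
                             out$sample_class))
  }
  if (any(values < 0)) stop("RPKM values must be non-negative")
  log2(values + pseudocount)
}

#' Restrict two expression matrices to their common gene universe
#'
#' Both matrices are restricted to the case-insensitive intersection of
#' their gene identifiers, in the order the genes appear in `a`. The same
#' genes must be used in both the main and the explanatory dataset, so
#' this is the mandatory first step of any cross-dataset analysis.
#'
#' @param a,b [expression_matrix()] objects.
#' @return a list with elements `a` and `b`, both restricted to the
#'   shared genes in identical order.
#' @export
intersect_genes <- function(a, b) {
  stopifnot(inherits(a, "expression_matrix"), inherits(b, "expression_matrix"))
  ka <- casefold(a$gene_ids)
  kb <- casefold(b$gene_ids)
  common <- ka[ka %in% kb]
  if (length(common) == 0) {
    stop("no genes shared between datasets (e.g. '", a$gene_ids[1], "' vs '",
         b$gene_ids[1], "'); check that both use the same identifier scheme")
  }
  message(length(common), " genes in common")
  ai <- match(common, ka)
  bi <- match(common, kb)
  list(
    a = expression_matrix(a$values[ai, , drop = FALSE], a$gene_ids[ai],
                          a$sample_ids, a$sample_class),
    b = expression_matrix(b$values[bi, , drop = FALSE], a$gene_ids[ai],
                          b$sample_ids, b$sample_class)
  )
}

#' Cross-platform rank normalization of two expression datasets
#'
#' Replaces every sample column of both datasets by the ranks of its
#' values mapped onto a common reference distribution: the mean sorted
#' profile across all columns of both datasets (quantile-normalization
#' style). After normalization a column depends only on the ordering of
#' its values, so strictly monotone platform effects (microarray vs
#' RNA-seq scales) are removed. Ties receive the average rank and are
#' mapped by linear interpolation into the reference profile.
#'
#' @param a,b [expression_matrix()] objects over an identical ordered
#'   gene universe (apply [intersect_genes()] first).
#' @return list with normalized `a` and `b`.
#' @export
rank_normalize <- function(a, b) {
  stopifnot(inherits(a, "expression_matrix"), inherits(b, "expression_matrix"))
  if (!identical(casefold(a$gene_ids), casefold(b$gene_ids))) {
    stop("gene universes differ; run intersect_genes() first")
  }
  pooled <- cbind(a$values, b$values)
  const <- apply(pooled, 2L, function(col) diff(range(col)) == 0)
  if (any(const)) {
    stop("cannot rank-normalize constant sample column(s): ",
         paste(colnames(pooled)[const], collapse = ", "))
  }
  k <- nrow(pooled)
  ref <- rowMeans(apply(pooled, 2L, sort))
  map_col <- function(col) {
    r <- rank(col, ties.method = "average")
    stats::approx(seq_len(k), ref, xout = r)$y
  }
  na <- a; nb <- b
  na$values <- apply(a$values, 2L, map_col)
  nb$values <- apply(b$values, 2L, map_col)
  dimnames(na$values) <- dimnames(a$values)
  dimnames(nb$values) <- dimnames(b$values)
  list(
    a = expression_matrix(na$values, a$gene_ids, a$sample_ids, a$sample_class),
    b = expression_matrix(nb$values, b$gene_ids, b$sample_ids, b$sample_class)
  )
}
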