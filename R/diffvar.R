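#' Per-class mean expression profiles
#'
#' Averages replicate sample columns within each class of a resource
#' dataset. Samples labelled `"unknown"` are excluded with a warning.
#' The class-mean profiles are the building blocks of differentiation
#' variables and can serve directly as explanatory columns for [cca()].
#'
#' @param resource an [expression_matrix()] with class labels.
#' @return a list with `means` (k genes x number of classes) and
#'   `class_labels`.
#' @export
class_means <- function(resource) {
  stopifnot(inherits(resource, "expression_matrix"))
  cl <- resource$sample_class
  if (any(cl == "unknown")) {
    warning(sum(cl == "unknown"), " unknown-labelled samples excluded from class means")
  }
  keep <- cl != "unknown"
  if (!any(keep)) stop("no class-labelled samples in resource dataset")
  cl <- cl[keep]
  v <- resource$values[, keep, drop = FALSE]
  labels <- unique(cl)
  means <- vapply(labels, function(l) rowMeans(v[, cl == l, drop = FALSE]),
                  numeric(nrow(v)))
  dimnames(means) <- list(resource$gene_ids, labels)
  list(means = means, class_labels = labels)
}

#' Differentiation variable between two cell programmes
#'
#' The differentiation variable from class X to class Y is the gene-wise
#' difference of their mean expression profiles, d = mu_y - mu_x. Genes
#' up-regulated along the X -> Y differentiation axis get positive
#' entries. Used as a single explanatory column, it yields the
#' one-dimensional ordination scoring of [cca_score_1d()].
#'
#' @param resource an [expression_matrix()] with class labels.
#' @param from_class,to_class class labels present in the resource.
#' @return object of class `differentiation_variable` with fields `d`,
#'   `from_class`, `to_class`, `gene_ids`.
#' @export
differentiation_variable <- function(resource, from_class, to_class) {
  if (identical(from_class, to_class)) {
    stop("from_class and to_class must differ")
  }
  cm <- class_means(resource)
  for (cl in c(from_class, to_class)) {
    if (!cl %in% cm$class_labels) stop("class not in resource dataset: ", cl)
  }
  d <- cm$means[, to_class] - cm$means[, from_class]
  if (all(d == 0)) {
    stop("degenerate differentiation variable: classes '", from_class,
         "' and '", to_class, "' have identical mean profiles")
  }
  structure(list(d = unname(d), from_class = from_class,
                 to_class = to_class, gene_ids = resource$gene_ids),
            class = "differentiation_variable")
}

#' @export
print.differentiation_variable <- function(x, ...) {
  cat("differentiation variable:", x$from_class, "->", x$to_class,
      "over", length(x$d), "genes\n")
  invisible(x)
}

#' One-vs-rest differentiation variable
#'
#' Contrasts one target class against the unweighted mean of all other
#' classes' mean profiles (mean of class means, not pooled samples, so
#' unequal replicate counts do not bias the rest profile):
#' d = mu_target - mean(mu_other). This is the explanatory variable used
#' by the automatic classification of undefined samples.
#'
#' @param resource an [expression_matrix()] with at least 2 classes.
#' @param target_class the class of interest.
#' @return a [differentiation_variable()] with `from_class = "rest"`.
#' @export
one_vs_rest_variable <- function(resource, target_class) {
  cm <- class_means(resource)
  if (!target_class %in% cm$class_labels) {
    stop("class not in resource dataset: ", target_class)
  }
  if (length(cm$class_labels) < 2) {
    stop("one-vs-rest contrast needs at least 2 classes")
  }
  rest <- cm$class_labels[cm$class_labels != target_class]
  mu_rest <- rowMeans(cm$means[, rest, drop = FALSE])
  d <- cm$means[, target_class] - mu_rest
  if (all(d == 0)) stop("degenerate one-vs-rest variable for ", target_class)
  structure(list(d = unname(d), from_class = "rest",
                 to_class = target_class, gene_ids = resource$gene_ids),
            class = "differentiation_variable")
}

#' Differentially expressed genes between two classes
#'
#' Selects genes passing both a significance filter and a fold-change
#' filter in the comparison of `class_a` against `class_b`:
#' Benjamini-Hochberg adjusted p-value of a two-sample Welch t-test
#' below `fdr`, and mean difference (class_a minus class_b) in the top
#' or bottom `fc_percentile` percent of all genes.
#'
#' @param resource an [expression_matrix()]; each class needs at least
#'   2 replicate samples for the t-test.
#' @param class_a,class_b class labels to compare.
#' @param fdr false discovery rate threshold (default 0.01).
#' @param fc_percentile percentage in (0, 50]; genes whose mean
#'   difference falls in the upper or lower tail of this size pass the
#'   fold-change filter (default 1).
#' @return character vector of gene identifiers, in input gene order.
#' @export
select_de_genes <- function(resource, class_a, class_b, fdr = 0.01,
                            fc_percentile = 1) {
  stopifnot(inherits(resource, "expression_matrix"))
  if (fc_percentile <= 0 || fc_percentile > 50) {
    stop("fc_percentile must be in (0, 50]")
  }
  ia <- resource$sample_class == class_a
  ib <- resource$sample_class == class_b
  if (sum(ia) < 2 || sum(ib) < 2) {
    stop("each class needs >= 2 replicates for the t-test; with single ",
         "replicates use select_top_features() (fold-change ranking) instead")
  }
  va <- resource$values[, ia, drop = FALSE]
  vb <- resource$values[, ib, drop = FALSE]
  k <- nrow(va)
  na <- ncol(va); nb <- ncol(vb)
  ma <- rowMeans(va); mb <- rowMeans(vb)
  s2a <- rowSums((va - ma)^2) / (na - 1)
  s2b <- rowSums((vb - mb)^2) / (nb - 1)
  se2 <- s2a / na + s2b / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((s2a / na)^2 / (na - 1) + (s2b / nb)^2 / (nb - 1))
  pval <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  pval[!is.finite(tstat)] <- 1   # zero-variance, zero-difference genes
  padj <- stats::p.adjust(pval, method = "BH")

  diff <- ma - mb
  lo <- stats::quantile(diff, fc_percentile / 100)
  hi <- stats::quantile(diff, 1 - fc_percentile / 100)
  fc_pass <- diff >= hi | diff <= lo
  if (fc_percentile == 50) fc_pass <- diff != 0   # no-filter limit

  sig <- if (fdr >= 1) rep(TRUE, k) else padj < fdr   # fdr = 1: no filter
  resource$gene_ids[sig & fc_pass & diff != 0]
}

#' Lineage-specific genes on the linear RPKM scale
#'
#' Marks a gene as specific to `target_class` when its class-mean RPKM
#' is at least `min_rpkm` and at least `fold` times greater than its
#' mean in every other lineage. Operates on linear-scale RPKM values.
#'
#' @param resource an [expression_matrix()] of linear-scale RPKM values.
#' @param target_class lineage of interest.
#' @param min_rpkm minimum class-mean RPKM (default 5).
#' @param fold required fold difference over every other lineage
#'   (default 2).
#' @return character vector of gene identifiers.
#' @export
select_lineage_genes <- function(resource, target_class, min_rpkm = 5,
                                 fold = 2) {
  cm <- class_means(resource)
  if (!target_class %in% cm$class_labels) {
    stop("class not in resource dataset: ", target_class)
  }
  if (length(cm$class_labels) < 2) stop("needs at least 2 lineages")
  mu_t <- cm$means[, target_class]
  others <- cm$means[, cm$class_labels != target_class, drop = FALSE]
  pass <- mu_t >= min_rpkm & mu_t >= fold * apply(others, 1L, max)
  resource$gene_ids[pass]
}

#' Top discriminative features for a target class
#'
#' Ranks genes by the absolute value of the one-vs-rest differentiation
#' variable for `target_class` and returns the `n` largest. Ties are
#' broken by lexicographic gene identifier, making the selection
#' deterministic and the result for `n` a prefix of the result for
#' `n + 1`.
#'
#' @param resource an [expression_matrix()] with >= 2 classes.
#' @param target_class the class of interest.
#' @param n number of genes to keep (1 <= n <= number of genes).
#' @return character vector of `n` gene identifiers, strongest first.
#' @export
select_top_features <- function(resource, target_class, n) {
  if (n <= 0) stop("n must be positive")
  dv <- one_vs_rest_variable(resource, target_class)
  if (n > length(dv$d)) stop("n exceeds the number of genes")
  ord <- order(-abs(dv$d), dv$gene_ids)
  dv$gene_ids[ord[seq_len(n)]]
}
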