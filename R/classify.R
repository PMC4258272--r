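#' One-dimensional CCA scoring against a differentiation variable
#'
#' Runs [cca()] with the single explanatory column d and returns the
#' principal sample scores of the unique constrained axis. The axis is
#' oriented so that the biplot coefficient of the sign-canonicalized
#' variable (d flipped, if needed, so its largest-magnitude gene entry
#' is positive) is positive. Because the canonical direction ignores the
#' sign d was supplied with, negating d -- equivalently swapping its
#' from/to classes -- leaves the returned scores unchanged, and
#' downstream predictions never depend on the labelling direction.
#' When the dominant gene of d is a marker of `to_class` (the typical
#' case for class contrasts), higher scores mean more aligned with the
#' `to_class` programme.
#'
#' @param test an [expression_matrix()] of samples to score.
#' @param d a [differentiation_variable()] over the same ordered gene
#'   universe as `test`.
#' @return named numeric vector of per-sample scores.
#' @export
cca_score_1d <- function(test, d) {
  stopifnot(inherits(test, "expression_matrix"),
            inherits(d, "differentiation_variable"))
  if (length(d$d) != nrow(test$values)) {
    stop("differentiation variable and test matrix gene universes differ")
  }
  res <- cca(test, d)
  scores <- res$sample_scores_principal[, 1L]
  # cca() orients the axis so the biplot score of d-as-passed is
  # positive; multiplying by the canonical sign of d makes the result
  # independent of the direction the contrast was written in
  stopifnot(res$biplot_scores[1L, 1L] >= 0)
  canon <- sign(d$d[which.max(abs(d$d))])
  scores * canon
}

#' Two-group partition of one-dimensional sample scores
#'
#' Exact k-means with k = 2 on a score vector. In one dimension the
#' optimal two-cluster solution is a threshold partition of the sorted
#' scores, so the global minimum of the within-cluster sum of squares is
#' found by enumerating all n - 1 splits (prefix-sum arithmetic, no
#' random initialization, fully deterministic; ties between splits go to
#' the first optimal split in sorted order). The cluster with the larger
#' mean score is called positive.
#'
#' @param scores numeric vector of >= 2 sample scores with >= 2 distinct
#'   values.
#' @return logical vector, `TRUE` for samples in the higher-score
#'   (positive) cluster.
#' @export
kmeans_classify <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 samples to partition")
  if (diff(range(scores)) == 0) {
    stop("all scores identical; cannot partition into 2 clusters")
  }
  o <- order(scores)
  s <- scores[o]
  n <- length(s)
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  t_idx <- seq_len(n - 1)
  ss_lo <- cs2[t_idx] - cs[t_idx]^2 / t_idx
  ss_hi <- (cs2[n] - cs2[t_idx]) - (cs[n] - cs[t_idx])^2 / (n - t_idx)
  t_best <- which.min(ss_lo + ss_hi)
  positive <- logical(n)
  positive[o[(t_best + 1):n]] <- TRUE
  positive
}

#' Confusion counts and summary metrics for a binary classification
#'
#' @param predicted logical vector of predicted-positive calls.
#' @param truth logical vector of true condition labels, same length.
#' @return object of class `classification_result` with fields
#'   `tp`, `fp`, `tn`, `fn`, `sensitivity` = TP / (TP + FN) (NA when
#'   there are no condition positives), `accuracy` =
#'   (TP + TN) / (TP + TN + FP + FN), and the inputs.
#' @export
confusion_metrics <- function(predicted, truth) {
  predicted <- as.logical(predicted)
  truth <- as.logical(truth)
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length")
  }
  tp <- sum(predicted & truth)
  fp <- sum(predicted & !truth)
  tn <- sum(!predicted & !truth)
  fn <- sum(!predicted & truth)
  structure(list(
    predicted_positive = predicted, truth = truth,
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    accuracy = (tp + tn) / length(truth)
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("tp=%d fp=%d tn=%d fn=%d  sensitivity=%.3f accuracy=%.3f\n",
              x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$accuracy))
  invisible(x)
}

#' Score and classify test samples against a target programme
#'
#' The automatic classification pipeline: build the one-vs-rest
#' differentiation variable for `target_class` from the resource
#' dataset (optionally restricted to the `n_features` strongest genes),
#' compute 1-D CCA sample scores of the test dataset, and partition the
#' scores with [kmeans_classify()]. When the test dataset carries class
#' labels, confusion metrics against `target_class` are attached.
#'
#' @param resource labelled [expression_matrix()] defining the
#'   programmes.
#' @param test [expression_matrix()] of samples to classify; gene
#'   universe is intersected with the resource automatically.
#' @param target_class the programme to detect.
#' @param n_features optional number of top one-vs-rest features to use
#'   (default: all shared genes).
#' @return a `classification_result` with additional fields `scores`
#'   and `target_class`.
#' @export
classify_samples <- function(resource, test, target_class,
                             n_features = NULL) {
  both <- suppressMessages(intersect_genes(resource, test))
  resource <- both$a; test <- both$b
  if (!is.null(n_features)) {
    genes <- select_top_features(resource, target_class, n_features)
    resource <- subset_expression(resource, genes = genes)
    test <- subset_expression(test, genes = genes)
  }
  d <- one_vs_rest_variable(resource, target_class)
  scores <- cca_score_1d(test, d)
  predicted <- kmeans_classify(scores)
  truth <- test$sample_class == target_class
  out <- if (any(test$sample_class != "unknown")) {
    confusion_metrics(predicted, truth)
  } else {
    structure(list(predicted_positive = predicted, truth = NULL),
              class = "classification_result")
  }
  out$scores <- scores
  out$target_class <- target_class
  out
}

#' Jackknife confidence interval for a classification metric
#'
#' Evaluates `evaluate` on every leave-one-out replicate of the sample
#' index set, then returns the jackknife mean and a normal-theory 95%
#' interval based on the jackknife standard error
#' SE^2 = ((m - 1) / m) * sum((theta_i - theta_bar)^2) over the m
#' replicates. Replicates on which the metric is NA (e.g. sensitivity
#' with no positives left) are dropped with a warning.
#'
#' @param evaluate function taking a vector of sample indices (the
#'   retained subset) and returning a single numeric metric.
#' @param n_samples number of samples in the test set (>= 3), or the
#'   test [expression_matrix()] itself.
#' @return list with `mean`, `se`, `ci95` (length-2 vector) and the
#'   per-replicate `values`.
#' @export
jackknife_ci <- function(evaluate, n_samples) {
  if (inherits(n_samples, "expression_matrix")) {
    n_samples <- ncol(n_samples$values)
  }
  if (n_samples < 3) stop("jackknife needs at least 3 samples")
  theta <- vapply(seq_len(n_samples), function(i) {
    evaluate(setdiff(seq_len(n_samples), i))
  }, numeric(1))
  if (anyNA(theta)) {
    warning(sum(is.na(theta)), " leave-one-out replicates with NA metric dropped")
    theta <- theta[!is.na(theta)]
  }
  m <- length(theta)
  if (m < 2) stop("fewer than 2 usable jackknife replicates")
  tb <- mean(theta)
  se <- sqrt((m - 1) / m * sum((theta - tb)^2))
  list(mean = tb, se = se, ci95 = c(tb - 1.96 * se, tb + 1.96 * se),
       values = theta)
}
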