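#' Chi-square standardization of an expression matrix
#'
#' Standardizes a non-negative matrix X in the chi-square metric. With
#' grand total n, row masses r = rowSums(X)/n and column masses
#' c = colSums(X)/n, the standardized matrix is
#'
#'   S = D_r^{-1/2} (X/n - r c^T) D_c^{-1/2}
#'
#' so that the squared Frobenius norm of S is the total inertia, i.e.
#' the Pearson chi-square statistic of X divided by n. S is invariant
#' under rescaling of X.
#'
#' @param x an [expression_matrix()] or a non-negative numeric matrix
#'   with positive row and column sums.
#' @return a list with `S` (k x p matrix), `r` (row masses), `c` (column
#'   masses) and `n` (grand total).
#' @export
chi_square_standardize <- function(x) {
  v <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  if (any(v < 0)) stop("chi-square standardization needs non-negative values")
  n <- sum(v)
  if (n <= 0) stop("matrix grand total must be positive")
  r <- rowSums(v) / n
  cm <- colSums(v) / n
  if (any(r == 0) || any(cm == 0)) {
    stop("zero row or column margin; drop empty genes/samples first")
  }
  P <- v / n
  S <- (P - tcrossprod(r, cm)) / sqrt(tcrossprod(r, cm))
  dimnames(S) <- dimnames(v)
  list(S = S, r = r, c = cm, n = n)
}

#' Standardize explanatory variables in the row-mass metric
#'
#' Centers and scales every column of the explanatory (differentiation
#' programme) matrix Z to weighted mean 0 and weighted variance 1, the
#' weights being the row masses r of the paired expression matrix. Using
#' the same D_r metric as the constrained projection keeps the
#' regression and the biplot correlations in one geometry.
#'
#' @param z_raw numeric matrix, k genes x q programmes; gene order must
#'   match the paired expression matrix.
#' @param r row masses (non-negative, summing to 1).
#' @param weighted if `FALSE`, plain unweighted standardization is used
#'   instead (sensitivity-check mode).
#' @return a list of class `explanatory_matrix` with fields `z`
#'   (standardized matrix), `programme_names`, `standardized = TRUE`.
#' @export
standardize_explanatory <- function(z_raw, r, weighted = TRUE) {
  z_raw <- as.matrix(z_raw)
  if (nrow(z_raw) != length(r)) stop("nrow(z_raw) must equal length(r)")
  if (is.null(colnames(z_raw))) {
    colnames(z_raw) <- paste0("programme", seq_len(ncol(z_raw)))
  }
  w <- if (weighted) r / sum(r) else rep(1 / nrow(z_raw), nrow(z_raw))
  mu <- colSums(z_raw * w)
  zc <- sweep(z_raw, 2L, mu)
  v <- colSums(zc^2 * w)
  if (any(v <= .Machine$double.eps * 100)) {
    stop("degenerate (constant) explanatory column(s): ",
         paste(colnames(z_raw)[v <= .Machine$double.eps * 100], collapse = ", "))
  }
  z <- sweep(zc, 2L, sqrt(v), "/")
  # Centering in the D_r metric removes one dimension, so the most the
  # standardized columns can span is min(q, k - 1); any further rank loss
  # means genuinely collinear programmes.
  qrz <- qr(z * sqrt(w))
  if (qrz$rank < min(ncol(z), nrow(z) - 1L)) {
    dropped <- setdiff(colnames(z), colnames(z)[qrz$pivot[seq_len(qrz$rank)]])
    stop("collinear explanatory columns after standardization: ",
         paste(dropped, collapse = ", "))
  }
  structure(list(z = z, programme_names = colnames(z), standardized = TRUE),
            class = "explanatory_matrix")
}

#' Project the standardized matrix onto the explanatory variables
#'
#' Forms the weighted-regression projection
#'
#'   Q = D_r^{1/2} Z (Z^T D_r Z)^{-1} Z^T D_r^{1/2}
#'
#' and returns the constrained space S* = Q S, the part of S explainable
#' by linear regression on Z in the D_r metric. Q is symmetric and
#' idempotent, so the Frobenius norm of S* never exceeds that of S.
#'
#' @param S chi-square standardized matrix (from
#'   [chi_square_standardize()]).
#' @param z an `explanatory_matrix` (from [standardize_explanatory()]).
#' @param r row masses.
#' @return list with `S_star` (projected matrix) and `Q` (k x k
#'   projection matrix).
#' @export
constrained_projection <- function(S, z, r) {
  stopifnot(inherits(z, "explanatory_matrix"), isTRUE(z$standardized))
  W <- z$z * sqrt(r)                      # D_r^{1/2} Z
  # orthogonal projector onto the column space of W via pivoted QR;
  # equivalent to W (W^T W)^{-1} W^T when W has full column rank but
  # numerically stable, and well defined in the q >= k limit where
  # centering costs one dimension
  qrW <- qr(W)
  if (qrW$rank < min(ncol(W), nrow(W) - 1L)) {
    stop("explanatory variables numerically collinear (Z^T D_r Z singular)")
  }
  B <- qr.Q(qrW)[, seq_len(qrW$rank), drop = FALSE]
  Q <- tcrossprod(B)
  list(S_star = Q %*% S, Q = Q)
}

# Fix the arbitrary SVD sign: orient each axis so that the
# largest-magnitude entry of `anchor` on that axis is positive.
# Returns the vector of signs (+1/-1) applied.
axis_signs <- function(anchor) {
  apply(anchor, 2L, function(col) {
    s <- sign(col[which.max(abs(col))])
    if (s == 0) 1 else s
  })
}

#' Canonical correspondence analysis of an expression matrix
#'
#' Runs the full constrained ordination: chi-square standardization of
#' `x`, weighted standardization of the explanatory profiles, projection
#' onto the explanatory space, and singular value decomposition
#' S* = U D_a V^T of the constrained matrix. Gene scores come in two
#' flavours: LC (linear-combination, i.e. fitted) scores D_r^{-1/2} U,
#' and WA (weighted-average) scores D_r^{-1/2} S V, the weighted
#' averages of the sample scores through the data; principal versions
#' multiply by the singular values. Sample scores are D_c^{-1/2} V
#' (standard) and D_c^{-1/2} V D_a (principal). Biplot scores are the
#' row-mass-weighted correlations of each explanatory column with the
#' standard LC gene scores, and lie in [-1, 1].
#'
#' Total inertia I_T = ||S||_F^2 is split into the constrained part
#' I_C = sum(alpha^2) = ||S*||_F^2 and the unconstrained remainder; the
#' fraction I_C / I_T is reported as `percent_explained`.
#'
#' With a single explanatory column (q = 1) the solution is
#' one-dimensional and the principal sample scores define a scoring
#' system along that differentiation variable (see [cca_score_1d()]).
#'
#' Axes are deterministic: each axis is oriented so its
#' largest-magnitude biplot score is positive, and axes with singular
#' value below `tol` times the largest are dropped.
#'
#' @param x an [expression_matrix()] (or non-negative matrix).
#' @param z_raw numeric matrix of explanatory profiles, k genes x q
#'   programmes, same gene order as `x`; a [differentiation_variable()]
#'   is also accepted.
#' @param weighted_z use row-mass-weighted standardization of Z
#'   (default); `FALSE` gives plain standardization.
#' @param tol relative singular-value tolerance for rank detection.
#' @return an object of class `cca_result`; see Details for fields.
#' @export
cca <- function(x, z_raw, weighted_z = TRUE, tol = 1e-10) {
  if (inherits(z_raw, "differentiation_variable")) {
    z_raw <- matrix(z_raw$d, ncol = 1,
                    dimnames = list(z_raw$gene_ids,
                                    paste0(z_raw$to_class, "_vs_",
                                           z_raw$from_class)))
  }
  z_raw <- as.matrix(z_raw)
  v <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  if (nrow(z_raw) != nrow(v)) {
    stop("x and z_raw must share the same ordered gene universe")
  }
  std <- chi_square_standardize(x)
  z <- standardize_explanatory(z_raw, std$r, weighted = weighted_z)
  proj <- constrained_projection(std$S, z, std$r)
  .cca_finish(std, proj$S_star, z, constrained = TRUE, tol = tol,
              sample_ids = colnames(v), gene_ids = rownames(v))
}

#' Unconstrained correspondence analysis
#'
#' Correspondence analysis is the q = k limit of the constrained
#' ordination: a weighted PCA of the matrix in the chi-square metric,
#' obtained by SVD of the standardized matrix S itself. All inertia is
#' "constrained" (I_C = I_T). Used internally as the oracle for the
#' full-rank limit of [cca()].
#'
#' @inheritParams cca
#' @return a `cca_result` with `biplot_scores = NULL`.
#' @export
correspondence_analysis <- function(x, tol = 1e-10) {
  v <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  std <- chi_square_standardize(x)
  .cca_finish(std, std$S, z = NULL, constrained = FALSE, tol = tol,
              sample_ids = colnames(v), gene_ids = rownames(v))
}

# shared SVD / score / inertia bookkeeping for cca() and
# correspondence_analysis()
.cca_finish <- function(std, S_star, z, constrained, tol, sample_ids,
                        gene_ids) {
  S <- std$S; r <- std$r; cm <- std$c
  I_T <- sum(S^2)
  sv <- svd(S_star)
  m_cap <- min(if (constrained) ncol(z$z) else nrow(S) - 1L,
               ncol(S) - 1L, nrow(S))
  m_cap <- max(m_cap, 0L)
  keep <- which(sv$d > tol * max(sv$d, .Machine$double.eps))
  keep <- keep[keep <= m_cap]
  if (length(keep) == 0) {
    # degenerate case (e.g. a constant matrix): report one zero axis
    keep <- 1L
    sv$d[1L] <- 0
  }
  m <- length(keep)
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  alpha <- sv$d[keep]

  lc_std <- U / sqrt(r)                  # D_r^{-1/2} U
  samp_std <- V / sqrt(cm)               # D_c^{-1/2} V

  if (constrained) {
    # weighted correlations of Z with standard LC scores; since Z has
    # weighted variance 1 and D_r^{-1/2}U has unit weighted norm and
    # weighted mean 0, this reduces to Z^T D_r^{1/2} U
    biplot <- crossprod(z$z * sqrt(r), U)
    signs <- axis_signs(biplot)
  } else {
    biplot <- NULL
    signs <- axis_signs(samp_std)
  }
  U <- sweep(U, 2L, signs, "*")
  V <- sweep(V, 2L, signs, "*")
  lc_std <- sweep(lc_std, 2L, signs, "*")
  samp_std <- sweep(samp_std, 2L, signs, "*")
  if (!is.null(biplot)) biplot <- sweep(biplot, 2L, signs, "*")

  wa_std <- (S %*% V) / sqrt(r)          # D_r^{-1/2} S V
  Da <- function(M) sweep(M, 2L, alpha, "*")

  ax <- paste0("Axis", seq_len(m))
  nm <- function(M, rn) { dimnames(M) <- list(rn, ax); M }
  res <- list(
    singular_values = stats::setNames(alpha, ax),
    gene_scores_lc_standard = nm(lc_std, gene_ids),
    gene_scores_lc_principal = nm(Da(lc_std), gene_ids),
    gene_scores_wa_standard = nm(wa_std, gene_ids),
    gene_scores_wa_principal = nm(Da(wa_std), gene_ids),
    sample_scores_standard = nm(samp_std, sample_ids),
    sample_scores_principal = nm(Da(samp_std), sample_ids),
    biplot_scores = if (is.null(biplot)) NULL else
      nm(biplot, z$programme_names),
    inertia_total = I_T,
    inertia_constrained = sum(alpha^2),
    inertia_unconstrained = I_T - sum(alpha^2),
    percent_explained = if (I_T > 0) sum(alpha^2) / I_T else NA_real_,
    row_masses = stats::setNames(r, gene_ids),
    col_masses = stats::setNames(cm, sample_ids),
    constrained = constrained
  )
  class(res) <- "cca_result"
  res
}

#' @export
print.cca_result <- function(x, ...) {
  cat(if (x$constrained) "Canonical correspondence analysis"
      else "Correspondence analysis", "\n")
  cat(sprintf("axes: %d   total inertia: %.6g   constrained: %.6g (%.1f%%)\n",
              length(x$singular_values), x$inertia_total,
              x$inertia_constrained, 100 * x$percent_explained))
  ax_pct <- 100 * x$singular_values^2 / x$inertia_constrained
  cat("per-axis inertia (% of constrained):",
      paste(sprintf("%s %.1f%%", names(x$singular_values), ax_pct),
            collapse = ", "), "\n")
  invisible(x)
}

#' Principal component analysis by SVD
#'
#' Thin wrapper around [stats::prcomp()] returning eigenvalues and the
#' percentage of variance per component alongside scores and loadings.
#' With samples in rows and genes in columns, the gene loadings can be
#' used directly as an explanatory matrix for [cca()] (ordination of one
#' dataset constrained by the principal axes of another).
#'
#' @param x numeric matrix, observations in rows, variables in columns
#'   (at least 2 columns).
#' @param center,scale passed to [stats::prcomp()]; a constant column
#'   with `scale = TRUE` is an error.
#' @return list with `scores`, `loadings`, `eigenvalues`,
#'   `percent_variance`.
#' @export
pca <- function(x, center = TRUE, scale = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("pca needs at least 2 columns")
  if (scale) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0)) stop("constant column(s) cannot be scaled: ",
                            paste(colnames(x)[sds == 0], collapse = ", "))
  }
  p <- stats::prcomp(x, center = center, scale. = scale)
  ev <- p$sdev^2
  list(scores = p$x, loadings = p$rotation, eigenvalues = ev,
       percent_variance = 100 * ev / sum(ev))
}

#' Serialize a CCA result as a directory of TSV files
#'
#' Writes `singular_values.tsv`, `gene_scores.tsv`, `sample_scores.tsv`,
#' `biplot_scores.tsv` (constrained results only) and `inertia.tsv`,
#' plus a `summary.json`. Output is bit-stable given identical inputs
#' because the axis sign convention is deterministic.
#'
#' @param result a `cca_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cca_result <- function(result, dir) {
  stopifnot(inherits(result, "cca_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(data.frame(axis = names(result$singular_values),
                singular_value = unname(result$singular_values)),
     "singular_values.tsv")
  gs <- data.frame(gene_id = rownames(result$gene_scores_wa_principal),
                   result$gene_scores_wa_principal,
                   check.names = FALSE)
  colnames(gs)[-1] <- paste0("wa_", colnames(gs)[-1])
  lc <- result$gene_scores_lc_principal
  colnames(lc) <- paste0("lc_", colnames(lc))
  wt(cbind(gs, lc), "gene_scores.tsv")
  wt(data.frame(sample_id = rownames(result$sample_scores_principal),
                result$sample_scores_principal, check.names = FALSE),
     "sample_scores.tsv")
  if (!is.null(result$biplot_scores)) {
    wt(data.frame(programme = rownames(result$biplot_scores),
                  result$biplot_scores, check.names = FALSE),
       "biplot_scores.tsv")
  }
  wt(data.frame(quantity = c("inertia_total", "inertia_constrained",
                             "inertia_unconstrained", "percent_explained"),
                value = c(result$inertia_total, result$inertia_constrained,
                          result$inertia_unconstrained,
                          result$percent_explained)),
     "inertia.tsv")
  jsonlite::write_json(
    list(n_axes = length(result$singular_values),
         inertia_total = result$inertia_total,
         inertia_constrained = result$inertia_constrained,
         percent_explained = result$percent_explained,
         constrained = result$constrained),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
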