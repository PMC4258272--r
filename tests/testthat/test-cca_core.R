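test_that("chi-square standardization matches the entrywise formula oracle", {
  x <- toy_x()
  std <- chi_square_standardize(x)
  expect_equal(std$S, oracle_chisq(x), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(std$n, 21)
  expect_equal(sum(std$r), 1)
  expect_equal(sum(std$c), 1)
  # ||S||_F^2 equals Pearson chi-square / n
  expected <- sum((x - outer(rowSums(x), colSums(x)) / sum(x))^2 /
                    (outer(rowSums(x), colSums(x)) / sum(x))) / sum(x)
  expect_equal(sum(std$S^2), expected, tolerance = 1e-12)
})

test_that("chi-square standardization is scale invariant and vanishes under independence", {
  x <- toy_x()
  expect_equal(chi_square_standardize(x)$S, chi_square_standardize(2 * x)$S,
               tolerance = 1e-12)
  flat <- matrix(3, 4, 3)
  expect_true(all(abs(chi_square_standardize(flat)$S) < 1e-14))
})

test_that("explanatory standardization yields weighted mean 0, variance 1", {
  r <- rep(1 / 3, 3)
  z <- standardize_explanatory(matrix(c(1, 2, 3), ncol = 1), r)
  # hand computation: mean 2, centered (-1,0,1), weighted sd sqrt(2/3)
  expect_equal(z$z[, 1], c(-1, 0, 1) / sqrt(2 / 3), ignore_attr = TRUE)
  expect_equal(sum(r * z$z[, 1]), 0)
  expect_equal(sum(r * z$z[, 1]^2), 1)
  # idempotence: an already weighted-(0,1) column is unchanged
  z2 <- standardize_explanatory(z$z, r)
  expect_equal(z2$z, z$z, tolerance = 1e-12)
  expect_error(standardize_explanatory(matrix(5, 3, 1), r), "constant")
  # duplicated programmes are collinear
  zz <- cbind(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_error(standardize_explanatory(zz, rep(0.25, 4)), "collinear")
})

test_that("the constrained projection is a symmetric idempotent contraction", {
  x <- random_x(5, 4, seed = 11)
  std <- chi_square_standardize(x)
  z <- standardize_explanatory(matrix(rnorm(5), ncol = 1), std$r)
  pr <- constrained_projection(std$S, z, std$r)
  expect_equal(pr$Q %*% pr$Q, pr$Q, tolerance = 1e-10)
  expect_equal(pr$Q, t(pr$Q), tolerance = 1e-10)
  expect_lte(sum(pr$S_star^2), sum(std$S^2) + 1e-12)
})

test_that("a programme orthogonal to the data explains nothing", {
  # X with identical columns -> S = 0, so any Z projects to zero inertia
  x <- matrix(rep(c(1, 4, 2, 6), 3), 4, 3)
  fit <- cca(x, matrix(c(1, -1, 2, 0), ncol = 1))
  expect_equal(fit$inertia_constrained, 0, tolerance = 1e-20)
  expect_equal(unname(fit$singular_values), 0)
})

test_that("full-rank explanatory limit reproduces unconstrained CA", {
  for (seed in 1:5) {
    x <- random_x(6, 4, seed = seed)
    set.seed(seed + 100)
    Z <- matrix(rnorm(36), 6, 6)   # q = k, full rank
    fit <- cca(x, Z)
    ca <- correspondence_analysis(x)
    expect_equal(fit$singular_values, ca$singular_values, tolerance = 1e-10)
    expect_equal(fit$inertia_constrained, ca$inertia_total,
                 tolerance = 1e-10)
  }
})

test_that("single-variable constrained inertia matches brute-force projection", {
  x <- random_x(4, 3, seed = 3)
  set.seed(4); zcol <- rnorm(4)
  fit <- cca(x, matrix(zcol, ncol = 1))
  expect_length(fit$singular_values, 1L)
  # oracle: dense normal-equations projection, no QR
  std <- chi_square_standardize(x)
  zs <- standardize_explanatory(matrix(zcol, ncol = 1), std$r)$z
  W <- zs * sqrt(std$r)
  Q <- W %*% solve(crossprod(W)) %*% t(W)
  expect_equal(unname(fit$singular_values[1]^2), sum((Q %*% std$S)^2),
               tolerance = 1e-12)
})

test_that("CA of a perfect 2x2 association has a single axis with inertia 1", {
  ca <- correspondence_analysis(matrix(c(10, 0, 0, 10), 2))
  expect_length(ca$singular_values, 1L)
  expect_equal(unname(ca$singular_values), 1)
  expect_equal(ca$inertia_total, 1)
})

test_that("inertia is conserved and constrained inertia is monotone in Z", {
  for (seed in 1:10) {
    x <- random_x(8, 5, seed = seed)
    ca <- correspondence_analysis(x)
    expect_equal(sum(ca$singular_values^2), ca$inertia_total,
                 tolerance = 1e-10)
    set.seed(seed)
    Z <- matrix(rnorm(8 * 3), 8, 3)
    ic <- vapply(1:3, function(q)
      cca(x, Z[, 1:q, drop = FALSE])$inertia_constrained, numeric(1))
    expect_true(all(diff(ic) >= -1e-12))       # nested projections
    expect_lte(ic[3], ca$inertia_total + 1e-12)
    fit <- cca(x, Z)
    expect_true(all(abs(fit$biplot_scores) <= 1 + 1e-10))
    expect_equal(fit$inertia_unconstrained,
                 fit$inertia_total - fit$inertia_constrained)
  }
})

test_that("singular values and inertia agree with an independent ordination oracle", {
  skip_if_not_installed("vegan")
  x <- random_x(10, 6, seed = 21)
  set.seed(22)
  Z <- matrix(rnorm(10 * 2), 10, 2)
  fit <- ccatx::cca(x, Z)
  ref <- vegan::cca(X = as.data.frame(x), Y = as.data.frame(Z))
  expect_equal(unname(fit$singular_values^2), unname(ref$CCA$eig),
               tolerance = 1e-10)
  expect_equal(fit$inertia_total, ref$tot.chi, tolerance = 1e-10)
  ca <- correspondence_analysis(x)
  ref_ca <- vegan::cca(X = as.data.frame(x))
  expect_equal(unname(ca$singular_values^2), unname(ref_ca$CA$eig),
               tolerance = 1e-10)
})

test_that("scores obey the CA transition formula and orthonormality", {
  x <- random_x(7, 5, seed = 31)
  ca <- correspondence_analysis(x)
  # WA standard gene scores equal LC principal gene scores when Q = I
  expect_equal(ca$gene_scores_wa_standard, ca$gene_scores_lc_principal,
               tolerance = 1e-10)
  # standard scores have unit weighted norm per axis
  expect_equal(colSums(ca$row_masses * ca$gene_scores_lc_standard^2),
               rep(1, length(ca$singular_values)), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(colSums(ca$col_masses * ca$sample_scores_standard^2),
               rep(1, length(ca$singular_values)), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("gene permutation permutes gene scores but not the solution", {
  x <- random_x(9, 4, seed = 41)
  set.seed(42)
  Z <- matrix(rnorm(9 * 2), 9, 2)
  fit <- cca(x, Z)
  perm <- sample(9)
  fit_p <- cca(x[perm, ], Z[perm, , drop = FALSE])
  expect_equal(fit_p$singular_values, fit$singular_values, tolerance = 1e-10)
  expect_equal(fit_p$sample_scores_principal, fit$sample_scores_principal,
               tolerance = 1e-10)
  expect_equal(fit_p$biplot_scores, fit$biplot_scores, tolerance = 1e-10)
  expect_equal(fit_p$gene_scores_lc_standard,
               fit$gene_scores_lc_standard[perm, ], tolerance = 1e-10)
})

test_that("axis orientation is deterministic and reconstruction sign-invariant", {
  x <- random_x(8, 5, seed = 51)
  set.seed(52)
  Z <- matrix(rnorm(8 * 2), 8, 2)
  fit1 <- cca(x, Z)
  fit2 <- cca(x, Z)
  expect_identical(fit1$gene_scores_wa_principal, fit2$gene_scores_wa_principal)
  # the largest-magnitude biplot score on each axis is positive
  for (j in seq_along(fit1$singular_values)) {
    bp <- fit1$biplot_scores[, j]
    expect_gt(bp[which.max(abs(bp))], 0)
  }
})

test_that("pca reports variance shares and matches covariance eigenvalues", {
  # exact line -> PC1 carries all variance
  line <- cbind(1:5, 2 * (1:5) + 3)
  p <- pca(line)
  expect_equal(p$percent_variance[1], 100)
  # 3-point toy set: eigenvalues equal those of the covariance matrix
  m <- rbind(c(0, 0), c(1, 2), c(3, 1))
  p2 <- pca(m)
  expect_equal(unname(p2$eigenvalues), sort(eigen(stats::cov(m))$values,
                                            decreasing = TRUE),
               tolerance = 1e-12)
  expect_error(pca(cbind(1:3)), "2 columns")
  expect_error(pca(cbind(a = rep(1, 3), b = 1:3), scale = TRUE), "constant")
})

test_that("PCA gene loadings work as explanatory variables for cca", {
  pair <- generate_pair(synthetic_spec(n_genes = 120, markers_per_class = 5,
                                       seed = 9))
  # samples x genes orientation: loadings are gene-indexed
  p <- pca(t(pair$resource$values))
  fit <- cca(pair$test, p$loadings[, 1:3])
  expect_length(fit$singular_values, 3L)
  expect_true(fit$percent_explained > 0 && fit$percent_explained <= 1)
})

test_that("cca results serialize to a stable TSV directory", {
  x <- random_x(6, 4, seed = 61)
  set.seed(62)
  fit <- cca(x, matrix(rnorm(12), 6, 2))
  dir <- file.path(tempdir(), "ccares")
  write_cca_result(fit, dir)
  expect_true(all(file.exists(file.path(dir,
    c("singular_values.tsv", "gene_scores.tsv", "sample_scores.tsv",
      "biplot_scores.tsv", "inertia.tsv", "summary.json")))))
  sv <- read.delim(file.path(dir, "singular_values.tsv"))
  expect_equal(sv$singular_value, unname(fit$singular_values),
               tolerance = 1e-12)
})
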