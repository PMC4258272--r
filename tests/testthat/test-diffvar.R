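test_that("class means average replicates and ignore unknown samples", {
  res <- tiny_resource()
  cm <- class_means(res)
  expect_equal(cm$class_labels, c("ClassA", "ClassB"))
  expect_equal(unname(cm$means["mA", ]), c(8.1, 2.05))
  # permuting samples leaves the means unchanged
  perm <- subset_expression(res, samples = c(3, 1, 4, 2))
  expect_equal(class_means(perm)$means[, cm$class_labels], cm$means)
  # unknown samples excluded with a warning
  res$sample_class[4] <- "unknown"
  expect_warning(cm2 <- class_means(res), "unknown")
  expect_equal(unname(cm2$means["mB", "ClassB"]), 8)
})

test_that("differentiation variables are antisymmetric class-mean differences", {
  res <- tiny_resource()
  d_ab <- differentiation_variable(res, "ClassA", "ClassB")
  d_ba <- differentiation_variable(res, "ClassB", "ClassA")
  cm <- class_means(res)
  expect_equal(d_ab$d, unname(cm$means[, "ClassB"] - cm$means[, "ClassA"]))
  expect_equal(d_ab$d, -d_ba$d)
  expect_equal(d_ab$to_class, "ClassB")
  expect_error(differentiation_variable(res, "ClassA", "ClassA"), "differ")
  expect_error(differentiation_variable(res, "ClassA", "Nope"), "not in")
  # marker genes point the expected way
  expect_gt(d_ab$d[2], 0)  # ClassB marker up along A -> B
  expect_lt(d_ab$d[1], 0)
})

test_that("one-vs-rest uses the mean of class means, not pooled samples", {
  # three classes with unequal replicate counts; per-gene class means are
  # 5, 1, 3 so d = 5 - mean(1, 3) = 3 (pooled would give a different rest)
  vals <- rbind(c(5, 5, 1, 3, 3, 3), c(10, 10, 2, 6, 6, 6))
  res <- quiet_em(vals, c("g1", "g2"),
                  sample_ids = paste0("s", 1:6),
                  sample_class = c("T", "T", "O1", "O2", "O2", "O2"))
  d <- one_vs_rest_variable(res, "T")
  expect_equal(d$d, c(3, 6))
  # with exactly two classes it reduces to the pairwise variable
  res2 <- tiny_resource()
  expect_equal(one_vs_rest_variable(res2, "ClassB")$d,
               differentiation_variable(res2, "ClassA", "ClassB")$d)
  expect_error(one_vs_rest_variable(res2, "Nope"), "not in")
  single <- quiet_em(matrix(1:4, 2), c("g1", "g2"),
                     sample_class = c("A", "A"))
  expect_error(one_vs_rest_variable(single, "A"), "2 classes")
})

test_that("select_de_genes recovers planted effects and honours both filters", {
  set.seed(123)
  k <- 1000
  vals <- matrix(rnorm(k * 10, mean = 5, sd = 0.3), k, 10)
  vals[1:20, 1:5] <- vals[1:20, 1:5] + 4     # planted DE genes
  vals <- pmax(vals, 0)
  res <- quiet_em(vals, paste0("g", seq_len(k)),
                  sample_class = rep(c("A", "B"), each = 5))
  hits <- select_de_genes(res, "A", "B", fdr = 0.01, fc_percentile = 2)
  expect_setequal(hits, paste0("g", 1:20))
  # no-filter limit: fdr = 1 and fc_percentile = 50 pass every gene with a
  # nonzero mean difference
  all_genes <- select_de_genes(res, "A", "B", fdr = 1, fc_percentile = 50)
  expect_length(all_genes, k)
  expect_error(select_de_genes(res, "A", "B", fc_percentile = 60),
               "fc_percentile")
  # single replicates are rejected with advice
  thin <- subset_expression(res, samples = c(1, 6))
  thin$sample_class <- c("A", "B")
  expect_error(select_de_genes(thin, "A", "B"), "replicates")
})

test_that("select_de_genes is invariant to sample order and global shifts", {
  set.seed(5)
  vals <- matrix(rnorm(200 * 6, 5), 200, 6)
  vals[1:5, 1:3] <- vals[1:5, 1:3] + 3
  res <- quiet_em(pmax(vals, 0), paste0("g", 1:200),
                  sample_class = rep(c("A", "B"), each = 3))
  base <- select_de_genes(res, "A", "B", fdr = 0.05, fc_percentile = 5)
  perm <- subset_expression(res, samples = sample(6))
  expect_setequal(select_de_genes(perm, "A", "B", fdr = 0.05,
                                  fc_percentile = 5), base)
  shifted <- res
  shifted$values <- res$values + 2
  expect_setequal(select_de_genes(shifted, "A", "B", fdr = 0.05,
                                  fc_percentile = 5), base)
})

test_that("lineage-specific filter applies the RPKM floor and fold rule", {
  # class means: g1 (10, 2, 3): >=5 and >=2x others -> specific to A
  # g2 (8, 6, 1): fails 2-fold vs B; g3 (4, 1, 1): fails RPKM floor
  vals <- rbind(c(10, 10, 2, 2, 3, 3),
                c(8, 8, 6, 6, 1, 1),
                c(4, 4, 1, 1, 1, 1))
  res <- quiet_em(vals, c("g1", "g2", "g3"),
                  sample_class = rep(c("A", "B", "C"), each = 2))
  expect_equal(select_lineage_genes(res, "A"), "g1")
  expect_equal(select_lineage_genes(res, "A", min_rpkm = 3), c("g1", "g3"))
})

test_that("select_top_features ranks by |d| with lexicographic ties, prefix-monotone", {
  vals <- rbind(c(9, 1), c(1, 9), c(5, 5), c(6, 4))
  res <- quiet_em(vals, c("bGene", "aGene", "flat", "mid"),
                  sample_class = c("A", "B"))
  # |d| for target A: bGene 8, aGene 8, flat 0, mid 2; tie broken by id
  expect_equal(select_top_features(res, "A", 1), "aGene")
  expect_equal(select_top_features(res, "A", 2), c("aGene", "bGene"))
  expect_equal(select_top_features(res, "A", 4),
               c("aGene", "bGene", "mid", "flat"))
  for (n in 1:3) {
    expect_equal(select_top_features(res, "A", n),
                 select_top_features(res, "A", n + 1)[1:n])
  }
  expect_error(select_top_features(res, "A", 0), "positive")
  expect_error(select_top_features(res, "A", 5), "exceeds")
})

test_that("planted synthetic markers dominate the top features", {
  pair <- generate_pair(synthetic_spec(n_genes = 200, markers_per_class = 5,
                                       seed = 77))
  top <- select_top_features(pair$resource, "Th2", 5)
  expect_setequal(top, pair$markers$Th2)
})
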