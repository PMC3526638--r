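# Discovery-phase statistics: the Re enrichment factor, the permutation
# engine against a full-enumeration oracle, the significance filter,
# normalization, clustering and PCA.

test_that("Re reproduces the hand-evaluated formula", {
  m <- matrix(c(8, 2, 2, 8), nrow = 2, byrow = TRUE,
              dimnames = list(c("prot1", "prot2"), c("s1", "s2")))
  re <- enrichment_factor(m)
  # (8/10) / (10/20) = 1.6
  expect_equal(re["prot1", "s1"], 1.6)
  expect_equal(re["prot1", "s2"], 0.4)

  # identical share in every sample -> Re = 1 everywhere
  hom <- matrix(c(3, 6, 9, 1, 2, 3), nrow = 2, byrow = TRUE)
  expect_equal(unname(enrichment_factor(hom)),
               matrix(1, 2, 3), tolerance = 1e-12)

  # zero count cell -> Re = 0; all-zero protein dropped; all-zero matrix errors
  z <- matrix(c(0, 4, 2, 2, 0, 0), nrow = 3, byrow = TRUE)
  re <- enrichment_factor(z)
  expect_equal(nrow(re), 2)
  expect_equal(re[1, 1], 0)
  expect_error(enrichment_factor(matrix(0, 2, 2)), "all-zero")
})

test_that("Re weighted-sum conservation holds exactly on random matrices", {
  set.seed(31)
  for (i in 1:50) {
    m <- matrix(rpois(20 * 6, lambda = sample(1:50, 1)), nrow = 20)
    m[1, ] <- m[1, ] + 1  # ensure a nonzero matrix
    re <- enrichment_factor(m)
    keep <- rowSums(m) > 0
    w <- rowSums(m[keep, , drop = FALSE]) / sum(m)
    expect_equal(unname(colSums(re * w)), rep(1, 6), tolerance = 1e-12)
  }
})

test_that("permutation p-values match full-enumeration oracle on 3-vs-3 rows", {
  set.seed(32)
  for (i in 1:5) {
    v1 <- rnorm(3); v2 <- rnorm(3, mean = i / 2)
    exact <- oracle_exact_perm_p(v1, v2)
    p <- permutation_test(matrix(c(v1, v2), nrow = 1),
                          rep(c("a", "b"), each = 3),
                          n_perm = 20000, statistic = "t", seed = 32L)
    expect_equal(p, exact, tolerance = 0.02)
  }
})

test_that("permutation extremes behave as defined", {
  # perfectly separated row reaches the add-one floor once the permutation
  # space is large enough that the observed split is never redrawn
  g12 <- rep(c("a", "b"), each = 12)
  sep <- matrix(c(1:12, 101:112), nrow = 1)
  p <- permutation_test(sep, g12, n_perm = 999, seed = 33L)
  expect_equal(p, 1 / 1000)
  g <- rep(c("a", "b"), each = 4)
  # identical multisets per group -> p near 1
  same <- matrix(rep(c(5, 6, 7, 8), 2), nrow = 1)
  expect_gt(permutation_test(same, g, n_perm = 999, seed = 33L), 0.5)
  # constant row -> p = 1
  expect_equal(permutation_test(matrix(3, 1, 8), g, n_perm = 99, seed = 1L), 1)
  expect_error(permutation_test(matrix(1:4, 1), c("a", "a", "a", "b"), 10),
               ">= 2 samples")
})

test_that("permutation p-values under a true null are super-uniform", {
  set.seed(34)
  x <- matrix(rnorm(300 * 10), nrow = 300)
  p <- permutation_test(x, rep(c("a", "b"), each = 5), n_perm = 499,
                        seed = 34L)
  for (t in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    mc_slack <- 3 * sqrt(t * (1 - t) / 300)
    expect_lte(mean(p <= t), t + mc_slack + 1 / 500)
  }
})

test_that("significance filter applies the configured rule", {
  expect_equal(sum(filter_significant(rep(0.5, 10), alpha = 0.01)$significant), 0)
  expect_equal(sum(filter_significant(rep(0.5, 10), alpha = 0.999)$significant), 10)
  p_a <- c(0.005, 0.5, 0.5, 0.005)
  p_t <- cbind(c(0.5, 0.005, 0.5, 0.005), c(0.5, 0.5, 0.5, 0.5))
  or_rule <- filter_significant(p_a, p_t, alpha = 0.01, rule = "or")
  expect_equal(or_rule$significant, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(or_rule$which_test, c("anova", "ttest", "none", "both"))
  and_rule <- filter_significant(p_a, p_t, alpha = 0.01, rule = "and")
  expect_equal(and_rule$significant, c(FALSE, FALSE, FALSE, TRUE))
  expect_error(filter_significant(p_a, alpha = 0), "alpha")
})

test_that("log2-quantile normalization matches its contract", {
  # identical columns are left at log2(x + 1)
  m <- matrix(c(0, 3, 7, 0, 3, 7), ncol = 2)
  expect_equal(normalize_log_quantile(m), log2(m + 1))
  # all columns share the same sorted values afterwards (tie-free input;
  # with ties the tie policy replaces rank ranges by their reference mean)
  set.seed(35)
  r <- matrix(rlnorm(60, 3, 0.5), ncol = 3)
  nm <- normalize_log_quantile(r)
  s <- apply(nm, 2, sort)
  expect_equal(s[, 1], s[, 2])
  expect_equal(s[, 1], s[, 3])
  # 3 x 2 toy against the hand-computed rank-mean table:
  # log2(m+1) columns (1,2,3) and (3,4,5) -> sorted row means (2,3,4)
  toy <- matrix(c(1, 3, 7, 7, 15, 31), ncol = 2)
  expect_equal(unname(normalize_log_quantile(toy)),
               matrix(c(2, 3, 4, 2, 3, 4), ncol = 2))
  # ties receive the mean of the reference values over their rank range
  tied <- matrix(c(5, 5, 9, 1, 3, 7), ncol = 2)  # col1 ranks {1,2} tied
  ref <- rowMeans(apply(log2(tied + 1), 2, sort))
  expect_equal(unname(normalize_log_quantile(tied))[1:2, 1],
               rep(mean(ref[1:2]), 2))
})

test_that("quantile normalization agrees with limma on tie-free matrices", {
  skip_if_not_installed("limma")
  set.seed(36)
  x <- matrix(rlnorm(200 * 5), ncol = 5)  # continuous -> ties absent
  expect_equal(unname(normalize_log_quantile(x)),
               unname(limma::normalizeQuantiles(log2(x + 1))),
               tolerance = 1e-10)
})

test_that("hierarchical clustering recovers planted groups and merges duplicates", {
  set.seed(37)
  x <- cbind(matrix(rnorm(50 * 6, 0, 0.2), ncol = 6),
             matrix(rnorm(50 * 5, 10, 0.2), ncol = 5))
  colnames(x) <- paste0("s", 1:11)
  cl <- hierarchical_cluster(x, k = 2)
  expect_equal(length(unique(cl$cluster[1:6])), 1)
  expect_equal(length(unique(cl$cluster[7:11])), 1)
  expect_true(cl$cluster[1] != cl$cluster[7])

  dup <- cbind(x[, 1], x[, 1], x[, 7])
  hc <- hierarchical_cluster(dup, k = 2)$hclust
  expect_equal(hc$height[1], 0)
  expect_error(hierarchical_cluster(x[, 1, drop = FALSE]), "two samples")
})

test_that("single linkage on collinear points reproduces hand-traced merges", {
  # samples at positions 0, 1, 3, 7 on a line; single linkage merges at
  # heights 1 (0-1), 2 (cluster-3), 4 (cluster-7)
  x <- matrix(c(0, 1, 3, 7), nrow = 1)
  colnames(x) <- paste0("s", 1:4)
  hc <- hierarchical_cluster(x, k = 2, method = "single")$hclust
  expect_equal(hc$height, c(1, 2, 4))
})

test_that("PCA bi-plot decomposition is exact and deterministically signed", {
  set.seed(38)
  x <- matrix(rnorm(12 * 8), nrow = 12)
  pc <- pca_biplot(x)
  recon <- pc$scores %*% t(pc$loadings) +
    matrix(rowMeans(x), nrow = ncol(x), ncol = nrow(x), byrow = TRUE)
  expect_equal(unname(recon), unname(t(x)), tolerance = 1e-10)
  # sign convention: the largest-magnitude loading of each component is positive
  for (j in seq_len(ncol(pc$loadings))) {
    l <- pc$loadings[, j]
    expect_gte(l[which.max(abs(l))], 0)
  }
  # data confined to one direction -> PC1 explains everything
  one_dir <- outer(c(1, 2, 3), c(0, 1, 2, 4))
  pc1 <- pca_biplot(one_dir)
  expect_equal(pc1$var_explained[1], 1)
  expect_error(pca_biplot(matrix(5, 3, 3)), "zero-variance")
})

test_that("PCA separates a planted two-group shift on one component", {
  set.seed(39)
  x <- matrix(rnorm(40 * 12), nrow = 40)
  x[1:10, 7:12] <- x[1:10, 7:12] + 4
  pc <- pca_biplot(x)
  lab <- rep(c(0, 1), each = 6)
  auc1 <- oracle_rank_auc(pc$scores[, 1], lab)
  expect_true(auc1 <= 0.05 || auc1 >= 0.95)
})

test_that("spectral counts track assigned true abundances", {
  sim <- generate_count_matrix(count_sim_config(n_proteins = 800,
                                                log2_fold = 0, seed = 40L))
  # within each sample, counts should rank like the (hidden) base
  # abundances; recover them via the global mean as a proxy-free check:
  # correlation between per-protein total counts across two disjoint
  # halves of samples is strongly positive
  h1 <- rowSums(sim$counts[, 1:9]); h2 <- rowSums(sim$counts[, 10:18])
  expect_gt(cor(h1, h2, method = "spearman"), 0.8)
})

test_that("lfq_stats returns a coherent per-protein table", {
  sim <- generate_count_matrix(count_sim_config(n_proteins = 60,
                                                frac_differential = 0.2,
                                                log2_fold = 2, seed = 41L))
  res <- lfq_stats(sim$counts, sim$group, n_perm = 200, seed = 42L)
  expect_true(all(c("protein_id", "re_mean_N", "re_mean_AD", "re_mean_SCC",
                    "p_anova", "significant", "which_test") %in% names(res)))
  expect_true(all(res$p_anova > 0 & res$p_anova <= 1))
  pt_cols <- grep("^p_t_", names(res))
  expect_equal(length(pt_cols), 3)  # three pairwise contrasts
})
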