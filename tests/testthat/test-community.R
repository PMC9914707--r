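test_that("chao1 matches the bias-corrected formula and its bounds", {
  expect_equal(chao1(c(1, 1, 2, 3)), 4.5)
  expect_equal(chao1(c(5, 10, 20)), 3)       # no singletons: S_obs
  expect_equal(chao1(numeric(0)), 0)
  expect_equal(chao1(c(0, 0, 0)), 0)
  expect_error(chao1(c(0.2, 0.8)), "integer counts")
  set.seed(31)
  for (i in 1:50) {
    x <- rpois(sample(5:60, 1), lambda = sample(1:5, 1))
    expect_gte(chao1(x), sum(x > 0))
  }
  # monotone non-decreasing in F1 at fixed F2 and S_obs is implied by
  # the closed form; spot-check adjacent F1 values
  expect_gte(chao1(c(1, 1, 1, 2, 2)), chao1(c(1, 1, 3, 2, 2)))
})

test_that("ace equals an independent transcription of the classic formula", {
  set.seed(32)
  for (i in 1:100) {
    x <- rpois(sample(5:80, 1), lambda = sample(1:8, 1))
    expected <- ace_oracle(x)
    if (is.na(expected)) next  # undefined-coverage case tested below
    expect_equal(ace(x), expected, tolerance = 1e-9,
                 info = paste("vector", i))
  }
  expect_equal(ace(c(50, 60, 70)), 3)  # no rare class: S_obs
  # all-singleton rare class: coverage 0, falls back to Chao1
  expect_warning(v <- ace(c(1, 1, 1)), "Chao1")
  expect_equal(v, chao1(c(1, 1, 1)))
})

test_that("richness estimators agree with vegan and ignore feature order", {
  skip_if_not_installed("vegan")
  set.seed(33)
  for (i in 1:20) {
    x <- rpois(40, lambda = 3)
    est <- vegan::estimateR(x)
    expect_equal(chao1(x), unname(est["S.chao1"]), tolerance = 1e-8)
    if (!is.na(est["S.ACE"]))
      expect_equal(ace(x), unname(est["S.ACE"]), tolerance = 1e-8)
    perm <- sample(x)
    expect_equal(chao1(perm), chao1(x))
    expect_equal(ace(perm), ace(x))
  }
})

test_that("alpha_diversity summarises each sample's counts", {
  m <- rbind(s1 = c(1, 1, 2, 3), s2 = c(0, 4, 4, 4))
  d <- alpha_diversity(m)
  expect_equal(d$sample_id, c("s1", "s2"))
  expect_equal(d$chao1, c(4.5, 3))
  expect_equal(d$observed, c(4L, 3L))
})

test_that("pca_ordination centres, orders and sign-fixes components", {
  set.seed(34)
  x <- matrix(rnorm(10 * 6), 10, 6)
  fit <- pca_ordination(x, n_components = 6)
  expect_equal(sum(fit$explained_variance), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$explained_variance) <= 1e-12))
  # sign convention: the largest-magnitude loading of each PC is positive
  for (j in seq_len(ncol(fit$loadings)))
    expect_gt(fit$loadings[which.max(abs(fit$loadings[, j])), j], 0)
  # rank-1 data: PC1 explains everything
  line <- outer(seq_len(5), c(1, 2, -1))
  f1 <- pca_ordination(line)
  expect_equal(f1$explained_variance[1], 1, tolerance = 1e-9)
  # permutation equivariance of samples
  perm <- sample(nrow(x))
  fp <- pca_ordination(x[perm, ], n_components = 2)
  expect_equal(unname(fp$scores), unname(pca_ordination(x)$scores[perm, ]),
               tolerance = 1e-8)
  expect_error(pca_ordination(x[1, , drop = FALSE]), ">= 2 samples")
})

test_that("group_test runs ANOVA + Tukey per feature and flags degenerates", {
  set.seed(35)
  groups <- rep(c("Control", "Model", "SjC"), each = 4)
  x <- cbind(
    shifted = rnorm(12, mean = rep(c(0, 3, 0), each = 4), sd = 0.3),
    null = rnorm(12),
    flat = rep(1, 12))
  res <- group_test(x, groups)
  expect_equal(res$feature_id, c("shifted", "null", "flat"))
  expect_true(res$significant[1])
  expect_true(res$degenerate[3])
  expect_true(is.na(res$anova_p[3]))
  expect_false(res$significant[3])
  # Tukey columns cover all three group pairs
  tk <- grep("^tukey_", names(res), value = TRUE)
  expect_setequal(tk, c("tukey_Model_vs_Control", "tukey_SjC_vs_Control",
                        "tukey_SjC_vs_Model"))
  # the shifted feature separates Model from both other groups
  expect_lt(res$tukey_Model_vs_Control[1], 0.05)
  expect_lt(res$tukey_SjC_vs_Model[1], 0.05)
  expect_gt(res$tukey_SjC_vs_Control[1], 0.05)
  # cross-check against aov run directly
  direct <- summary(stats::aov(x[, 1] ~ factor(groups)))[[1]]
  expect_equal(res$anova_F[1], direct[1, "F value"])
  expect_equal(res$anova_p[1], direct[1, "Pr(>F)"])
})

test_that("two-group ANOVA reduces to the pooled two-sided t-test", {
  set.seed(36)
  g <- rep(c("a", "b"), each = 6)
  for (i in 1:10) {
    v <- rnorm(12, mean = rep(c(0, runif(1, 0, 2)), each = 6))
    res <- group_test(matrix(v, ncol = 1), g)
    tt <- t.test(v ~ g, var.equal = TRUE)
    expect_equal(res$anova_p[1], tt$p.value, tolerance = 1e-10)
  }
})

test_that("group_test validates its design", {
  expect_error(group_test(matrix(rnorm(8), 4), rep("a", 4)), ">= 2 groups")
  expect_error(group_test(matrix(rnorm(6), 3), c("a", "a", "b")),
               ">= 2 samples")
  res_bh <- group_test(matrix(rnorm(36), 12), rep(c("a", "b", "c"), 4),
                       p_adjust = "BH")
  expect_true("anova_p_adj" %in% names(res_bh))
})
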