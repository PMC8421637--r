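test_that("paired t follows the textbook formula", {
  r <- paired_t(c(0, 0, 0), c(1, 2, 3))
  expect_equal(r$statistic, 3.4641, tolerance = 1e-4)
  expect_equal(r$df, 2L)
  expect_equal(r$p, t.test(c(1, 2, 3))$p.value, tolerance = 1e-12)
  # antisymmetry
  set.seed(1)
  a <- rnorm(15)
  b <- rnorm(15)
  expect_equal(paired_t(a, b)$statistic, -paired_t(b, a)$statistic)
  expect_equal(paired_t(a, b)$statistic,
               unname(t.test(b, a, paired = TRUE)$statistic),
               tolerance = 1e-12)
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)), "zero variance")
})

test_that("the ANCOVA F matches an independent least-squares solve", {
  set.seed(2)
  n <- 30
  g <- rep(c("ctl", "dep"), each = 15)
  covs <- data.frame(age = rnorm(n, 25, 4), edu = rnorm(n, 15, 2),
                     fd = runif(n, 0.05, 0.2))
  y <- rnorm(n) + 0.4 * (g == "dep") + 0.1 * covs$age
  r <- ancova_group_effect(y, g, covs)
  # oracle: explicit normal equations via solve(X'X)
  X <- cbind(1, g == "dep", as.matrix(covs))
  bf <- solve(t(X) %*% X, t(X) %*% y)
  rss_f <- sum((y - X %*% bf)^2)
  Xr <- X[, -2]
  br <- solve(t(Xr) %*% Xr, t(Xr) %*% y)
  rss_r <- sum((y - Xr %*% br)^2)
  F_oracle <- (rss_r - rss_f) / (rss_f / (n - 5))
  expect_equal(r$statistic, F_oracle, tolerance = 1e-10)
  expect_equal(r$df, c(1, n - 5))
  # cross-check against lm + anova
  a <- anova(lm(y ~ as.matrix(covs)), lm(y ~ g + as.matrix(covs)))
  expect_equal(r$statistic, a$F[2], tolerance = 1e-10)
  expect_equal(r$p, a$`Pr(>F)`[2], tolerance = 1e-10)
})

test_that("ANCOVA degenerates as theory says", {
  # identical outcome and covariates across groups: exactly no group effect
  y <- rep(c(1.3, 2.1, 0.7, 1.8, 2.4), 2)
  covs <- data.frame(age = rep(c(21, 24, 27, 23, 25), 2))
  g <- rep(c("a", "b"), each = 5)
  expect_lt(ancova_group_effect(y, g, covs)$statistic, 1e-20)
  # without covariates the F equals the squared pooled two-sample t
  set.seed(3)
  y2 <- rnorm(24)
  g2 <- rep(c("a", "b"), each = 12)
  f <- ancova_group_effect(y2, g2)$statistic
  tt <- t.test(y2[g2 == "a"], y2[g2 == "b"], var.equal = TRUE)$statistic
  expect_equal(f, unname(tt)^2, tolerance = 1e-10)
  expect_error(ancova_group_effect(y2, g2, data.frame(k = rep(1, 24))),
               "rank deficient")
})

test_that("summary-statistic t tests recompute published group comparisons", {
  bdi <- two_sample_t_summary(24, 10.58, 6.68, 26, 4.04, 4.65)
  expect_equal(round(bdi$statistic, 3), 4.044)
  expect_equal(bdi$df, 48)
  expect_lt(bdi$p, 0.001)
  expect_equal(two_sample_t_summary(10, 5, 1, 12, 5, 2)$statistic, 0)
  # pooled equals Welch when group sizes and spreads match
  a <- two_sample_t_summary(15, 3.2, 1.1, 15, 2.7, 1.1, "pooled")
  b <- two_sample_t_summary(15, 3.2, 1.1, 15, 2.7, 1.1, "welch")
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
  expect_equal(a$df, b$df, tolerance = 1e-12)
  expect_error(two_sample_t_summary(5, 1, 0, 5, 2, 0), "not both 0")
})

test_that("Spearman correlation uses mid-ranks and the t approximation", {
  expect_equal(spearman(1:10, (1:10)^3)$statistic, 1)
  r <- spearman(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$statistic, 0.6)
  ct <- cor.test(c(3, 1, 4, 1, 5, 9, 2, 6), c(2, 7, 1, 8, 2, 8, 1, 8),
                 method = "spearman", exact = FALSE)
  ours <- spearman(c(3, 1, 4, 1, 5, 9, 2, 6), c(2, 7, 1, 8, 2, 8, 1, 8))
  expect_equal(ours$statistic, unname(ct$estimate), tolerance = 1e-12)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
  # exact option for small tie-free samples
  x <- c(2, 5, 1, 4, 3)
  y <- c(1, 4, 2, 5, 3)
  expect_equal(spearman(x, y, exact = TRUE)$p,
               cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
})

test_that("partial correlation matches the precision-matrix formulation", {
  set.seed(4)
  n <- 10
  x <- rnorm(n)
  y <- rnorm(n)
  covs <- matrix(rnorm(n * 3), n, 3)
  r <- partial_pearson(x, y, covs)
  # oracle: partial correlation from the inverse correlation matrix
  Om <- solve(cor(cbind(x, y, covs)))
  expect_equal(r$statistic, -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2]),
               tolerance = 1e-10)
  expect_equal(r$df, n - 3 - 2)
  # reductions
  expect_equal(partial_pearson(x, y)$statistic, cor(x, y), tolerance = 1e-12)
  y_lin <- covs %*% c(1, -2, 0.5)
  expect_lt(abs(partial_pearson(x, as.numeric(y_lin), covs)$statistic), 1e-6)
})

test_that("BH adjustment reproduces the hand-computed step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.04, 0.05)), c(0.04, 0.04, 0.05, 0.05))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.3, 0.001, 0.04, 0.9, 0.02)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_equal(order(q[order(p)]), seq_along(p))  # order preserved
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the cohort battery emits the right families and is order-invariant", {
  small <- planted_design(n_nodes = 12, n_volumes = 150,
                          base_partition = rep(1:3, each = 4),
                          within_module_corr = 0.8)
  w <- window_config(40, 5, 10)
  coh <- generate_cohort(c(dependent = 8, control = 9), list(pre = small),
                         effect = 0.5, seed = 21, window = w,
                         events_lambda = 3)
  res <- run_study_stats(coh, "subnetwork")
  for (key in unique(paste(res$test, res$group))) {
    expect_equal(sum(paste(res$test, res$group) == key), 6L)
  }
  expect_true(all(res$p_fdr >= res$p - 1e-15))
  resg <- run_study_stats(coh, "global")
  expect_equal(resg$p_fdr, resg$p)  # single global outcome is unadjusted
  # permuting subjects changes nothing
  coh_perm <- coh
  idx <- rev(seq_len(nrow(coh$subjects)))
  coh_perm$subjects <- coh$subjects[idx, ]
  res_perm <- run_study_stats(coh_perm, "subnetwork")
  m <- match(paste(res$outcome, res$test, res$group),
             paste(res_perm$outcome, res_perm$test, res_perm$group))
  expect_equal(res$statistic, res_perm$statistic[m], tolerance = 1e-12)
})
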