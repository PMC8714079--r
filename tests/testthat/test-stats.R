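test_that("normality assessment is a validated Shapiro-Wilk p-value", {
  expect_error(assess_normality(c(1, 2)), "3 <= n")
  # frozen reference value computed independently (scipy.stats.shapiro)
  x <- c(2.1, 3.4, 1.9, 2.8, 3.0, 2.5, 3.9, 2.2, 2.7, 3.1)
  expect_equal(assess_normality(x), 0.9403260, tolerance = 1e-6)
})

test_that("Shapiro-Wilk rejects at close to nominal rate under the null", {
  set.seed(71)
  rej <- mean(replicate(2000, assess_normality(rnorm(50)) < 0.05))
  expect_gt(rej, 0.035)
  expect_lt(rej, 0.065)
})

# deterministic fixtures with known screen outcomes: exact normal scores pass
# Shapiro-Wilk with p ~ 1; the heavy-tailed vector fails it decisively
norm_scores <- function(n, mean = 0, sd = 1) mean + sd * qnorm((1:n - 0.5) / n)
skewed <- c(rep(1, 15), 8, 9, 10, 30, 60)

test_that("the decision tree picks the stated test in every cell of the grid", {
  g_sim  <- list(a = norm_scores(15), b = norm_scores(15, 1, sqrt(2)))
  g_diff <- list(a = norm_scores(15), b = norm_scores(15, 1, 2))
  expect_gt(choose_test(g_sim)$variance_ratio, 1)
  expect_lt(choose_test(g_sim)$variance_ratio, 3)
  expect_equal(choose_test(g_sim)$test, "student_t")
  expect_gte(choose_test(g_diff)$variance_ratio, 3)
  expect_equal(choose_test(g_diff)$test, "welch_t")

  g3_sim  <- list(a = norm_scores(15), b = norm_scores(15, 1), c = norm_scores(15, 2))
  g3_diff <- list(a = norm_scores(15), b = norm_scores(15, 1, 2), c = norm_scores(15, 2))
  expect_equal(choose_test(g3_sim)$test, "anova_tukey_kramer")
  expect_equal(choose_test(g3_diff)$test, "anova_tukey_kramer")

  expect_equal(choose_test(list(a = skewed, b = norm_scores(15)))$test, "kruskal_dunn_bh")
  expect_equal(choose_test(list(a = skewed, b = skewed + 1))$test, "kruskal_dunn_bh")
  expect_equal(choose_test(list(a = norm_scores(15), b = norm_scores(15, 1, 2),
                                c = skewed))$test, "kruskal_dunn_bh")
  expect_equal(choose_test(list(a = norm_scores(15), b = norm_scores(15),
                                c = skewed))$test, "kruskal_dunn_bh")

  expect_error(choose_test(list(a = 1:2, b = 1:10)), "n >= 3")
})

test_that("the plan records its inputs and the tree is a pure function of them", {
  plan <- choose_test(list(a = norm_scores(12), b = norm_scores(12, 0.5)))
  expect_length(plan$normality_p, 2)
  expect_true(is.finite(plan$variance_ratio))
  plan2 <- choose_test(list(a = norm_scores(12), b = norm_scores(12, 0.5)))
  expect_identical(plan[c("test", "normality_p", "variance_ratio")],
                   plan2[c("test", "normality_p", "variance_ratio")])
})

test_that("identical groups are not called significant", {
  set.seed(72)
  g <- rnorm(20, 1, 0.1)
  res <- run_comparison(list(a = g, b = g + rnorm(20, 0, 1e-9)))
  expect_gt(res$pairs$p_raw, 0.5)
  expect_false(res$pairs$significant)
  expect_error(run_comparison(list(a = rep(1, 5), b = rep(1, 5))), "degenerate")
})

test_that("Tukey-Kramer adjusted p-values match the reference implementation", {
  set.seed(73)
  groups <- list(a = rnorm(12, 0), b = rnorm(15, 0.5), c = rnorm(9, 1))
  res <- run_comparison(groups, choose_test(groups))
  expect_equal(res$plan$test, "anova_tukey_kramer")

  df <- data.frame(y = unlist(groups), g = rep(names(groups), lengths(groups)))
  ref <- TukeyHSD(aov(y ~ g, data = df))$g
  # match pairs irrespective of orientation/order
  key <- apply(res$pairs[, c("group1", "group2")], 1,
               function(r) paste(sort(r), collapse = "-"))
  ref_key <- sapply(strsplit(rownames(ref), "-"),
                    function(r) paste(sort(r), collapse = "-"))
  expect_equal(res$pairs$p_adj[order(key)], unname(ref[, "p adj"][order(ref_key)]),
               tolerance = 1e-10)
  expect_true(all(res$pairs$p_adj >= res$pairs$p_raw - 1e-12))
  # omnibus F agrees with aov
  expect_equal(res$overall$p,
               summary(aov(y ~ g, data = df))[[1]][["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("Dunn z-statistics match a hand computation on a small tied example", {
  groups <- list(a = c(1, 2, 4), b = c(3, 5, 6), c = c(2, 7, 8))
  res <- dunn_test(groups)
  # independent computation from the definition
  v <- unlist(groups); r <- rank(v); N <- 9
  rbar <- c(mean(r[1:3]), mean(r[4:6]), mean(r[7:9]))
  ties <- table(v); tt <- sum(ties^3 - ties) / (12 * (N - 1))
  sg <- sqrt((N * (N + 1) / 12 - tt) * (2 / 3))
  z_ab <- (rbar[1] - rbar[2]) / sg
  expect_equal(res$pairs$statistic[res$pairs$group1 == "a" & res$pairs$group2 == "b"],
               z_ab)
  expect_equal(res$pairs$p_adj, benjamini_hochberg(res$pairs$p_raw))
  expect_equal(unname(res$overall$statistic),
               unname(kruskal.test(v, factor(rep(letters[1:3], each = 3)))$statistic))
})

test_that("Benjamini-Hochberg follows the step-up formula", {
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6)
  adj <- benjamini_hochberg(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_true(all(adj <= 1))
  # invariant to input order
  perm <- sample(seq_along(p))
  expect_equal(benjamini_hochberg(p[perm]), adj[perm])
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("lognormal data routes the comparison to the non-parametric branch", {
  set.seed(74)
  picks <- replicate(50, {
    g <- simulate_measurement_groups(c(1, 1), c(0.8, 0.8), c(30, 30),
                                     distribution = "lognormal",
                                     seed = sample.int(1e6, 1))
    choose_test(g)$test
  })
  expect_gt(mean(picks == "kruskal_dunn_bh"), 0.9)
})
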