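test_that("trial errors average in consecutive non-overlapping blocks", {
  expect_equal(block_average_errors(c(3, 2, 1)), 2)
  expect_equal(block_average_errors(c(0, 0, 0, 6, 6, 6)), c(0, 6))
  expect_error(block_average_errors(rep(1, 7)), "blocks of 3")
  expect_equal(block_average_errors(1:4, block_size = 2), c(1.5, 3.5))
})

test_that("t-tests match their closed forms", {
  same <- c(1, 2, 3, 4)
  r <- t_test(same, same, "student")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  w <- t_test(c(1, 2, 3), c(2, 3, 4), "welch")
  expect_equal(w$statistic, -sqrt(3) / sqrt(2), tolerance = 1e-6) # -1.224745
  expect_equal(w$df, 4)
  expect_equal(w$p_value, 0.2878641, tolerance = 1e-6)
  # equal n and equal sample variances: Welch df = Student df, same p
  x <- c(1, 2, 3, 5); y <- x + 2
  expect_equal(t_test(x, y, "welch")$p_value, t_test(x, y, "student")$p_value)
  expect_error(t_test(1, c(1, 2)), "at least 2")
})

test_that("one-way ANOVA reduces to t^2 for two groups and 0 for identical ones", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  r <- oneway_anova_tukey(g)
  expect_equal(r$anova$F, 0)
  expect_true(all(r$tukey$p_adj == 1))
  set.seed(61)
  x <- rnorm(8); y <- rnorm(8, 0.5)
  r2 <- oneway_anova_tukey(list(x = x, y = y))
  tt <- t_test(x, y, "student")
  expect_equal(r2$anova$F, tt$statistic^2, tolerance = 1e-10)
  expect_equal(r2$anova$p_value, tt$p_value, tolerance = 1e-10)
  expect_error(oneway_anova_tukey(list(a = 1, b = c(1, 2))), "at least 2")
})

test_that("Tukey adjusted p agrees with the studentized range distribution", {
  set.seed(62)
  g <- list(a = rnorm(6), b = rnorm(6, 0.8), c = rnorm(6, 1.6))
  r <- oneway_anova_tukey(g)
  n <- 6; k <- 3; dfe <- 15
  mse <- sum(vapply(g, function(x) sum((x - mean(x))^2), 1)) / dfe
  means <- vapply(g, mean, 1)
  combs <- combn(3, 2)
  for (j in seq_len(ncol(combs))) {
    q <- abs(means[combs[2, j]] - means[combs[1, j]]) / sqrt(mse / n)
    p <- unname(ptukey(q, k, dfe, lower.tail = FALSE))
    cmp <- paste(names(g)[combs[2, j]], names(g)[combs[1, j]], sep = "-")
    expect_equal(r$tukey$p_adj[r$tukey$comparison == cmp], p, tolerance = 1e-10)
  }
})

test_that("RM ANOVA matches stats::aov on balanced and unbalanced designs", {
  d <- sim_rm_table(seed = 7)
  fit <- rm_anova_two_way(d)
  a <- summary(aov(value ~ group * level + Error(factor(animal_id)), data = d))
  between <- a[["Error: factor(animal_id)"]][[1]]
  within <- a[["Error: Within"]][[1]]
  expect_equal(fit$effects$F[1], between["group", "F value"], tolerance = 1e-10)
  expect_equal(fit$effects$F[2], within["level", "F value"], tolerance = 1e-10)
  expect_equal(fit$effects$F[3], within["group:level", "F value"],
               tolerance = 1e-10)
  # unbalanced groups (drop 3 animals from one group)
  du <- d[!(d$animal_id %in% 1:3), ]
  fitu <- rm_anova_two_way(du)
  au <- summary(aov(value ~ group * level + Error(factor(animal_id)), data = du))
  expect_equal(fitu$effects$F[1],
               au[["Error: factor(animal_id)"]][[1]]["group", "F value"],
               tolerance = 1e-10)
  expect_equal(fitu$effects$F[2],
               au[["Error: Within"]][[1]]["level", "F value"], tolerance = 1e-10)
})

test_that("RM ANOVA between-group F matches a linear mixed-model fit", {
  skip_if_not_installed("lmerTest")
  d <- sim_rm_table(seed = 7) # 2 groups x 12 animals x 4 levels
  fit <- rm_anova_two_way(d)
  lf <- lmerTest::lmer(value ~ group * level + (1 | animal_id), data = d)
  lt <- anova(lf)
  expect_equal(fit$effects$F[1], lt["group", "F value"], tolerance = 1e-6)
  expect_equal(fit$effects$df2[1], lt["group", "DenDF"], tolerance = 1e-6)
})

test_that("sphericity correction behaves as Greenhouse-Geisser epsilon", {
  d2 <- sim_rm_table(seed = 8, k = 2)
  fit2 <- rm_anova_two_way(d2)
  expect_equal(fit2$epsilon_gg, 1) # 2 within levels: epsilon is exactly 1
  expect_equal(fit2$effects$df1[2], 1)
  for (s in 1:5) {
    d <- sim_rm_table(seed = 100 + s, k = 5)
    e <- rm_anova_two_way(d)$epsilon_gg
    expect_gte(e, 1 / 4)
    expect_lte(e, 1)
  }
})

test_that("zero group effect gives F = 0 and incomplete designs error", {
  d <- sim_rm_table(seed = 9)
  # mirror the groups so group means are identical at every level
  d2 <- d
  d2$animal_id <- d$animal_id + max(d$animal_id)
  d2$group <- ifelse(d$group == "TBI", "sham", "TBI")
  both <- rbind(d, d2)
  fit <- rm_anova_two_way(both)
  expect_equal(fit$effects$F[1], 0, tolerance = 1e-12)
  expect_error(rm_anova_two_way(d[-1, ]), "incomplete design")
})

test_that("Sidak and Holm adjustments match their definitions", {
  expect_equal(sidak_adjust(0, m = 5), 0)
  expect_equal(sidak_adjust(1, m = 5), 1)
  expect_equal(sidak_adjust(0.05, m = 2), 1 - 0.95^2) # 0.0975
  expect_error(sidak_adjust(1.2), "\\[0, 1\\]")
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.3), 0.3)
  set.seed(63)
  p <- runif(10)
  h <- holm_adjust(p)
  expect_true(all(h >= p))
  expect_true(all(diff(h[order(p)]) >= 0))
  s <- sidak_adjust(p)
  expect_true(all(s >= p & s <= 1))
})

test_that("ROUT flags a gross outlier and nothing else", {
  r <- rout_outliers(c(1, 2, 3, 2, 1, 100), Q = 1)
  expect_identical(r$outliers, 6L)
  expect_equal(r$cleaned, c(1, 2, 3, 2, 1))
  expect_lt(abs(r$center - 1.8), 0.5) # robust fit ignores the outlier
})

test_that("ROUT never flags constant data or residuals within one RSDR", {
  r <- rout_outliers(rep(3, 6))
  expect_length(r$outliers, 0)
  set.seed(64)
  for (i in 1:20) {
    x <- rnorm(8)
    r <- rout_outliers(x, Q = 1)
    if (r$rsdr > 0 && max(abs(x - r$center)) <= r$rsdr)
      expect_length(r$outliers, 0)
  }
  expect_error(rout_outliers(c(1, 2)), "at least 3")
  expect_error(rout_outliers(1:5, Q = 0), "percentage")
})
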