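test_that("apoptotic index follows the counts formula under both poolings", {
  one <- apoptotic_index(data.frame(apoptotic = 30, total = 100))
  expect_identical(one$index, 30)

  zero <- apoptotic_index(data.frame(apoptotic = c(0, 0), total = c(50, 70)))
  expect_identical(zero$index, 0)

  # equal totals: poolings agree
  eq <- data.frame(apoptotic = c(10, 30), total = c(100, 100))
  expect_equal(apoptotic_index(eq, "pooled_counts")$index, 20)
  expect_equal(apoptotic_index(eq, "mean_of_fields")$index, 20)

  # unequal totals: poolings diverge, each matching its own arithmetic
  uneq <- data.frame(apoptotic = c(10, 30), total = c(100, 50))
  expect_equal(apoptotic_index(uneq, "pooled_counts")$index, 40 / 150 * 100)
  expect_equal(apoptotic_index(uneq, "mean_of_fields")$index, (10 + 60) / 2)

  expect_error(apoptotic_index(data.frame(apoptotic = 5, total = 2)),
               "apoptotic <= total")
  expect_error(apoptotic_index(data.frame(apoptotic = 0, total = 0)),
               "zero total")

  # bounded and monotone in the apoptotic count
  idx <- vapply(0:50, function(a) {
    apoptotic_index(data.frame(apoptotic = a, total = 50))$index
  }, numeric(1))
  expect_true(all(idx >= 0 & idx <= 100))
  expect_true(all(diff(idx) > 0))
})

test_that("body-weight percent change matches the day-21/day-1 formula", {
  expect_identical(body_weight_percent(250, 295), 18)
  expect_identical(body_weight_percent(300, 300), 0)
  expect_equal(body_weight_percent(300, 292), -8 / 3, tolerance = 1e-12)
  expect_equal(body_weight_percent(c(250, 300), c(295, 292)),
               c(18, -8 / 3), tolerance = 1e-12)
  expect_error(body_weight_percent(0, 100), "> 0")
  expect_error(body_weight_percent(NA, 100), "required")
})

test_that("simulated TUNEL fields respect the phantom's apoptosis labels", {
  cfg <- small_config(n_neurons = 3000, glia = 0)
  cfg$apoptosis_prob[["control"]] <- 0
  st <- section_phantom(generate_phantom(cfg, "control"), seed = 3)
  f0 <- simulate_tunel_fields(st, n_fields = 10, seed = 4)
  expect_identical(nrow(f0), 10L)
  expect_true(all(f0$apoptotic == 0))
  expect_true(all(f0$total >= f0$apoptotic))

  cfg$apoptosis_prob[["control"]] <- 0.3
  st2 <- section_phantom(generate_phantom(cfg, "control"), seed = 3)
  f3 <- simulate_tunel_fields(st2, n_fields = 10, seed = 4)
  ai <- apoptotic_index(f3)
  expect_equal(ai$index, 30, tolerance = 0.25)
})

test_that("the decision tree picks branches from normality and variance checks", {
  set.seed(42)
  norm <- data.frame(g = rep(c("a", "b", "c"), each = 8),
                     y = rnorm(24, mean = 10))
  res <- compare_groups(norm, y, g)
  expect_identical(res$branch, "anova")
  expect_true(res$normality_passed)
  expect_identical(nrow(res$posthoc), 3L)

  # a constant group is degenerate -> nonparametric branch
  degen <- data.frame(g = rep(c("a", "b"), each = 5),
                      y = c(rep(1, 5), rnorm(5)))
  res2 <- compare_groups(degen, y, g)
  expect_identical(res2$branch, "kruskal")
  expect_true(any(res2$normality$degenerate))

  # identical values everywhere: no difference declared
  flat <- data.frame(g = rep(c("a", "b", "c"), each = 4), y = rep(5, 12))
  res3 <- compare_groups(flat, y, g)
  expect_identical(res3$p_value, 1)
  expect_false(res3$significant)
})

test_that("the decision tree is a pure function of its inputs", {
  df <- data.frame(g = rep(c("a", "b", "c"), each = 6),
                   y = c(1.2, 0.8, 1.1, 0.9, 1.0, 1.3,
                         2.1, 1.9, 2.4, 2.0, 1.8, 2.2,
                         1.5, 1.4, 1.7, 1.6, 1.5, 1.8))
  r1 <- compare_groups(df, y, g)
  r2 <- compare_groups(df, y, g)
  expect_identical(glance(r1), glance(r2))
  expect_identical(r1$posthoc, r2$posthoc)
})

test_that("Dunn's post hoc matches an independent rank computation", {
  df <- data.frame(g = rep(c("a", "b", "c"), each = 4),
                   y = c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8))
  res <- compare_groups(df, y, g, test = "kruskal")
  expect_identical(res$branch, "kruskal")
  # independent evaluation of the z statistic for the (a, b) pair
  r <- rank(df$y)
  N <- 12
  ties <- table(r)
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  z_ab <- (mean(r[df$g == "a"]) - mean(r[df$g == "b"])) / sqrt(s2 * (1 / 4 + 1 / 4))
  row_ab <- res$posthoc[res$posthoc$group1 == "a" & res$posthoc$group2 == "b", ]
  expect_equal(row_ab$statistic, z_ab, tolerance = 1e-12)
  expect_equal(row_ab$p_value, 2 * pnorm(-abs(z_ab)), tolerance = 1e-12)
})

test_that("pairwise design runs two-tailed Mann-Whitney on all pairs", {
  df <- data.frame(g = rep(c("a", "b", "c"), each = 6),
                   y = c(1:6, 4:9, 7:12))
  res <- compare_groups(df, y, g, design = "pairwise")
  expect_identical(res$branch, "mann_whitney")
  expect_identical(nrow(res$posthoc), 3L)
  # identical samples give p ~= 1
  same <- data.frame(g = rep(c("a", "b"), each = 4), y = rep(c(1, 2, 3, 4), 2))
  expect_gte(compare_groups(same, y, g, design = "pairwise")$p_value, 0.9)
})

test_that("the two-way design reports the group main effect with Tukey post hoc", {
  set.seed(99)
  df <- expand.grid(g = c("ctrl", "csd"), day = c(1, 7, 14, 21),
                    animal = 1:6)
  df$y <- 250 + 2 * df$day + ifelse(df$g == "csd", -15, 0) + rnorm(nrow(df), 0, 5)
  res <- compare_groups(df, y, g, design = "two_way", block = day)
  expect_identical(res$test, "two-way ANOVA")
  expect_lt(res$p_value, 0.05)
  expect_identical(nrow(res$posthoc), 1L)
})

test_that("forced branches keep their nominal size under the null", {
  # quick 300-replicate sanity check; the full calibration lives in the
  # acceptance suite
  set.seed(2024)
  rej <- replicate(300, {
    df <- data.frame(g = rep(c("a", "b", "c"), each = 6), y = rnorm(18))
    compare_groups(df, y, g, test = "anova")$p_value < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})
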