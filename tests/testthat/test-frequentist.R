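test_that("paired t-test reproduces the closed-form hand example", {
  tbl <- as_cs_table(data.frame(p = c(3, 5, 4), m = c(1, 2, 3)), cs1 = p, cs2 = m)
  fit <- cs_freq_test(tbl)
  # diffs (2, 3, 1): mean 2, sd 1 -> t = 2 / (1/sqrt(3)) = 2 sqrt(3)
  expect_equal(fit$test, "paired")
  expect_equal(fit$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(fit$df, 2)
  expect_equal(fit$cohen_d, 2, tolerance = 1e-12)
  expect_equal(fit$mean_diff, 2)
})

test_that("zero-variance difference scores are a degenerate-input error", {
  same <- as_cs_table(data.frame(p = c(1, 2, 4), m = c(1, 2, 4)), cs1 = p, cs2 = m)
  expect_error(cs_freq_test(same), "zero variance")
  shifted <- as_cs_table(data.frame(p = c(3, 4, 6), m = c(1, 2, 4)), cs1 = p, cs2 = m)
  expect_error(cs_freq_test(shifted), "zero variance")
})

test_that("the acquisition-phase summary statistics are internally consistent", {
  fit <- cs_analyze_summary(t = 2.92, n1 = 40, sensitivity = FALSE)
  expect_equal(round(fit$freq$p, 3), 0.006)
  expect_equal(round(fit$freq$cohen_d, 2), 0.46)
  expect_equal(fit$freq$df, 39)
})

test_that("a two-level group triggers the independent design on difference scores", {
  df <- data.frame(
    p = c(3, 5, 4, 2, 4), m = c(1, 2, 3, 2, 2),
    grp = c("a", "a", "a", "b", "b")
  )
  tbl <- as_cs_table(df, cs1 = p, cs2 = m, group = grp)
  expect_equal(select_cs_test(tbl), "independent")
  fit <- cs_freq_test(tbl)
  ref <- oracle_independent_t(c(2, 3, 1), c(0, 2))
  expect_equal(fit$t, ref$t, tolerance = 1e-12)
  expect_equal(fit$df, ref$df)
  expect_equal(fit$p, ref$p, tolerance = 1e-12)
  expect_equal(fit$cohen_d, ref$d, tolerance = 1e-12)
})

test_that("independent t-test reproduces hand-computed cases", {
  # groups (2, 4) vs (0, 2): mean diff 2, pooled sd sqrt(2), t = sqrt(2)
  ref <- oracle_independent_t(c(2, 4), c(0, 2))
  expect_equal(ref$t, sqrt(2), tolerance = 1e-12)
  df <- data.frame(
    p = c(2, 4, 0, 2), m = c(0, 0, 0, 0), grp = rep(c("g1", "g2"), each = 2)
  )
  fit <- cs_freq_test(as_cs_table(df, cs1 = p, cs2 = m, group = grp))
  expect_equal(fit$t, sqrt(2), tolerance = 1e-12)
  expect_equal(fit$df, 2)
  expect_equal(fit$mean_diff, 2)
  expect_equal(fit$cohen_d, sqrt(2), tolerance = 1e-12)
  # symmetric groups give t = 0 exactly
  sym <- data.frame(
    p = c(1, 2, 3, 1, 2, 3), m = rep(0, 6), grp = rep(c("x", "y"), each = 3)
  )
  fit0 <- cs_freq_test(as_cs_table(sym, cs1 = p, cs2 = m, group = grp))
  expect_equal(fit0$t, 0)
  expect_equal(fit0$cohen_d, 0)
})

test_that("paired results match the direct-formula oracle on random tables", {
  set.seed(501)
  for (i in 1:1000) {
    n <- sample(3:12, 1)
    cs1 <- rnorm(n, mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    cs2 <- rnorm(n, mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    fit <- cs_freq_test(as_cs_table(data.frame(a = cs1, b = cs2), cs1 = a, cs2 = b))
    ref <- oracle_paired_t(cs1, cs2)
    expect_equal(fit$t, ref$t, tolerance = 1e-10)
    expect_equal(fit$df, ref$df)
    expect_equal(fit$p, ref$p, tolerance = 1e-10)
    expect_equal(fit$cohen_d, ref$d, tolerance = 1e-10)
    # t-to-d conversion agrees with the data-level effect size
    expect_equal(cohen_d_from_t(fit$t, n), fit$cohen_d, tolerance = 1e-12)
  }
})

test_that("t statistics convert to the printed effect sizes", {
  expect_equal(round(cohen_d_from_t(2.92, 40), 2), 0.46)
  expect_equal(round(cohen_d_from_t(2.185, 40), 2), 0.35)
  expect_equal(cohen_d_from_t(0, 17), 0)
  expect_equal(cohen_d_from_t(2, 10, 10), 2 * sqrt(0.2), tolerance = 1e-12)
  expect_error(cohen_d_from_t(1, 1), ">= 2")
})

test_that("descriptives use the n-1 denominator and se = sd/sqrt(n)", {
  tbl <- as_cs_table(data.frame(p = c(2, 4, 6), m = c(5, 5, 5)), cs1 = p, cs2 = m)
  desc <- cs_descriptives(tbl)
  cs1_row <- desc[desc$stimulus == "cs1", ]
  expect_equal(cs1_row$mean, 4)
  expect_equal(cs1_row$sd, 2)
  expect_equal(cs1_row$se, 2 / sqrt(3))
  expect_equal(desc[desc$stimulus == "cs2", ]$sd, 0)
  grouped <- simulate_cs(n = 5, groups = 2, seed = 2)
  expect_equal(nrow(cs_descriptives(grouped)), 4) # 2 stimuli x 2 groups
})

test_that("tidy and glance return one-row summaries", {
  tbl <- simulate_cs(n = 15, mu1 = 1, mu2 = 0, seed = 6)
  fit <- cs_freq_test(tbl)
  td <- tidy(fit)
  expect_equal(nrow(td), 1)
  expect_named(
    td,
    c("test", "t", "df", "p", "mean_diff", "conf.low", "conf.high", "cohen_d", "n1", "n2")
  )
  expect_identical(td, glance(fit))
  expect_true(td$conf.low <= td$conf.high)
})
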