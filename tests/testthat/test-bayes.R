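test_that("the Bayes factor matches a dense trapezoid quadrature oracle", {
  cases <- list(
    list(t = 0, n1 = 20, n2 = NULL, r = 0.707),
    list(t = 2.92, n1 = 40, n2 = NULL, r = 0.707),
    list(t = -1.5, n1 = 12, n2 = NULL, r = 1),
    list(t = 1.8, n1 = 25, n2 = 27, r = 0.707)
  )
  for (cs in cases) {
    fit <- bf_ttest(cs$t, n1 = cs$n1, n2 = cs$n2, scale = cs$r)
    ref <- oracle_bf10_trapezoid(cs$t, n1 = cs$n1, n2 = cs$n2, r = cs$r)
    expect_equal(fit$bf10, ref, tolerance = 1e-6)
  }
  # no-effect data always favour H0 under the symmetric prior
  expect_lt(bf_ttest(0, n1 = 20)$bf10, 1)
})

test_that("delta-integral and g-mixture formulations agree", {
  for (t in c(-3, 0, 1.5, 4)) {
    for (n in c(5, 40)) {
      for (r in c(0.5, 1.414)) {
        a <- condlab:::jzs_bf10_delta(t, df = n - 1, eff_n = n, r = r)$bf10
        b <- condlab:::jzs_bf10_gmix(t, df = n - 1, eff_n = n, r = r)$bf10
        expect_equal(a, b, tolerance = 1e-6)
      }
    }
  }
})

test_that("reciprocity, symmetry and quadrature error bounds hold", {
  for (t in c(0.3, 2.185, 3.7)) {
    fit <- bf_ttest(t, n1 = 40)
    neg <- bf_ttest(-t, n1 = 40)
    expect_identical(fit$bf01, 1 / fit$bf10) # reciprocal, not re-integrated
    expect_equal(fit$bf10, neg$bf10, tolerance = 1e-9) # symmetric prior
    expect_lt(fit$quad_error, 1e-6)
    expect_lt(fit$cross_rel_diff, 1e-6)
  }
})

test_that("evidence for H1 grows strictly with |t| at fixed n and scale", {
  ts <- seq(0, 4, by = 0.5)
  bfs <- vapply(ts, function(t) bf_ttest(t, n1 = 40)$bf10, numeric(1))
  expect_true(all(diff(bfs) > 0))
})

test_that("the Bayes factor collapses to 1 as the prior concentrates on H0", {
  expect_equal(bf_ttest(2.92, n1 = 40, scale = 1e-6)$bf10, 1, tolerance = 1e-4)
  expect_equal(bf_ttest(-1.2, n1 = 15, scale = 1e-6)$bf10, 1, tolerance = 1e-4)
})

test_that("two-sample designs use the pooled df and effective sample size", {
  fit <- bf_ttest(2.1, n1 = 30, n2 = 20)
  expect_equal(fit$design, "independent")
  expect_equal(fit$df, 48)
  expect_equal(fit$effective_n, 30 * 20 / 50)
})

test_that("prior odds scale the posterior odds multiplicatively", {
  expect_equal(posterior_odds(1, 6.57), 6.57)
  expect_equal(posterior_odds(2, 0.5), 1)
  expect_equal(posterior_odds(1, 1), 1)
  fit <- bf_ttest(2.92, n1 = 40, prior_odds = 3)
  expect_equal(fit$posterior_odds, 3 * fit$bf10)
})

test_that("bf from data auto-selects the design and matches bf from t", {
  tbl <- simulate_cs(n = 30, mu1 = 5, mu2 = 4, sigma = 2, rho = 0.5, seed = 13)
  freq <- cs_freq_test(tbl)
  bayes <- cs_bayes_test(tbl)
  expect_equal(bayes$design, "paired")
  expect_identical(bayes$bf10, bf_ttest(freq$t, n1 = 30)$bf10)

  grp <- simulate_cs(n = 15, mu1 = 5, mu2 = 4, groups = 2, seed = 14)
  bayes2 <- cs_bayes_test(grp)
  expect_equal(bayes2$design, "independent")
  expect_equal(bayes2$df, 28)
})

test_that("degenerate data propagate the zero-variance error", {
  same <- as_cs_table(
    data.frame(p = c(3, 4, 6), m = c(1, 2, 4)),
    cs1 = p, cs2 = m
  )
  expect_error(cs_bayes_test(same), "zero variance")
})

test_that("large samples with a real effect give decisive evidence", {
  tbl <- simulate_cs(
    n = 500, mu1 = 0.8, mu2 = 0, sigma = 1, rho = 0.5,
    seed = 99
  )
  expect_gt(cs_bayes_test(tbl)$bf10, 100)
})

test_that("large null samples mostly favour H0 by more than 3", {
  bf01s <- vapply(
    null_batch(n = 500, sigma = 1, rho = 0.5, reps = 200, seed = 700),
    function(tbl) cs_bayes_test(tbl)$bf01, numeric(1)
  )
  expect_gt(mean(bf01s > 3), 0.5)
  expect_gt(stats::median(bf01s), 3)
})

test_that("evidence accumulates with sample size at a fixed true effect", {
  med_bf <- vapply(c(20, 80, 320), function(n) {
    bfs <- vapply(1:40, function(i) {
      tbl <- simulate_cs(
        n = n, mu1 = 0.5, mu2 = 0, sigma = 1, rho = 0.5,
        seed = 4000 + 500 * i
      )
      cs_bayes_test(tbl)$bf10
    }, numeric(1))
    stats::median(bfs)
  }, numeric(1))
  expect_true(all(diff(med_bf) > 0))
})

test_that("invalid Bayes inputs are rejected", {
  expect_error(bf_ttest(Inf, 40), "finite")
  expect_error(bf_ttest(2, 40, scale = 0), "positive")
  expect_error(bf_ttest(2, 40, scale = -1), "positive")
  expect_error(bf_ttest(2, 40, prior_odds = 0), "positive")
  expect_error(bf_ttest(2, 1), ">= 2")
})
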