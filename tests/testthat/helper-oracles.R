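# Independent reference implementations used to cross-check the package.
# These deliberately avoid the code paths they verify: the t-test oracle
# works from the textbook formulas (not stats::t.test), and the Bayes
# factor oracle is a dense trapezoid rule on a fixed delta grid (not the
# package's adaptive quadrature on the compactified domain).

oracle_paired_t <- function(cs1, cs2) {
  d <- cs1 - cs2
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1), d = m / s)
}

oracle_independent_t <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  m1 <- sum(x) / n1
  m2 <- sum(y) / n2
  sp2 <- (sum((x - m1)^2) + sum((y - m2)^2)) / (n1 + n2 - 2)
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(
    t = t, df = n1 + n2 - 2, p = 2 * stats::pt(-abs(t), n1 + n2 - 2),
    d = (m1 - m2) / sqrt(sp2)
  )
}

# Dense brute-force trapezoid quadrature for the JZS Bayes factor.
# Truncation at |delta| = 30 is harmless for the moderate (t, n) used in
# tests: the noncentral-t density at the observed t is numerically zero
# once the noncentrality exceeds ~|t| + 15.
oracle_bf10_trapezoid <- function(t, n1, n2 = NULL, r = 0.707,
                                  half_width = 30, n_grid = 240001L) {
  if (is.null(n2)) {
    df <- n1 - 1
    eff_n <- n1
  } else {
    df <- n1 + n2 - 2
    eff_n <- n1 * n2 / (n1 + n2)
  }
  delta <- seq(-half_width, half_width, length.out = n_grid)
  f <- suppressWarnings(stats::dt(t, df, ncp = delta * sqrt(eff_n))) *
    stats::dcauchy(delta, 0, r)
  h <- delta[2L] - delta[1L]
  num <- h * (sum(f) - (f[1L] + f[n_grid]) / 2)
  num / stats::dt(t, df)
}

# Small CSV written through base R so reader tests do not depend on the
# package's own writer.
write_fixture_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}
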