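#' Descriptive statistics per stimulus (and per group)
#'
#' Mean, standard deviation (n - 1 denominator), standard error and n
#' for the CS1 and CS2 responses, split by group when a group column is
#' present.
#'
#' @param table A [cs_table][as_cs_table] (or any data frame with
#'   numeric `cs1`/`cs2` columns and an optional `group` column).
#' @return A tibble with one row per stimulus (per group when grouped)
#'   and columns `stimulus`, (`group`,) `n`, `mean`, `sd`, `se`.
#' @examples
#' tbl <- simulate_cs(n = 20, mu1 = 5, mu2 = 3, sigma = 2, rho = 0.5, seed = 1)
#' cs_descriptives(tbl)
#' @export
cs_descriptives <- function(table) {
  long <- tidyr::pivot_longer(table,
    cols = c("cs1", "cs2"),
    names_to = "stimulus", values_to = "response"
  )
  keys <- if (has_group(table)) c("stimulus", "group") else "stimulus"
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$response),
      sd = sd(.data$response),
      se = sd(.data$response) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}

#' Automatic test selection for a conditioning table
#'
#' Mirrors the automatic design choice of the analysis engine: a paired
#' samples t-test on the CS1 - CS2 difference scores when no group
#' column is present, and an independent samples t-test comparing the
#' two groups' difference scores when a two-level group column is
#' present. The user never specifies the test.
#'
#' @inheritParams cs_descriptives
#' @return `"paired"` or `"independent"`.
#' @export
select_cs_test <- function(table) {
  if (has_group(table)) "independent" else "paired"
}

#' Frequentist t-test for differential conditioning data
#'
#' Runs the automatically selected design ([select_cs_test()]) on the
#' within-subject difference scores d = CS1 - CS2: a paired t-test of
#' the mean difference against zero, or a pooled-variance independent
#' t-test of group 1's differences against group 2's. Two-sided p
#' throughout; the 95% CI uses the central-t quantile at the test's
#' degrees of freedom. Cohen's d is mean(d)/sd(d) for the paired design
#' and the pooled-sd standardized mean difference for the independent
#' design.
#'
#' @inheritParams cs_descriptives
#' @return An object of class `cs_freq`: a list with elements
#'   `test` ("paired"/"independent"), `t`, `df`, `p`, `mean_diff`
#'   (CS1 - CS2, or group1 - group2 of difference scores), `ci95`,
#'   `cohen_d`, and `n` (named sample sizes). Has [tidy()] and
#'   [glance()] methods.
#' @examples
#' tbl <- simulate_cs(n = 40, mu1 = 5, mu2 = 3, sigma = 2, rho = 0.5, seed = 1)
#' cs_freq_test(tbl)
#' @export
cs_freq_test <- function(table) {
  d <- table$cs1 - table$cs2
  if (select_cs_test(table) == "paired") {
    paired_ttest(d)
  } else {
    split_d <- split(d, table$group)
    independent_ttest(split_d[[1L]], split_d[[2L]], names(split_d))
  }
}

paired_ttest <- function(d) {
  n <- length(d)
  if (n < 2L) abort("Paired t-test needs at least 2 difference scores.")
  if (sd(d) == 0) {
    abort(paste(
      "Difference scores have zero variance;",
      "the t statistic is undefined for these data."
    ))
  }
  ht <- stats::t.test(d)
  new_cs_freq(
    test = "paired",
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p = ht$p.value,
    mean_diff = unname(ht$estimate),
    ci95 = as.numeric(ht$conf.int),
    cohen_d = mean(d) / sd(d),
    n = c(n = n)
  )
}

independent_ttest <- function(d1, d2, group_names = c("1", "2")) {
  n1 <- length(d1)
  n2 <- length(d2)
  if (n1 < 2L || n2 < 2L) abort("Each group needs at least 2 difference scores.")
  sp2 <- ((n1 - 1) * stats::var(d1) + (n2 - 1) * stats::var(d2)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    abort(paste(
      "Pooled variance of the difference scores is zero;",
      "the t statistic is undefined for these data."
    ))
  }
  ht <- stats::t.test(d1, d2, var.equal = TRUE)
  out <- new_cs_freq(
    test = "independent",
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p = ht$p.value,
    mean_diff = unname(ht$estimate[1L] - ht$estimate[2L]),
    ci95 = as.numeric(ht$conf.int),
    cohen_d = (mean(d1) - mean(d2)) / sqrt(sp2),
    n = c(n1 = n1, n2 = n2)
  )
  out$groups <- group_names
  out
}

new_cs_freq <- function(test, t, df, p, mean_diff, ci95, cohen_d, n) {
  structure(
    list(
      test = test, t = t, df = df, p = p, mean_diff = mean_diff,
      ci95 = ci95, cohen_d = cohen_d, n = n
    ),
    class = "cs_freq"
  )
}

#' Cohen's d from a t statistic
#'
#' Converts a reported t statistic into a standardized effect size:
#' d = t / sqrt(n) for paired (one-sample) designs and
#' d = t * sqrt(1/n1 + 1/n2) for independent two-sample designs, so a
#' printed summary statistic is enough to recover the effect size.
#'
#' @param t t statistic.
#' @param n1 Sample size (per-design: total n for paired; group 1 n for
#'   independent).
#' @param n2 Group 2 sample size; `NULL` (default) selects the paired
#'   conversion.
#' @return Cohen's d, with the sign of `t`.
#' @examples
#' cohen_d_from_t(2.92, 40)   # ~0.46
#' cohen_d_from_t(2.185, 40)  # ~0.35
#' @export
cohen_d_from_t <- function(t, n1, n2 = NULL) {
  stopifnot(is.numeric(t), length(t) == 1L, is.finite(t))
  check_n(n1, "n1")
  if (is.null(n2)) {
    t / sqrt(n1)
  } else {
    check_n(n2, "n2")
    t * sqrt(1 / n1 + 1 / n2)
  }
}

check_n <- function(n, what) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) ||
    n < 2 || n != round(n)) {
    abort(sprintf("`%s` must be a single integer >= 2.", what))
  }
}

#' @export
print.cs_freq <- function(x, ...) {
  cat(sprintf(
    "%s samples t-test: %s\n",
    if (x$test == "paired") "Paired" else "Independent",
    freq_line(x)
  ))
  cat(sprintf(
    "mean difference = %s, 95%% CI [%s, %s], n = %s\n",
    fmt_num(x$mean_diff), fmt_num(x$ci95[1L]), fmt_num(x$ci95[2L]),
    paste(x$n, collapse = ", ")
  ))
  invisible(x)
}

#' Tidy a frequentist conditioning test
#'
#' @param x A `cs_freq` object from [cs_freq_test()].
#' @param ... Unused.
#' @return A one-row tibble with columns `test`, `t`, `df`, `p`,
#'   `mean_diff`, `conf.low`, `conf.high`, `cohen_d`, `n1`, `n2`.
#' @export
tidy.cs_freq <- function(x, ...) {
  tibble(
    test = x$test, t = x$t, df = x$df, p = x$p,
    mean_diff = x$mean_diff,
    conf.low = x$ci95[1L], conf.high = x$ci95[2L],
    cohen_d = x$cohen_d,
    n1 = unname(x$n[1L]),
    n2 = if (length(x$n) > 1L) unname(x$n[2L]) else NA_integer_
  )
}

#' @rdname tidy.cs_freq
#' @export
glance.cs_freq <- tidy.cs_freq
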