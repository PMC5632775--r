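#' Full conditioning analysis pipeline
#'
#' One-call analysis of a differential-conditioning dataset:
#' descriptives, the automatically selected frequentist t-test
#' ([cs_freq_test()]), the default JZS Bayes factor
#' ([cs_bayes_test()]), and — by default — the prior-scale sensitivity
#' curve ([bf_sensitivity()]). The result bundles everything needed by
#' [render_report()], [write_results()] and the plot functions.
#'
#' @param data A data frame with one row per participant, or an
#'   existing [cs_table][as_cs_table].
#' @param cs1,cs2,group,subject <[`tidy-select`][dplyr::dplyr_tidy_select]>
#'   Column selections forwarded to [as_cs_table()]; default to columns
#'   named `cs1`/`cs2` (no group).
#' @inheritParams bf_ttest
#' @param sensitivity Compute the robustness curve? Default `TRUE`.
#' @param scales Grid of Cauchy scales for the curve; default
#'   [default_scales()].
#' @param alpha Significance level used by report interpretation.
#' @return An object of class `cs_analysis`: list with `table`,
#'   `descriptives`, `freq` (`cs_freq`), `bayes` (`cs_bf`),
#'   `sensitivity` (`cs_sensitivity` or `NULL`) and `alpha`. Has
#'   [tidy()], [glance()] and `print()` methods.
#' @examples
#' tbl <- simulate_cs(n = 40, mu1 = 5, mu2 = 4, sigma = 2, rho = 0.5, seed = 11)
#' fit <- cs_analyze(tbl, scales = c(0.5, 0.707, 1, 1.414))
#' glance(fit)
#' cat(render_report(fit, interpret = TRUE))
#' @export
cs_analyze <- function(data, cs1 = NULL, cs2 = NULL, group = NULL,
                       subject = NULL, scale = 0.707, prior_odds = 1,
                       sensitivity = TRUE, scales = default_scales(),
                       alpha = 0.05) {
  table <- if (inherits(data, "cs_table")) {
    data
  } else if (quo_is_null(enquo(cs1))) {
    as_cs_table(data, cs1 = "cs1", cs2 = "cs2")
  } else {
    as_cs_table(data,
      cs1 = {{ cs1 }}, cs2 = {{ cs2 }},
      group = {{ group }}, subject = {{ subject }}
    )
  }
  freq <- cs_freq_test(table)
  bayes <- cs_bayes_test(table, scale = scale, prior_odds = prior_odds)
  curve <- NULL
  if (isTRUE(sensitivity)) {
    n <- unname(freq$n)
    curve <- bf_sensitivity(
      freq$t,
      n1 = n[1L], n2 = if (length(n) > 1L) n[2L] else NULL,
      scales = scales
    )
  }
  new_cs_analysis(
    table = table, descriptives = cs_descriptives(table),
    freq = freq, bayes = bayes, sensitivity = curve, alpha = alpha
  )
}

#' Conditioning analysis from printed summary statistics
#'
#' Rebuilds the full analysis bundle from a reported t statistic and
#' sample size(s) alone — the route for re-evaluating published results
#' when the raw data are unavailable. The p-value and Cohen's d are
#' recovered from t and the degrees of freedom; descriptives and the
#' mean-difference CI are unavailable and omitted from the report.
#'
#' @inheritParams bf_ttest
#' @inheritParams cs_analyze
#' @return A `cs_analysis` bundle (without `table`/`descriptives`).
#' @examples
#' fit <- cs_analyze_summary(t = 2.185, n1 = 40, scales = c(0.707, 1, 1.414))
#' cat(render_report(fit, interpret = TRUE))
#' @export
cs_analyze_summary <- function(t, n1, n2 = NULL, scale = 0.707,
                               prior_odds = 1, sensitivity = TRUE,
                               scales = default_scales(), alpha = 0.05) {
  bayes <- bf_ttest(t, n1 = n1, n2 = n2, scale = scale, prior_odds = prior_odds)
  freq <- new_cs_freq(
    test = bayes$design, t = t, df = bayes$df,
    p = 2 * pt(-abs(t), df = bayes$df),
    mean_diff = NA_real_, ci95 = c(NA_real_, NA_real_),
    cohen_d = cohen_d_from_t(t, n1, n2),
    n = bayes$n
  )
  curve <- if (isTRUE(sensitivity)) bf_sensitivity(t, n1, n2, scales = scales)
  new_cs_analysis(
    table = NULL, descriptives = NULL, freq = freq, bayes = bayes,
    sensitivity = curve, alpha = alpha
  )
}

new_cs_analysis <- function(table, descriptives, freq, bayes, sensitivity,
                            alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  structure(
    list(
      table = table, descriptives = descriptives, freq = freq,
      bayes = bayes, sensitivity = sensitivity, alpha = alpha
    ),
    class = "cs_analysis"
  )
}

#' @export
print.cs_analysis <- function(x, ...) {
  cat(render_report(x), sep = "")
  invisible(x)
}

#' Tidy a conditioning analysis bundle
#'
#' `tidy()` stacks every computed quantity as one row per
#' (section, quantity) pair — the same tidy layout [write_results()]
#' uses for CSV output. `glance()` returns the headline one-row
#' summary.
#'
#' @param x A `cs_analysis` bundle.
#' @param ... Unused.
#' @return A tibble: `tidy()` with columns `section`, `quantity`,
#'   `value`; `glance()` one row with the test name, t, df, p, Cohen's
#'   d, scale, BF10, BF01 and posterior odds.
#' @export
tidy.cs_analysis <- function(x, ...) {
  rows <- list()
  if (!is.null(x$descriptives)) {
    d <- x$descriptives
    key <- if ("group" %in% names(d)) {
      paste0(d$stimulus, ".", d$group)
    } else {
      d$stimulus
    }
    rows$descriptives <- tibble(
      section = "descriptives",
      quantity = c(
        paste0(key, ".n"), paste0(key, ".mean"),
        paste0(key, ".sd"), paste0(key, ".se")
      ),
      value = c(as.numeric(d$n), d$mean, d$sd, d$se)
    )
  }
  f <- x$freq
  rows$freq <- tibble(
    section = "frequentist",
    quantity = c(
      "t", "df", "p", "mean_diff", "ci95_lower", "ci95_upper", "cohen_d",
      paste0("n", if (length(f$n) > 1L) seq_along(f$n) else "")
    ),
    value = c(
      f$t, f$df, f$p, f$mean_diff, f$ci95[1L], f$ci95[2L], f$cohen_d,
      as.numeric(f$n)
    )
  )
  b <- x$bayes
  rows$bayes <- tibble(
    section = "bayesian",
    quantity = c(
      "scale", "bf10", "bf01", "prior_odds", "posterior_odds",
      "effective_n", "df", "quad_error"
    ),
    value = c(
      b$scale, b$bf10, b$bf01, b$prior_odds, b$posterior_odds,
      b$effective_n, b$df, b$quad_error
    )
  )
  if (!is.null(x$sensitivity)) {
    s <- x$sensitivity
    rows$sens <- tibble(
      section = "sensitivity",
      quantity = c(
        paste0("bf10.r=", s$scale), paste0("bf01.r=", s$scale),
        "direction_stable"
      ),
      value = c(s$bf10, s$bf01, as.numeric(attr(s, "direction_stable")))
    )
  }
  dplyr::bind_rows(rows)
}

#' @rdname tidy.cs_analysis
#' @export
glance.cs_analysis <- function(x, ...) {
  tibble(
    test = x$freq$test, t = x$freq$t, df = x$freq$df, p = x$freq$p,
    cohen_d = x$freq$cohen_d, scale = x$bayes$scale,
    bf10 = x$bayes$bf10, bf01 = x$bayes$bf01,
    posterior_odds = x$bayes$posterior_odds
  )
}

#' Write analysis results to JSON or CSV
#'
#' Serialises a `cs_analysis` bundle at full numeric precision (display
#' rounding is the report's job, not the file's). JSON preserves the
#' nested structure (descriptives, frequentist, bayesian, sensitivity);
#' CSV is the tidy one-row-per-quantity layout of [tidy.cs_analysis()].
#' Both round-trip through [read_results()] with numerically identical
#' values.
#'
#' @param x A `cs_analysis` bundle.
#' @param path Output file path.
#' @param format `"json"` or `"csv"`; default inferred from the file
#'   extension (falling back to JSON).
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = NULL) {
  stopifnot(inherits(x, "cs_analysis"))
  format <- format %||%
    (if (tolower(tools::file_ext(path)) == "csv") "csv" else "json")
  format <- match.arg(format, c("json", "csv"))
  if (format == "csv") {
    readr::write_csv(tidy(x), path)
  } else {
    # digits = I(17): enough significant digits for an exact
    # binary64 round-trip (jsonlite's NA caps at 15)
    jsonlite::write_json(
      results_list(x), path,
      auto_unbox = TRUE, digits = I(17), dataframe = "columns", na = "null"
    )
  }
  invisible(path)
}

results_list <- function(x) {
  f <- x$freq
  b <- x$bayes
  out <- list(
    descriptives = x$descriptives,
    frequentist = list(
      test = f$test, t = f$t, df = f$df, p = f$p, mean_diff = f$mean_diff,
      ci95 = f$ci95, cohen_d = f$cohen_d, n = as.numeric(f$n)
    ),
    bayesian = list(
      design = b$design, scale = b$scale, bf10 = b$bf10, bf01 = b$bf01,
      prior_odds = b$prior_odds, posterior_odds = b$posterior_odds,
      effective_n = b$effective_n, df = b$df, quad_error = b$quad_error
    ),
    alpha = x$alpha
  )
  if (!is.null(x$sensitivity)) {
    s <- x$sensitivity
    out$sensitivity <- list(
      scale = s$scale, bf10 = s$bf10, bf01 = s$bf01,
      direction_stable = attr(s, "direction_stable")
    )
  }
  out
}

#' Read back a results file
#'
#' Inverse of [write_results()]: JSON files return the nested results
#' list; CSV files return the tidy (section, quantity, value) tibble.
#'
#' @param path Path written by [write_results()].
#' @param format `"json"` or `"csv"`; default inferred from extension.
#' @return A nested list (JSON) or tibble (CSV).
#' @export
read_results <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  format <- format %||%
    (if (tolower(tools::file_ext(path)) == "csv") "csv" else "json")
  format <- match.arg(format, c("json", "csv"))
  if (format == "csv") {
    # base read.csv: strtod parsing recovers readr's shortest-round-trip
    # doubles exactly
    as_tibble(utils::read.csv(path, colClasses = c(
      section = "character", quantity = "character", value = "numeric"
    )))
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
}
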