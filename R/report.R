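# Locale-independent display formatting. All rounding lives here; every
# stored number is full precision. sprintf() in R always uses "." as the
# decimal separator, so reports are byte-stable across locales.
fmt_num <- function(x, digits = 2) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), x))
}

# APA-style p: 3 decimals, no leading zero, floored at "< .001".
fmt_p <- function(p) {
  if (is.na(p)) {
    return("= NA")
  }
  if (p < 0.001) {
    return("< .001")
  }
  paste("=", sub("^0", "", sprintf("%.3f", p)))
}

freq_line <- function(freq) {
  sprintf(
    "t(%g) = %s, p %s, Cohen's d = %s",
    freq$df, fmt_num(freq$t), fmt_p(freq$p), fmt_num(freq$cohen_d)
  )
}

#' Evidence category of a Bayes factor
#'
#' Maps a Bayes factor onto the classical evidence categories
#' (Jeffreys' scale): whichever of BF10 and BF01 = 1/BF10 exceeds 1 is
#' graded as anecdotal (1 < BF <= 3, "not worth more than a bare
#' mention"), substantial (3 < BF <= 10), strong (10 < BF <= 30), very
#' strong (30 < BF <= 100) or decisive (BF > 100); a Bayes factor of
#' exactly 1 supports neither hypothesis. Boundaries are half-open as
#' listed. An alternative vocabulary (e.g. "moderate" for the 3-10
#' band) is in circulation; this package uses the labels above.
#'
#' @param bf10 Vector of Bayes factors for H1 over H0 (> 0).
#' @return A tibble with one row per input: `bf10`, `favours`
#'   (`"H1"`, `"H0"` or `"neither"`), `bf` (the reported direction's
#'   Bayes factor, >= 1), `label`, and `description` (a ready-made
#'   sentence fragment).
#' @examples
#' bf_category(c(1.43, 6.57, 0.02))
#' @export
bf_category <- function(bf10) {
  if (!is.numeric(bf10) || any(!is.finite(bf10)) || any(bf10 <= 0)) {
    abort("`bf10` must be positive and finite.")
  }
  favours <- ifelse(bf10 > 1, "H1", ifelse(bf10 < 1, "H0", "neither"))
  bf <- pmax(bf10, 1 / bf10)
  label <- dplyr::case_when(
    bf == 1 ~ "equal support",
    bf <= 3 ~ "anecdotal",
    bf <= 10 ~ "substantial",
    bf <= 30 ~ "strong",
    bf <= 100 ~ "very strong",
    TRUE ~ "decisive"
  )
  description <- dplyr::case_when(
    label == "equal support" ~ "equal support for both hypotheses",
    label == "anecdotal" ~ paste0(
      "anecdotal evidence for ", favours,
      " (not worth more than a bare mention)"
    ),
    TRUE ~ paste0(label, " evidence for ", favours)
  )
  tibble(
    bf10 = bf10, favours = favours, bf = bf,
    label = label, description = description
  )
}

#' Significance label for a p-value
#'
#' `"significant"` iff p < alpha (strict inequality: p equal to alpha
#' is non-significant).
#'
#' @param p p-value in \[0, 1\].
#' @param alpha Significance level in (0, 1); default .05.
#' @return `"significant"` or `"non-significant"` (vectorised over `p`).
#' @examples
#' significance_label(0.006)
#' significance_label(0.035, alpha = 0.016) # Bonferroni-corrected level
#' @export
significance_label <- function(p, alpha = 0.05) {
  stopifnot(
    is.numeric(p), all(p >= 0 & p <= 1),
    is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1
  )
  ifelse(p < alpha, "significant", "non-significant")
}

#' Render the automatic results report
#'
#' Builds the Markdown results text for a [cs_analyze()] (or
#' [cs_analyze_summary()]) bundle: descriptive statistics, the
#' frequentist t/p/d line with the 95% CI, the Bayesian panel (prior
#' scale, BF10, BF01, prior and posterior odds), a robustness panel
#' when a sensitivity curve is present, and — only when `interpret =
#' TRUE` — interpretation sentences labelling the p-value against
#' `alpha` and the Bayes factor against the evidence categories of
#' [bf_category()]. Output is deterministic: rendering the same bundle
#' twice yields byte-identical text, with "." as decimal separator
#' regardless of locale. Display precision: t, d and BFs to 2 decimals,
#' p to 3 with a "< .001" floor; unrounded values are available via
#' [write_results()].
#'
#' @param x A `cs_analysis` bundle.
#' @param interpret Append the interpretation section? Default `FALSE`.
#' @param alpha Significance level used by the interpretation; defaults
#'   to the bundle's `alpha`.
#' @return A single character string of Markdown.
#' @export
render_report <- function(x, interpret = FALSE, alpha = NULL) {
  stopifnot(inherits(x, "cs_analysis"))
  if (is.null(x$freq) || is.null(x$bayes)) {
    abort("Bundle is incomplete: frequentist and Bayesian results are required.")
  }
  alpha <- alpha %||% x$alpha
  out <- c("# Conditioning analysis report", "")
  if (!is.null(x$descriptives)) {
    out <- c(out, "## Descriptive statistics", "", descriptives_md(x$descriptives), "")
  }
  out <- c(out, "## Frequentist results", "", freq_md(x$freq), "")
  out <- c(out, "## Bayesian results", "", bayes_md(x$bayes), "")
  if (!is.null(x$sensitivity)) {
    out <- c(out, "## Robustness to the prior scale", "", robustness_summary(x$sensitivity), "")
  }
  if (isTRUE(interpret)) {
    out <- c(out, "## Interpretation", "", interpret_md(x, alpha), "")
  }
  paste(out, collapse = "\n")
}

descriptives_md <- function(desc) {
  grouped <- "group" %in% names(desc)
  header <- if (grouped) {
    c(
      "| stimulus | group | n | mean | sd | se |",
      "|---|---|---|---|---|---|"
    )
  } else {
    c("| stimulus | n | mean | sd | se |", "|---|---|---|---|---|")
  }
  rows <- vapply(seq_len(nrow(desc)), function(i) {
    cells <- c(
      toupper(desc$stimulus[i]),
      if (grouped) as.character(desc$group[i]),
      as.character(desc$n[i]),
      fmt_num(desc$mean[i]), fmt_num(desc$sd[i]), fmt_num(desc$se[i])
    )
    paste0("| ", paste(cells, collapse = " | "), " |")
  }, character(1))
  paste(c(header, rows), collapse = "\n")
}

freq_md <- function(freq) {
  name <- if (freq$test == "paired") {
    "Paired samples t-test (CS1 - CS2)"
  } else {
    "Independent samples t-test on the CS1 - CS2 difference scores (group 1 - group 2)"
  }
  lines <- sprintf("%s: %s.", name, freq_line(freq))
  if (!is.na(freq$mean_diff)) {
    lines <- c(lines, sprintf(
      "Mean difference = %s, 95%% CI [%s, %s].",
      fmt_num(freq$mean_diff), fmt_num(freq$ci95[1L]), fmt_num(freq$ci95[2L])
    ))
  }
  paste(lines, collapse = " ")
}

bayes_md <- function(bayes) {
  paste(
    sprintf(
      "Default Bayesian %s samples t-test with a Cauchy prior scale factor of %s:",
      bayes$design, fmt_num(bayes$scale, 3)
    ),
    sprintf("BF10 = %s, BF01 = %s.", fmt_num(bayes$bf10), fmt_num(bayes$bf01)),
    sprintf(
      "Prior odds = %s, posterior odds = %s.",
      fmt_num(bayes$prior_odds), fmt_num(bayes$posterior_odds)
    )
  )
}

interpret_md <- function(x, alpha) {
  cat_row <- bf_category(x$bayes$bf10)
  lines <- c(
    sprintf(
      "The p-value (p %s) is %s at alpha = %s.",
      fmt_p(x$freq$p), significance_label(x$freq$p, alpha),
      sub("0+$", "", sub("^0", "", fmt_num(alpha, 3)))
    ),
    sprintf(
      "BF10 = %s: %s.", fmt_num(x$bayes$bf10), cat_row$description
    ),
    paste(
      "This interpretation is generated from the numerical values alone;",
      "researchers are free to question or ignore it."
    )
  )
  paste(lines, collapse = " ")
}
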