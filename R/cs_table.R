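#' Build a conditioning table from a data frame
#'
#' Standardises per-participant differential-conditioning data into the
#' table every analysis function in condlab consumes: one row per
#' participant with the conditioned response (CR) to the reinforced
#' stimulus (`cs1`), the CR to the unreinforced stimulus (`cs2`), and an
#' optional two-level `group` label. Rows with a missing or non-finite
#' value in any selected column are dropped listwise (so the paired
#' CS1/CS2 scores stay aligned) and the number of dropped rows is
#' reported via a message.
#'
#' @param data A data frame with one row per participant.
#' @param cs1,cs2 <[`tidy-select`][dplyr::dplyr_tidy_select]> Columns
#'   holding the CS1 and CS2 response magnitudes (e.g. mean startle EMG
#'   per stimulus). Must be numeric.
#' @param group <[`tidy-select`][dplyr::dplyr_tidy_select]> Optional
#'   column with exactly two distinct group labels. Group order follows
#'   first appearance in the data, which fixes the sign convention of
#'   group contrasts.
#' @param subject <[`tidy-select`][dplyr::dplyr_tidy_select]> Optional
#'   column of participant identifiers; row numbers are used when absent.
#'
#' @return A tibble of class `cs_table` with columns `subject_id`,
#'   `cs1`, `cs2` and, when selected, `group` (a factor with levels in
#'   first-appearance order). At least 2 complete rows (2 per group when
#'   grouped) are required.
#'
#' @examples
#' df <- data.frame(AcqPemg = c(5.1, 6.3, 4.8), AcqMemg = c(3.2, 4.1, 4.0))
#' as_cs_table(df, cs1 = AcqPemg, cs2 = AcqMemg)
#' @export
as_cs_table <- function(data, cs1, cs2, group = NULL, subject = NULL) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.")
  }
  sel <- dplyr::select(data, cs1 = {{ cs1 }}, cs2 = {{ cs2 }})
  if (!identical(names(sel), c("cs1", "cs2"))) {
    abort("`cs1` and `cs2` must each select exactly one column.")
  }
  grp <- dplyr::select(data, group = {{ group }})
  sub <- dplyr::select(data, subject_id = {{ subject }})
  out <- as_tibble(sel)
  out$subject_id <- if (ncol(sub) == 1L) {
    as.character(sub$subject_id)
  } else {
    as.character(seq_len(nrow(out)))
  }
  if (ncol(grp) == 1L) out$group <- grp$group
  out <- out[, intersect(c("subject_id", "cs1", "cs2", "group"), names(out))]
  validate_cs_table(out)
}

# Listwise deletion + structural checks shared by as_cs_table and the readers.
validate_cs_table <- function(out) {
  for (col in c("cs1", "cs2")) {
    if (!is.numeric(out[[col]])) {
      abort(sprintf("Column selected for `%s` must be numeric.", col))
    }
  }
  ok <- is.finite(out$cs1) & is.finite(out$cs2)
  if ("group" %in% names(out)) ok <- ok & !is.na(out$group)
  n_drop <- sum(!ok)
  if (n_drop > 0L) {
    inform(sprintf(
      "Dropped %d row%s with missing or non-finite values (listwise deletion).",
      n_drop, if (n_drop == 1L) "" else "s"
    ))
    out <- out[ok, , drop = FALSE]
  }
  if (nrow(out) < 2L) {
    abort("At least 2 complete rows are required.")
  }
  if ("group" %in% names(out)) {
    lev <- unique(as.character(out$group))
    if (length(lev) != 2L) {
      abort(sprintf(
        "Group column must have exactly 2 levels after listwise deletion; found %d (%s).",
        length(lev), paste(head(lev, 5L), collapse = ", ")
      ))
    }
    out$group <- factor(as.character(out$group), levels = lev)
    if (any(table(out$group) < 2L)) {
      abort("Each group must contain at least 2 complete rows.")
    }
  }
  class(out) <- c("cs_table", class(as_tibble(out)))
  out
}

#' Read a conditioning table from a delimited file
#'
#' Reads per-participant CS1/CS2 response data from a delimited text
#' file and validates it via [as_cs_table()]. The file extension picks
#' the parser: `.csv` is comma-delimited, `.txt` is any-whitespace
#' delimited, and `.sav` (SPSS) is supported when the haven or foreign
#' package is installed. A header row is required.
#'
#' @param path Path to the data file.
#' @param cs1,cs2 Column names (strings) holding the CS1 and CS2
#'   response magnitudes.
#' @param group Optional column name (string) with two group labels.
#' @param delim Optional single-character delimiter overriding the
#'   extension-based choice.
#'
#' @return A validated [cs_table][as_cs_table] tibble.
#' @seealso [as_cs_table()] for data already in R; [write_results()] for
#'   the machine-readable output side.
#' @export
read_cs_table <- function(path, cs1, cs2, group = NULL, delim = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort(sprintf("File not found: %s", path))
  }
  raw <- read_raw_table(path, delim)
  for (nm in c(cs1, cs2, group)) {
    if (!nm %in% names(raw)) {
      abort(sprintf(
        "Column '%s' not found in %s (available: %s).",
        nm, basename(path), paste(names(raw), collapse = ", ")
      ))
    }
  }
  as_cs_table(raw,
    cs1 = dplyr::all_of(cs1), cs2 = dplyr::all_of(cs2),
    group = dplyr::all_of(group %||% character(0))
  )
}

read_raw_table <- function(path, delim = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (!is.null(delim)) {
    return(readr::read_delim(path, delim = delim, show_col_types = FALSE))
  }
  if (ext == "csv") {
    readr::read_csv(path, show_col_types = FALSE)
  } else if (ext %in% c("txt", "dat", "tsv")) {
    readr::read_table(path, show_col_types = FALSE)
  } else if (ext == "sav") {
    read_sav_table(path)
  } else {
    abort(sprintf("Unsupported file extension '.%s' (use .csv, .txt or .sav).", ext))
  }
}

read_sav_table <- function(path) {
  if (requireNamespace("haven", quietly = TRUE)) {
    as_tibble(haven::read_sav(path))
  } else if (requireNamespace("foreign", quietly = TRUE)) {
    as_tibble(foreign::read.spss(path, to.data.frame = TRUE))
  } else {
    abort("Reading .sav files requires the 'haven' or 'foreign' package.")
  }
}

`%||%` <- function(x, y) if (is.null(x)) y else x

has_group <- function(table) "group" %in% names(table)
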