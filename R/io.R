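# Count-table file I/O and report writing.
#
# Two dialects are accepted, both with file order authoritative (rows are
# never sorted): a two-column `label,count` table (CSV or TSV, header
# auto-detected) or a single delimited row of integers.

#' Read a count table from a delimited text file
#'
#' @param path Path to a CSV or TSV file holding either two columns
#'   `label,count` (header optional) or a single row of integer counts.
#'   The delimiter is auto-detected (tab wins over comma if both occur).
#'
#' @return A count tibble with columns `label` and `count`, in file order.
#' @examples
#' read_count_table(system.file("extdata", "gss_1998.csv",
#'                              package = "entrotest"))
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("Empty count file: %s", path))
  sep <- if (any(grepl("\t", lines))) "\t" else ","
  fields <- lapply(lines, function(l) trimws(strsplit(l, sep, fixed = TRUE)[[1]]))

  parse_count <- function(txt, line) {
    val <- suppressWarnings(as.numeric(txt))
    if (is.na(val) || val < 0 || val != round(val)) {
      abort(sprintf(
        "Line %d of %s: '%s' is not a non-negative integer count.",
        line, path, txt
      ))
    }
    val
  }

  if (length(lines) == 1 && length(fields[[1]]) >= 2 &&
      !anyNA(suppressWarnings(as.numeric(fields[[1]])))) {
    # single row of integers
    cts <- vapply(seq_along(fields[[1]]),
                  function(j) parse_count(fields[[1]][j], 1L), 0)
    return(count_table(cts))
  }

  start <- 1L
  if (length(fields[[1]]) >= 2 &&
      is.na(suppressWarnings(as.numeric(fields[[1]][2])))) {
    start <- 2L  # header row like "label,count"
    if (length(lines) < 2) abort(sprintf("No data rows in %s", path))
  }
  labels <- character()
  cts <- numeric()
  for (i in seq(start, length(lines))) {
    f <- fields[[i]]
    if (length(f) != 2) {
      abort(sprintf("Line %d of %s: expected 'label%scount', got '%s'.",
                    i, path, sep, lines[i]))
    }
    labels <- c(labels, f[1])
    cts <- c(cts, parse_count(f[2], i))
  }
  count_table(cts, labels = labels)
}

#' Write a count table to a delimited text file
#'
#' Mirrors [read_count_table()]: writes `label,count` rows with a header,
#' tab-separated when the path ends in `.tsv`.
#'
#' @param counts A count table or numeric vector of counts.
#' @param path Output path.
#'
#' @return The input, invisibly.
#' @export
write_count_table <- function(counts, path) {
  tbl <- as_count_tbl(counts)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(tbl[, c("label", "count")], path,
                     sep = sep, quote = FALSE, row.names = FALSE)
  invisible(counts)
}

#' Write an analysis result to JSON or TSV
#'
#' Tidies the result (laws and tests via their [tidy()] methods, data
#' frames as-is) and writes it as machine-readable JSON or a tab-separated
#' table.
#'
#' @param result An `entropy_law`, `entropy_test`, or data frame.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`; inferred from the path extension by
#'   default.
#'
#' @return `result`, invisibly.
#' @export
write_report <- function(result, path, format = NULL) {
  format <- format %||% (if (grepl("\\.json$", path)) "json" else "tsv")
  tbl <- if (is.data.frame(result)) as_tibble(result) else tidy(result)
  if (format == "json") {
    jsonlite::write_json(tbl, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(result)
}

#' GSS religious-intolerance count tables
#'
#' Counts of responses to the General Social Survey item asking agreement
#' with the statement that religious people are often too intolerant, on a
#' five-level scale from "strongly agree" to "strongly disagree", for the
#' 1998, 2008, and 2018 waves (totals 1202, 1323, 1130). Shipped as
#' plain-text fixtures under `inst/extdata`. With `collapsed = TRUE` the
#' 1998 five-level table is pooled into agreement / indifference /
#' disagreement (counts 577, 278, 347).
#'
#' @param year `"1998"`, `"2008"`, or `"2018"`.
#' @param collapsed Logical; collapse the five levels into three
#'   (only meaningful for 1998, but applied to any year).
#'
#' @return A count tibble with columns `label` and `count`.
#' @examples
#' gss_counts("1998")
#' gss_counts("1998", collapsed = TRUE)
#' @export
gss_counts <- function(year = c("1998", "2008", "2018"), collapsed = FALSE) {
  year <- match.arg(as.character(year), c("1998", "2008", "2018"))
  path <- system.file("extdata", paste0("gss_", year, ".csv"),
                      package = "entrotest")
  tbl <- read_count_table(path)
  if (collapsed) {
    tbl <- collapse_categories(
      tbl, groups = list(1:2, 3, 4:5),
      labels = c("agreement", "indifference", "disagreement")
    )
  }
  tbl
}
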