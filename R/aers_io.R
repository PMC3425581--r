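#' File dialect for legacy AERS quarterly extracts
#'
#' The legacy AERS quarterly convention is dollar-delimited ASCII, one record
#' per line, first line naming the columns. Both the delimiter and the
#' per-table column schema are configurable because extracts in the wild
#' differ; the defaults follow the legacy layout (a minimal column subset
#' sufficient for the analysis).
#'
#' @param delimiter single-character field delimiter (default `"$"`).
#' @param encoding text encoding the files are declared to be in.
#' @param columns named list of character vectors: expected header columns for
#'   each of the five tables `DEMO`, `DRUG`, `REAC`, `OUTC`, `RPSR`.
#' @param date_format `strptime` format of date fields (legacy AERS uses
#'   `YYYYMMDD`).
#' @return an object of class `aers_dialect`.
#' @export
aers_dialect <- function(delimiter = "$",
                         encoding = "UTF-8",
                         columns = NULL,
                         date_format = "%Y%m%d") {
  stopifnot(is.character(delimiter), nchar(delimiter) == 1L)
  default_cols <- list(
    DEMO = c("ISR", "CASE", "FDA_DT", "AGE", "AGE_COD", "GNDR_COD", "OCCP_COD"),
    DRUG = c("ISR", "DRUG_SEQ", "ROLE_COD", "DRUGNAME"),
    REAC = c("ISR", "PT"),
    OUTC = c("ISR", "OUTC_COD"),
    RPSR = c("ISR", "RPSR_COD")
  )
  columns <- utils::modifyList(default_cols, columns %||% list())
  structure(list(delimiter = delimiter, encoding = encoding,
                 columns = columns, date_format = date_format),
            class = "aers_dialect")
}

aers_table_names <- function() c("DEMO", "DRUG", "REAC", "OUTC", "RPSR")

# Read one delimited table file. Raw field strings are preserved exactly
# (no quoting, no type inference, no trimming beyond the line terminator);
# lines with the wrong field count go to the rejects log.
read_one_table <- function(path, table_name, dialect) {
  if (!file.exists(path)) {
    stop(sprintf("missing %s file: %s", table_name, path), call. = FALSE)
  }
  expected <- dialect$columns[[table_name]]
  lines <- readLines(path, encoding = dialect$encoding, warn = FALSE)
  n_bad_enc <- sum(!validEnc(lines))
  if (n_bad_enc > 0) {
    message(sprintf("%s: %d line(s) contained invalid %s bytes; replacement characters substituted",
                    table_name, n_bad_enc, dialect$encoding))
    lines <- iconv(lines, from = dialect$encoding, to = "UTF-8", sub = "�")
  }
  if (length(lines) == 0L) {
    stop(sprintf("%s file has no header row: %s", table_name, path), call. = FALSE)
  }
  header <- strsplit(lines[[1L]], dialect$delimiter, fixed = TRUE)[[1L]]
  if (!identical(header, expected)) {
    stop(sprintf("%s header mismatch: got [%s], expected [%s]",
                 table_name, paste(header, collapse = ", "),
                 paste(expected, collapse = ", ")), call. = FALSE)
  }
  body <- lines[-1L]
  rejects <- tibble::tibble(table = character(), line = integer(), reason = character())
  ok <- logical(0)
  if (length(body) == 0L) {
    rows <- tibble::as_tibble(stats::setNames(
      rep(list(character()), length(expected)), expected))
  } else {
    parts <- strsplit(body, dialect$delimiter, fixed = TRUE)
    # strsplit drops a trailing empty field; pad rows that are one short but
    # end in the delimiter
    parts <- lapply(seq_along(parts), function(i) {
      p <- parts[[i]]
      if (length(p) == length(expected) - 1L && endsWith(body[[i]], dialect$delimiter)) {
        p <- c(p, "")
      }
      p
    })
    ok <- lengths(parts) == length(expected)
    if (any(!ok)) {
      rejects <- tibble::tibble(
        table = table_name,
        line = which(!ok) + 1L,  # 1-based file line number incl. header
        reason = sprintf("expected %d fields, got %d",
                         length(expected), lengths(parts)[!ok])
      )
    }
    kept <- parts[ok]
    if (length(kept) == 0L) {
      rows <- tibble::as_tibble(stats::setNames(
        rep(list(character()), length(expected)), expected))
    } else {
      mat <- do.call(rbind, kept)
      rows <- tibble::as_tibble(stats::setNames(
        lapply(seq_along(expected), function(j) mat[, j]), expected))
    }
  }
  rows$.line <- if (nrow(rows)) which(ok) + 1L else integer()
  list(rows = rows, rejects = rejects)
}

#' Read one quarter of AERS-style table files
#'
#' Reads the five per-table delimited files into raw row tables, preserving
#' field strings byte-for-byte. Malformed lines (wrong field count) are
#' skipped and recorded in a rejects log with their file line numbers; a
#' missing file is a fatal error naming the table.
#'
#' @param paths named list/vector of file paths; names among
#'   `DEMO, DRUG, REAC, OUTC, RPSR`. `DRUG` and `REAC` are required for a
#'   useful quarter; any subset may be given.
#' @param dialect an [aers_dialect()].
#' @return an object of class `aers_raw`: list with `tables` (named list of
#'   tibbles of raw strings), `rejects` (tibble: table, line, reason) and
#'   `n_rows` (named integer of data rows read per table).
#' @export
read_quarter <- function(paths, dialect = aers_dialect()) {
  paths <- as.list(paths)
  bad <- setdiff(names(paths), aers_table_names())
  if (length(bad)) {
    stop("unknown table name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- lapply(names(paths), function(tn) read_one_table(paths[[tn]], tn, dialect))
  names(res) <- names(paths)
  tables <- lapply(res, `[[`, "rows")
  rejects <- dplyr::bind_rows(lapply(res, `[[`, "rejects"))
  structure(list(
    tables = tables,
    rejects = rejects,
    n_rows = vapply(tables, nrow, integer(1))
  ), class = "aers_raw")
}

#' Combine raw quarters
#'
#' Stacks the per-table rows of several [read_quarter()] results so a
#' multi-quarter study window can be assembled in one pass.
#'
#' @param ... `aers_raw` objects.
#' @return a single `aers_raw` object.
#' @export
bind_quarters <- function(...) {
  quarters <- list(...)
  if (length(quarters) == 1L && is.list(quarters[[1]]) &&
      !inherits(quarters[[1]], "aers_raw")) {
    quarters <- quarters[[1]]
  }
  stopifnot(all(vapply(quarters, inherits, logical(1), "aers_raw")))
  tns <- unique(unlist(lapply(quarters, function(q) names(q$tables))))
  tables <- lapply(tns, function(tn) {
    dplyr::bind_rows(lapply(quarters, function(q) q$tables[[tn]]))
  })
  names(tables) <- tns
  structure(list(
    tables = tables,
    rejects = dplyr::bind_rows(lapply(quarters, `[[`, "rejects")),
    n_rows = vapply(tables, nrow, integer(1))
  ), class = "aers_raw")
}

#' Assemble case reports from raw table rows
#'
#' Joins the per-table raw rows on the report instance key (ISR). Every ISR
#' with at least one drug mention and at least one reaction becomes a case
#' report; demographics are optional (missing demographics yield unknown
#' sex/occupation and `NA` age/date). ISRs with drugs but no reactions, or
#' reactions but no drugs, are excluded and counted.
#'
#' @param raw an `aers_raw` object from [read_quarter()]/[bind_quarters()].
#' @param dialect the [aers_dialect()] used to read it (for date parsing).
#' @return an object of class `aers_cases`: list of tidy tibbles
#'   \describe{
#'     \item{cases}{isr_id, case_id, receipt_date (Date), date_raw,
#'       age (years), sex, reporter_occupation — one row per report}
#'     \item{drugs}{isr_id, verbatim_name, canonical_drug (NA until
#'       [annotate_cases()]), role}
#'     \item{reactions}{isr_id, reaction (normalized preferred-term string)}
#'     \item{outcomes}{isr_id, outcome (deduplicated per report)}
#'   }
#'   with an `exclusions` attribute summarising dropped ISRs.
#' @export
assemble_cases <- function(raw, dialect = aers_dialect()) {
  stopifnot(inherits(raw, "aers_raw"))
  tb <- raw$tables
  empty_chr <- character()

  drug_tb <- tb$DRUG %||% tibble::tibble(ISR = empty_chr, ROLE_COD = empty_chr,
                                         DRUGNAME = empty_chr)
  reac_tb <- tb$REAC %||% tibble::tibble(ISR = empty_chr, PT = empty_chr)
  demo_tb <- tb$DEMO %||% tibble::tibble(ISR = empty_chr, CASE = empty_chr,
                                         FDA_DT = empty_chr, AGE = empty_chr,
                                         AGE_COD = empty_chr, GNDR_COD = empty_chr,
                                         OCCP_COD = empty_chr)
  outc_tb <- tb$OUTC %||% tibble::tibble(ISR = empty_chr, OUTC_COD = empty_chr)

  drug_isr <- unique(drug_tb$ISR)
  reac_isr <- unique(reac_tb$ISR)
  keep_isr <- intersect(drug_isr, reac_isr)
  excl_drug_only <- setdiff(drug_isr, reac_isr)
  excl_reac_only <- setdiff(reac_isr, drug_isr)

  drugs <- drug_tb |>
    dplyr::filter(.data$ISR %in% keep_isr, .data$DRUGNAME != "") |>
    dplyr::transmute(
      isr_id = .data$ISR,
      verbatim_name = .data$DRUGNAME,
      canonical_drug = NA_character_,
      role = role_from_code(.data$ROLE_COD)
    )

  reactions <- reac_tb |>
    dplyr::filter(.data$ISR %in% keep_isr, .data$PT != "") |>
    dplyr::transmute(isr_id = .data$ISR,
                     reaction = normalize_term(.data$PT)) |>
    dplyr::distinct()

  outcomes <- outc_tb |>
    dplyr::filter(.data$ISR %in% keep_isr, .data$OUTC_COD != "") |>
    dplyr::transmute(isr_id = .data$ISR,
                     outcome = outcome_from_code(.data$OUTC_COD)) |>
    dplyr::distinct()

  demo <- demo_tb |> dplyr::filter(.data$ISR %in% keep_isr)
  age_num <- suppressWarnings(as.numeric(demo$AGE))
  age_years <- dplyr::case_when(
    is.na(age_num) ~ NA_real_,
    toupper(demo$AGE_COD) %in% c("", "YR") ~ age_num,
    toupper(demo$AGE_COD) == "MON" ~ age_num / 12,
    toupper(demo$AGE_COD) == "DY" ~ age_num / 365.25,
    toupper(demo$AGE_COD) == "DEC" ~ age_num * 10,
    TRUE ~ NA_real_
  )
  demo_cases <- tibble::tibble(
    isr_id = demo$ISR,
    case_id = ifelse(demo$CASE == "", demo$ISR, demo$CASE),
    date_raw = demo$FDA_DT,
    receipt_date = as.Date(demo$FDA_DT, format = dialect$date_format),
    age = age_years,
    sex = dplyr::case_when(toupper(demo$GNDR_COD) %in% c("M", "F") ~ toupper(demo$GNDR_COD),
                           TRUE ~ "UNK"),
    reporter_occupation = occupation_from_code(demo$OCCP_COD)
  ) |>
    # a report instance has one demographic record; if an extract repeats it,
    # keep the first occurrence deterministically
    dplyr::distinct(.data$isr_id, .keep_all = TRUE)

  cases <- tibble::tibble(isr_id = keep_isr) |>
    dplyr::left_join(demo_cases, by = "isr_id") |>
    dplyr::mutate(
      case_id = dplyr::coalesce(.data$case_id, .data$isr_id),
      date_raw = dplyr::coalesce(.data$date_raw, ""),
      sex = dplyr::coalesce(.data$sex, "UNK"),
      reporter_occupation = dplyr::coalesce(.data$reporter_occupation, "UNKNOWN")
    ) |>
    dplyr::arrange(.data$isr_id)

  new_aers_cases(
    cases = cases,
    drugs = dplyr::arrange(drugs, .data$isr_id, .data$verbatim_name),
    reactions = dplyr::arrange(reactions, .data$isr_id, .data$reaction),
    outcomes = dplyr::arrange(outcomes, .data$isr_id, .data$outcome),
    exclusions = tibble::tibble(
      isr_id = c(excl_drug_only, excl_reac_only),
      reason = rep(c("NO_REACTIONS", "NO_DRUGS"),
                   c(length(excl_drug_only), length(excl_reac_only)))
    )
  )
}

new_aers_cases <- function(cases, drugs, reactions, outcomes,
                           exclusions = tibble::tibble(isr_id = character(),
                                                       reason = character())) {
  structure(list(cases = cases, drugs = drugs, reactions = reactions,
                 outcomes = outcomes),
            exclusions = exclusions,
            class = "aers_cases")
}

#' @export
print.aers_cases <- function(x, ...) {
  cat(sprintf("<aers_cases> %d case reports, %d drug mentions, %d reactions, %d outcome rows\n",
              nrow(x$cases), nrow(x$drugs), nrow(x$reactions), nrow(x$outcomes)))
  excl <- attr(x, "exclusions")
  if (!is.null(excl) && nrow(excl)) {
    cat(sprintf("  %d ISR(s) excluded during assembly\n", nrow(excl)))
  }
  invisible(x)
}

#' Number of case reports in an `aers_cases` object
#' @param x an `aers_cases` object.
#' @return integer count of report instances.
#' @export
n_cases <- function(x) {
  stopifnot(inherits(x, "aers_cases"))
  nrow(x$cases)
}

# Subset an aers_cases object to a set of ISR ids (internal).
filter_cases <- function(x, isr_keep) {
  new_aers_cases(
    cases = dplyr::filter(x$cases, .data$isr_id %in% isr_keep),
    drugs = dplyr::filter(x$drugs, .data$isr_id %in% isr_keep),
    reactions = dplyr::filter(x$reactions, .data$isr_id %in% isr_keep),
    outcomes = dplyr::filter(x$outcomes, .data$isr_id %in% isr_keep),
    exclusions = attr(x, "exclusions")
  )
}

#' Restrict case reports to a receipt-date window
#'
#' Reports with unparseable or missing receipt dates are kept and flagged in
#' the returned object's `undated` attribute rather than dropped, since the
#' source data does not say how such records should be treated.
#'
#' @param x an `aers_cases` object.
#' @param start,end window bounds (inclusive), anything `as.Date` accepts.
#'   Defaults cover July 2005 through March 2011.
#' @return the filtered `aers_cases` object.
#' @export
filter_date_window <- function(x, start = "2005-07-01", end = "2011-03-31") {
  stopifnot(inherits(x, "aers_cases"))
  start <- as.Date(start); end <- as.Date(end)
  dated <- !is.na(x$cases$receipt_date)
  inside <- dated & x$cases$receipt_date >= start & x$cases$receipt_date <= end
  keep <- x$cases$isr_id[inside | !dated]
  out <- filter_cases(x, keep)
  attr(out, "undated") <- x$cases$isr_id[!dated]
  out
}

#' Write a result table as CSV
#'
#' RFC-4180 CSV with a header row. Numeric formatting is left at full
#' precision so that [read_result_table()] round-trips values exactly;
#' display rounding is applied upstream by the table builders.
#'
#' @param table a data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(table, path) {
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' Read back a result table written by [write_result_table()]
#' @param path CSV path.
#' @return a tibble.
#' @export
read_result_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
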