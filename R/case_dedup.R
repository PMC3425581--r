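#' Collapse follow-up report versions to one report per case
#'
#' Safety reports arrive in versions: a follow-up shares the case-level key
#' of the initial report. Counting versions would double-count patients, so
#' for each `case_id` only the report with the latest receipt date survives
#' (ties broken deterministically by largest `isr_id`, lexicographically).
#' Undated reports sort before dated ones, so a dated follow-up supersedes
#' an undated initial.
#'
#' @param x an `aers_cases` object.
#' @return the surviving `aers_cases`; the decisions log (tibble:
#'   `kept_isr`, `dropped_isr`, `reason = "FOLLOWUP_VERSION"`) is attached
#'   as attribute `dedup_decisions`.
#' @export
dedup_versions <- function(x) {
  stopifnot(inherits(x, "aers_cases"))
  ranked <- x$cases |>
    dplyr::mutate(.date_key = dplyr::coalesce(.data$receipt_date, as.Date("0001-01-01"))) |>
    dplyr::arrange(.data$case_id, dplyr::desc(.data$.date_key), dplyr::desc(.data$isr_id))
  keep <- ranked |> dplyr::distinct(.data$case_id, .keep_all = TRUE)
  decisions <- ranked |>
    dplyr::anti_join(dplyr::select(keep, "isr_id"), by = "isr_id") |>
    dplyr::left_join(dplyr::select(keep, "case_id", kept_isr = "isr_id"),
                     by = "case_id") |>
    dplyr::transmute(kept_isr = .data$kept_isr, dropped_isr = .data$isr_id,
                     reason = "FOLLOWUP_VERSION")
  out <- filter_cases(x, keep$isr_id)
  attr(out, "dedup_decisions") <- decisions
  out
}

#' Remove heuristic duplicate case reports
#'
#' Independently submitted reports describing the same adverse event in the
#' same patient (e.g. one from the physician and one from the manufacturer)
#' carry different case keys, so version collapsing cannot see them. This
#' conservative field-agreement heuristic treats reports as duplicates only
#' when they agree on \emph{all} of: the sorted set of canonical drugs, the
#' sorted set of reaction terms, sex, age (exactly, both present), and
#' receipt date within `date_window` days. Within a duplicate group the
#' earliest-received report survives (tie: smallest `isr_id`).
#'
#' Reports with any missing blocking field (no canonical drug, unknown sex,
#' missing age or date) never match anything — absence of evidence is not
#' agreement.
#'
#' @param x an `aers_cases` object, already version-deduplicated and
#'   annotated with canonical drug names.
#' @param date_window maximum receipt-date separation, in days, for two
#'   reports to be considered the same event (default 30).
#' @return surviving `aers_cases` with attribute `dedup_decisions` (tibble:
#'   `kept_isr`, `dropped_isr`, `reason = "HEURISTIC_DUPLICATE"`).
#' @export
dedup_heuristic <- function(x, date_window = 30) {
  stopifnot(inherits(x, "aers_cases"))
  drug_key <- x$drugs |>
    dplyr::filter(!is.na(.data$canonical_drug)) |>
    dplyr::distinct(.data$isr_id, .data$canonical_drug) |>
    dplyr::group_by(.data$isr_id) |>
    dplyr::summarise(drug_set = paste(sort(.data$canonical_drug), collapse = "|"))
  reac_key <- x$reactions |>
    dplyr::group_by(.data$isr_id) |>
    dplyr::summarise(reac_set = paste(sort(unique(.data$reaction)), collapse = "|"))
  keyed <- x$cases |>
    dplyr::left_join(drug_key, by = "isr_id") |>
    dplyr::left_join(reac_key, by = "isr_id") |>
    dplyr::mutate(
      eligible = !is.na(.data$drug_set) & !is.na(.data$reac_set) &
        .data$sex %in% c("M", "F") & !is.na(.data$age) &
        !is.na(.data$receipt_date),
      block = paste(.data$drug_set, .data$reac_set, .data$sex, .data$age, sep = "\r")
    )

  survivors <- character(0)
  decisions <- list()
  eligible <- keyed[keyed$eligible, , drop = FALSE]
  survivors <- keyed$isr_id[!keyed$eligible]
  if (nrow(eligible)) {
    groups <- split(eligible, eligible$block)
    for (g in groups) {
      g <- g[order(g$receipt_date, g$isr_id), , drop = FALSE]
      # chain rule: a report joins the open duplicate cluster while it is
      # within date_window of the cluster's first (surviving) report
      anchor_date <- NULL
      anchor_isr <- NULL
      for (i in seq_len(nrow(g))) {
        if (is.null(anchor_date) ||
            as.numeric(g$receipt_date[i] - anchor_date) > date_window) {
          anchor_date <- g$receipt_date[i]
          anchor_isr <- g$isr_id[i]
          survivors <- c(survivors, anchor_isr)
        } else {
          decisions[[length(decisions) + 1L]] <- tibble::tibble(
            kept_isr = anchor_isr, dropped_isr = g$isr_id[i],
            reason = "HEURISTIC_DUPLICATE")
        }
      }
    }
  }
  decisions <- if (length(decisions)) dplyr::bind_rows(decisions) else
    tibble::tibble(kept_isr = character(), dropped_isr = character(),
                   reason = character())
  out <- filter_cases(x, survivors)
  attr(out, "dedup_decisions") <- dplyr::arrange(decisions, .data$dropped_isr)
  out
}

#' Run both deduplication stages
#'
#' Version collapsing ([dedup_versions()]) followed by the duplicate-report
#' heuristic ([dedup_heuristic()]); decision logs from both stages are
#' concatenated.
#'
#' @inheritParams dedup_heuristic
#' @return surviving `aers_cases` with combined `dedup_decisions` attribute.
#' @export
dedup_cases <- function(x, date_window = 30) {
  v <- dedup_versions(x)
  h <- dedup_heuristic(v, date_window = date_window)
  attr(h, "dedup_decisions") <- dplyr::bind_rows(attr(v, "dedup_decisions"),
                                                 attr(h, "dedup_decisions"))
  h
}
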