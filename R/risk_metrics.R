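#' Prescribing ratios from summed new-prescription totals
#'
#' Spontaneous-report counts cannot be compared across drugs with very
#' different market sizes, so each drug's summed new-prescription total
#' (NRx) is scaled to the most-prescribed drug in the comparison set:
#' `pr[d] = nrx[d] / max(nrx)`, rounded half-up to 4 decimals. The
#' most-prescribed drug has ratio exactly 1.
#'
#' @param nrx named numeric vector (or two-column data frame `drug`, `nrx`)
#'   of summed new-prescription counts; all positive.
#' @return a tibble of class `prescription_table` with columns `drug`,
#'   `nrx`, `pr`.
#' @examples
#' prescribing_ratios(statin_nrx())
#' @export
prescribing_ratios <- function(nrx) {
  if (is.data.frame(nrx)) {
    stopifnot(all(c("drug", "nrx") %in% names(nrx)))
    nrx <- stats::setNames(nrx$nrx, nrx$drug)
  }
  if (length(nrx) == 0L) stop("empty prescription table", call. = FALSE)
  if (any(is.na(nrx)) || any(nrx <= 0)) {
    stop("all NRx counts must be positive", call. = FALSE)
  }
  out <- tibble::tibble(
    drug = names(nrx),
    nrx = unname(nrx),
    pr = round_half_up(unname(nrx) / max(nrx), 4)
  )
  structure(dplyr::arrange(out, dplyr::desc(.data$nrx)),
            class = c("prescription_table", class(out)))
}

#' The published statin NRx totals
#'
#' Summed quarterly new-prescription totals for the six statins over
#' July 2005 through March 2011, used as the prescribing denominator in the
#' worked example.
#'
#' @return named numeric vector of NRx counts.
#' @export
statin_nrx <- function() {
  df <- readr::read_csv(system.file("extdata", "statin_nrx.csv",
                                    package = "aersrank", mustWork = TRUE),
                        col_types = "cd", progress = FALSE)
  stats::setNames(df$nrx, df$drug)
}

#' Published myalgia case-report counts for the six statins
#'
#' The primary-suspect and all-suspect deduplicated myalgia report counts
#' for July 2005 through March 2011, packaged as the worked-example input:
#' feeding them through [prescribing_ratios()], [normalized_rate()] and
#' [ranked_risk()] (via [build_risk_table()]) reproduces the published
#' derived columns.
#'
#' @return tibble: drug, primary_count, all_count.
#' @export
statin_myalgia_counts <- function() {
  readr::read_csv(system.file("extdata", "statin_myalgia_counts.csv",
                              package = "aersrank", mustWork = TRUE),
                  col_types = "cii", progress = FALSE)
}

#' Count matching case reports for one drug and category
#'
#' A report counts if it matches the category and mentions the drug in the
#' requested suspect role: `PRIMARY` counts only primary-suspect mentions;
#' `ALL_SUSPECT` counts primary or secondary suspect. Concomitant and
#' interacting mentions are excluded unless `include_concomitant = TRUE`.
#' Each report counts at most once regardless of how many of its reactions
#' or drug mentions qualify.
#'
#' @param x an annotated, deduplicated `aers_cases` object.
#' @param drug canonical drug name.
#' @param cat an [event_category()].
#' @param role_scope `"PRIMARY"` or `"ALL_SUSPECT"`.
#' @param include_concomitant widen `ALL_SUSPECT` to every mention role.
#' @return integer count of case reports.
#' @export
count_reports <- function(x, drug, cat, role_scope = c("PRIMARY", "ALL_SUSPECT"),
                          include_concomitant = FALSE) {
  role_scope <- match.arg(role_scope)
  stopifnot(inherits(x, "aers_cases"))
  if (!drug %in% x$drugs$canonical_drug) {
    warning(sprintf("drug '%s' not present in any report", drug), call. = FALSE)
    return(0L)
  }
  roles <- switch(role_scope,
                  PRIMARY = "PRIMARY_SUSPECT",
                  ALL_SUSPECT = if (include_concomitant) aers_roles()
                                else c("PRIMARY_SUSPECT", "SECONDARY_SUSPECT"))
  drug_isr <- unique(x$drugs$isr_id[x$drugs$canonical_drug %in% drug &
                                      x$drugs$role %in% roles])
  length(intersect(drug_isr, matching_isrs(x, cat)))
}

#' Prescription-normalized reporting rate
#'
#' The report count divided by the drug's prescribing ratio: reports per
#' unit prescribing ratio. Kept at full precision; display rounding (half-up
#' to integer) is applied by the table builders.
#'
#' @param count non-negative report count.
#' @param pr prescribing ratio in (0, 1].
#' @return numeric rate.
#' @export
normalized_rate <- function(count, pr) {
  if (any(is.na(pr)) || any(pr <= 0)) {
    stop("prescribing ratio must be positive", call. = FALSE)
  }
  count / pr
}

#' Ranked risk: normalized rates rescaled to the highest-rate drug
#'
#' Within one adverse-event category the drug with the highest normalized
#' rate is assigned 100 and every other drug is expressed as a half-up
#' rounded integer percentage of it. An all-zero input yields all zeros with
#' a warning.
#'
#' @param rates named numeric vector of normalized rates (one per drug).
#' @return named integer vector, 0–100, same names as `rates`.
#' @export
ranked_risk <- function(rates) {
  stopifnot(is.numeric(rates))
  if (all(rates == 0)) {
    warning("all rates are zero; ranked risks are all zero", call. = FALSE)
    return(stats::setNames(as.integer(rates), names(rates)))
  }
  stats::setNames(as.integer(round_half_up(100 * rates / max(rates))),
                  names(rates))
}

#' Build the per-category risk table
#'
#' The central result table: per drug, the primary-suspect and all-suspect
#' report counts for one category, the prescribing ratio, the normalized
#' rates (displayed half-up rounded to integers) and the ranked risks.
#'
#' @param x an annotated, deduplicated `aers_cases` object.
#' @param cat an [event_category()].
#' @param pr_table a [prescribing_ratios()] table; its drugs define the rows.
#' @param include_concomitant see [count_reports()].
#' @return tibble: drug, primary_count, all_count, pr, primary_rate,
#'   all_rate, ranked_primary, ranked_all — sorted by descending
#'   ranked_primary.
#' @export
risk_table <- function(x, cat, pr_table, include_concomitant = FALSE) {
  stopifnot(inherits(pr_table, "prescription_table"))
  drugs <- pr_table$drug
  primary <- vapply(drugs, function(d)
    count_reports(x, d, cat, "PRIMARY"), integer(1))
  all_ct <- vapply(drugs, function(d)
    count_reports(x, d, cat, "ALL_SUSPECT", include_concomitant), integer(1))
  build_risk_table(cat$name, drugs, primary, all_ct, pr_table$pr)
}

#' Assemble a risk table from pre-tabulated counts
#'
#' The arithmetic core of [risk_table()], exposed so published count tables
#' can be fed through the identical rate and ranking computation.
#'
#' @param category category name (label column).
#' @param drug,primary_count,all_count,pr parallel vectors per drug.
#' @return the risk-table tibble (see [risk_table()]).
#' @export
build_risk_table <- function(category, drug, primary_count, all_count, pr) {
  stopifnot(length(drug) == length(primary_count),
            length(drug) == length(all_count),
            length(drug) == length(pr))
  if (any(all_count < primary_count)) {
    stop("all-suspect count below primary count — inconsistent inputs",
         call. = FALSE)
  }
  p_rate <- normalized_rate(primary_count, pr)
  a_rate <- normalized_rate(all_count, pr)
  tibble::tibble(
    category = category,
    drug = drug,
    primary_count = as.integer(primary_count),
    all_count = as.integer(all_count),
    pr = pr,
    primary_rate = as.integer(round_half_up(p_rate)),
    all_rate = as.integer(round_half_up(a_rate)),
    ranked_primary = unname(ranked_risk(stats::setNames(p_rate, drug))),
    ranked_all = unname(ranked_risk(stats::setNames(a_rate, drug)))
  ) |>
    dplyr::arrange(dplyr::desc(.data$ranked_primary))
}

#' Combined risk across several categories
#'
#' Per drug, category counts are summed (a report matching k categories
#' contributes k, mirroring a sum of per-category tables), divided by the
#' prescribing ratio, and expressed as a percentage of the highest-rate
#' drug, to one decimal. `counting = "unique_case"` instead counts each
#' report once if it matches any category.
#'
#' @param x annotated, deduplicated `aers_cases`.
#' @param cats list of [event_category()] objects.
#' @param pr_table a [prescribing_ratios()] table.
#' @param role_scope `"PRIMARY"` or `"ALL_SUSPECT"`.
#' @param counting `"per_category_sum"` (default) or `"unique_case"`.
#' @return tibble: drug, combined_count, pr, combined_rate,
#'   percent_of_max (one decimal).
#' @export
combined_risk <- function(x, cats, pr_table,
                          role_scope = c("PRIMARY", "ALL_SUSPECT"),
                          counting = c("per_category_sum", "unique_case")) {
  role_scope <- match.arg(role_scope)
  counting <- match.arg(counting)
  stopifnot(inherits(pr_table, "prescription_table"))
  drugs <- pr_table$drug
  roles <- if (role_scope == "PRIMARY") "PRIMARY_SUSPECT"
           else c("PRIMARY_SUSPECT", "SECONDARY_SUSPECT")
  counts <- vapply(drugs, function(d) {
    drug_isr <- unique(x$drugs$isr_id[x$drugs$canonical_drug %in% d &
                                        x$drugs$role %in% roles])
    per_cat <- lapply(cats, function(cat) intersect(drug_isr, matching_isrs(x, cat)))
    if (counting == "per_category_sum") sum(lengths(per_cat))
    else length(unique(unlist(per_cat)))
  }, numeric(1))
  rate <- normalized_rate(counts, pr_table$pr)
  pct <- if (all(rate == 0)) rate else round_half_up(100 * rate / max(rate), 1)
  tibble::tibble(drug = drugs, combined_count = as.integer(counts),
                 pr = pr_table$pr, combined_rate = rate,
                 percent_of_max = pct) |>
    dplyr::arrange(dplyr::desc(.data$percent_of_max))
}

#' Yearly primary-suspect report counts
#'
#' Partitions a (drug, category) primary-suspect count by receipt year;
#' undated reports fall into an `"UNKNOWN"` bucket so the yearly counts
#' always sum to the total.
#'
#' @param x annotated, deduplicated `aers_cases`.
#' @param drug canonical drug name.
#' @param cat an [event_category()].
#' @return tibble: year (character; calendar year or `"UNKNOWN"`), n.
#' @export
yearly_trend <- function(x, drug, cat) {
  stopifnot(inherits(x, "aers_cases"))
  isr <- intersect(
    unique(x$drugs$isr_id[x$drugs$canonical_drug %in% drug &
                            x$drugs$role == "PRIMARY_SUSPECT"]),
    matching_isrs(x, cat))
  dates <- x$cases$receipt_date[match(isr, x$cases$isr_id)]
  year <- ifelse(is.na(dates), "UNKNOWN", format(dates, "%Y"))
  tibble::tibble(year = year) |>
    dplyr::count(.data$year, name = "n") |>
    dplyr::arrange(.data$year)
}

#' Stratify a (drug, category) count by outcome or reporter
#'
#' `OUTCOME` strata are non-exclusive: a report listing both death and
#' hospitalization contributes to both, so outcome counts can exceed the
#' report total. `REPORTER` strata are exclusive and partition the count;
#' reporter output also carries each stratum's percentage of the total.
#'
#' @param x annotated, deduplicated `aers_cases`.
#' @param drug canonical drug name.
#' @param cat an [event_category()].
#' @param axis `"OUTCOME"` or `"REPORTER"`.
#' @param role_scope `"PRIMARY"` or `"ALL_SUSPECT"`.
#' @return tibble: drug, category, stratum, n (+ `percent` for REPORTER).
#' @export
stratify <- function(x, drug, cat, axis = c("OUTCOME", "REPORTER"),
                     role_scope = c("PRIMARY", "ALL_SUSPECT")) {
  axis <- match.arg(axis)
  role_scope <- match.arg(role_scope)
  roles <- if (role_scope == "PRIMARY") "PRIMARY_SUSPECT"
           else c("PRIMARY_SUSPECT", "SECONDARY_SUSPECT")
  isr <- intersect(
    unique(x$drugs$isr_id[x$drugs$canonical_drug %in% drug &
                            x$drugs$role %in% roles]),
    matching_isrs(x, cat))
  if (axis == "OUTCOME") {
    out <- x$outcomes |>
      dplyr::filter(.data$isr_id %in% isr) |>
      dplyr::count(stratum = .data$outcome, name = "n")
  } else {
    total <- length(isr)
    out <- x$cases |>
      dplyr::filter(.data$isr_id %in% isr) |>
      dplyr::count(stratum = .data$reporter_occupation, name = "n") |>
      dplyr::mutate(percent = if (total > 0) round_half_up(100 * .data$n / total, 1)
                    else numeric(length(.data$n)))
  }
  dplyr::bind_cols(tibble::tibble(drug = rep(drug, nrow(out)),
                                  category = rep(cat$name, nrow(out))), out)
}

#' Sensitivity analysis: ratios from peak annual prescriptions
#'
#' Re-runs the risk-table pipeline with prescribing ratios derived from each
#' drug's \emph{peak} annual prescription count rather than the summed total
#' — a check that the ranking is not an artifact of the denominator choice.
#'
#' @param nrx_by_year data frame with columns `drug`, `year`, `nrx`.
#' @param x annotated, deduplicated `aers_cases`.
#' @param cat an [event_category()].
#' @param include_concomitant see [count_reports()].
#' @return risk-table tibble with an extra column `variant = "peak_rx"`.
#' @export
sensitivity_peak_rx <- function(nrx_by_year, x, cat, include_concomitant = FALSE) {
  stopifnot(all(c("drug", "year", "nrx") %in% names(nrx_by_year)))
  peak <- nrx_by_year |>
    dplyr::group_by(.data$drug) |>
    dplyr::summarise(nrx = max(.data$nrx))
  pr_table <- prescribing_ratios(stats::setNames(peak$nrx, peak$drug))
  out <- risk_table(x, cat, pr_table, include_concomitant)
  out$variant <- "peak_rx"
  out
}
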