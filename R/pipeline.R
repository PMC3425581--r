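#' Pipeline run configuration
#'
#' Collects every knob of the end-to-end analysis. All referenced files
#' must exist at validation time; validation failures name the offending
#' field so misconfigured runs die before any work is done.
#'
#' @param input_paths named character vector of quarterly table files
#'   (names among `DEMO, DRUG, REAC, OUTC, RPSR`), or a list of such
#'   vectors for multi-quarter runs.
#' @param dictionary_path synonym dictionary CSV (`NULL` uses the packaged
#'   statin dictionary).
#' @param category_path category definition CSV (`NULL` uses the packaged
#'   muscle categories).
#' @param nrx_path prescription table CSV with columns `drug,nrx` (`NULL`
#'   uses the packaged statin NRx totals).
#' @param output_dir directory for result tables (created if needed).
#' @param dialect an [aers_dialect()].
#' @param date_window length-2 receipt-date window, or `NULL` to skip
#'   windowing.
#' @param max_distance fuzzy-match threshold for [match_drug()].
#' @param dedup_window heuristic dedup date window, days.
#' @param role_scope `"PRIMARY"`/`"ALL_SUSPECT"` for the combined-risk table.
#' @param include_concomitant widen all-suspect counting to every role.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input_paths,
                       dictionary_path = NULL,
                       category_path = NULL,
                       nrx_path = NULL,
                       output_dir = "aersrank_out",
                       dialect = aers_dialect(),
                       date_window = c("2005-07-01", "2011-03-31"),
                       max_distance = 1L,
                       dedup_window = 30,
                       role_scope = "PRIMARY",
                       include_concomitant = FALSE) {
  # a single quarter is a named vector/list of per-table paths; several
  # quarters come as an unnamed list of such vectors
  single <- !is.null(names(input_paths)) &&
    all(names(input_paths) %in% aers_table_names())
  quarters <- if (single) list(input_paths) else input_paths
  for (q in quarters) {
    missing <- q[!file.exists(unlist(q))]
    if (length(missing)) {
      stop("run_config: input_paths refers to missing file(s): ",
           paste(unlist(missing), collapse = ", "), call. = FALSE)
    }
  }
  for (field in c("dictionary_path", "category_path", "nrx_path")) {
    p <- get(field)
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("run_config: %s does not exist: %s", field, p), call. = FALSE)
    }
  }
  structure(list(quarters = quarters, dictionary_path = dictionary_path,
                 category_path = category_path, nrx_path = nrx_path,
                 output_dir = output_dir, dialect = dialect,
                 date_window = date_window, max_distance = max_distance,
                 dedup_window = dedup_window, role_scope = role_scope,
                 include_concomitant = include_concomitant),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Read → assemble → (optional) date window → normalize drug names → dedup
#' → per-category risk tables → combined risk → yearly trends →
#' outcome/reporter stratifications. Every stage's output is materialized
#' under `output_dir` so any step can be audited, and a JSON run manifest
#' records configuration, row-count conservation and output file hashes.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list: `cases` (final `aers_cases`), `tables`
#'   (named list of result tibbles), `manifest` (the manifest list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)

  quarters <- lapply(config$quarters, read_quarter, dialect = config$dialect)
  raw <- if (length(quarters) == 1L) quarters[[1]] else bind_quarters(quarters)
  assembled <- assemble_cases(raw, dialect = config$dialect)
  n_assembled <- n_cases(assembled)

  windowed <- if (!is.null(config$date_window)) {
    filter_date_window(assembled, config$date_window[1], config$date_window[2])
  } else assembled
  n_windowed <- n_cases(windowed)

  dict <- if (is.null(config$dictionary_path)) default_statin_dictionary()
          else synonym_dictionary(config$dictionary_path)
  annotated <- annotate_cases(windowed, dict, config$max_distance)
  write_result_table(attr(annotated, "consolidation"), out("consolidation.csv"))

  deduped <- dedup_cases(annotated, date_window = config$dedup_window)
  decisions <- attr(deduped, "dedup_decisions")
  write_result_table(decisions, out("dedup_decisions.csv"))
  n_final <- n_cases(deduped)

  cats <- if (is.null(config$category_path)) default_muscle_categories()
          else load_categories(config$category_path)
  nrx <- if (is.null(config$nrx_path)) statin_nrx() else {
    df <- readr::read_csv(config$nrx_path, col_types = "cd", progress = FALSE)
    stats::setNames(df$nrx, df$drug)
  }
  pr_table <- prescribing_ratios(nrx)
  write_result_table(pr_table, out("prescribing_ratios.csv"))

  risk <- dplyr::bind_rows(lapply(cats, function(cat)
    risk_table(deduped, cat, pr_table, config$include_concomitant)))
  write_result_table(risk, out("risk_tables.csv"))

  combined <- combined_risk(deduped, cats, pr_table, config$role_scope)
  write_result_table(combined, out("combined_risk.csv"))

  yearly <- dplyr::bind_rows(lapply(names(cats), function(cn) {
    dplyr::bind_rows(lapply(pr_table$drug, function(d) {
      yt <- yearly_trend(deduped, d, cats[[cn]])
      if (nrow(yt)) dplyr::bind_cols(tibble::tibble(drug = d, category = cn), yt)
    }))
  }))
  write_result_table(yearly, out("yearly_trends.csv"))

  strat <- dplyr::bind_rows(lapply(names(cats), function(cn) {
    dplyr::bind_rows(lapply(pr_table$drug, function(d) {
      dplyr::bind_rows(
        stratify(deduped, d, cats[[cn]], "OUTCOME"),
        stratify(deduped, d, cats[[cn]], "REPORTER")
      )
    }))
  }))
  write_result_table(strat, out("stratifications.csv"))

  n_read <- sum(raw$n_rows)
  manifest <- list(
    package_version = as.character(utils::packageVersion("aersrank")),
    config = list(
      date_window = config$date_window, max_distance = config$max_distance,
      dedup_window = config$dedup_window, role_scope = config$role_scope,
      include_concomitant = config$include_concomitant
    ),
    conservation = list(
      rows_read = n_read,
      rows_rejected = nrow(raw$rejects),
      reports_assembled = n_assembled,
      reports_excluded_assembly = nrow(attr(assembled, "exclusions")),
      reports_in_window = n_windowed,
      reports_dropped_dedup = nrow(decisions),
      reports_final = n_final,
      dedup_balance = n_windowed == n_final + nrow(decisions)
    ),
    outputs = {
      fs <- list.files(config$output_dir, pattern = "[.]csv$", full.names = TRUE)
      stats::setNames(as.list(unname(tools::md5sum(fs))), basename(fs))
    }
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(cases = deduped,
                 tables = list(prescribing_ratios = pr_table, risk = risk,
                               combined = combined, yearly = yearly,
                               stratifications = strat,
                               consolidation = attr(annotated, "consolidation"),
                               dedup_decisions = decisions),
                 manifest = manifest))
}
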