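#' Normalize a verbatim drug-name string
#'
#' Reduces the free-text drug names entered on safety reports to a canonical
#' comparison form: case-folded, bracketed qualifiers removed, punctuation
#' stripped, whitespace collapsed, and trailing dosage/strength/form tokens
#' (e.g. `10 MG TABLET`, `CAP`, `ER`, bare numbers) dropped. The function is
#' idempotent: normalizing an already-normalized string is a no-op.
#'
#' Dosage-token stripping is applied only at the end of the string so that a
#' salt or form word inside a name is never removed from the middle.
#'
#' @param raw character vector of verbatim names (possibly empty strings).
#' @return character vector of normalized names.
#' @examples
#' normalize_name("LIPITOR 10 MG TABLET")      # "lipitor"
#' normalize_name("Atorvastatin  (Calcium)")   # "atorvastatin"
#' @export
normalize_name <- function(raw) {
  x <- tolower(raw)
  x <- stringr::str_remove_all(x, "\\([^)]*\\)|\\[[^]]*\\]|\\{[^}]*\\}")
  x <- stringr::str_replace_all(x, "[[:punct:]]", " ")
  x <- stringr::str_squish(x)
  dosage <- c("mg", "mcg", "g", "ml", "tab", "tablet", "tablets",
              "cap", "capsule", "capsules", "hcl", "er", "xl", "sr")
  # trailing run of form/strength tokens: unit words, bare numbers, or a
  # number fused with a unit ("10mg")
  drop_pattern <- sprintf("( (%s|[0-9]+([.][0-9]+)?(%s)?))+$",
                          paste(dosage, collapse = "|"),
                          paste(c("mg", "mcg", "g", "ml"), collapse = "|"))
  x <- stringr::str_remove(x, drop_pattern)
  # a name that was nothing but dosage tokens reduces to empty
  x[x %in% c(dosage)] <- ""
  suppressWarnings(x[!is.na(as.numeric(x))] <- "")
  x
}

#' Load and validate a synonym dictionary
#'
#' A synonym dictionary maps every known variant of a drug name (generic
#' names, brand names, foreign designations, misspellings, dosage-bearing
#' strings) to one canonical drug. Variants are stored normalized (see
#' [normalize_name()]); a normalized variant mapping to two canonical drugs
#' is a fatal dictionary error — consolidation must never be ambiguous.
#'
#' @param path two-column delimited file (`canonical,variant`), or `NULL` to
#'   build from `entries`.
#' @param entries alternatively, a data frame with columns `canonical` and
#'   `variant`.
#' @param provenance tag recorded per variant (`"curated"` or `"generated"`).
#' @return an object of class `synonym_dictionary`: tibble with columns
#'   `canonical`, `variant` (normalized), `provenance`.
#' @export
synonym_dictionary <- function(path = NULL, entries = NULL, provenance = "curated") {
  if (is.null(entries)) {
    stopifnot(!is.null(path))
    entries <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                               progress = FALSE)
  }
  stopifnot(all(c("canonical", "variant") %in% names(entries)))
  dict <- tibble::as_tibble(entries) |>
    dplyr::transmute(
      canonical = normalize_name(.data$canonical),
      variant = normalize_name(.data$variant),
      provenance = if ("provenance" %in% names(entries)) .data$provenance else provenance
    ) |>
    dplyr::filter(.data$variant != "") |>
    dplyr::distinct(.data$canonical, .data$variant, .keep_all = TRUE)
  clash <- dict |>
    dplyr::count(.data$variant) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(clash)) {
    stop("synonym dictionary maps variant(s) to multiple canonical drugs: ",
         paste(clash$variant, collapse = ", "), call. = FALSE)
  }
  # every canonical name is implicitly a variant of itself
  self <- tibble::tibble(canonical = unique(dict$canonical),
                         variant = unique(dict$canonical),
                         provenance = "curated")
  dict <- dplyr::bind_rows(dict, dplyr::anti_join(self, dict, by = "variant")) |>
    dplyr::arrange(.data$canonical, .data$variant)
  structure(dict, class = c("synonym_dictionary", class(dict)))
}

#' The packaged statin synonym dictionary
#'
#' A curated dictionary covering the six statins (atorvastatin, simvastatin,
#' lovastatin, pravastatin, rosuvastatin, fluvastatin): generic and brand
#' names, salt forms, common foreign designations and frequent misspellings.
#' It is deliberately small and hand-checked; edit-distance matching in
#' [match_drug()] acts as a safety net for variants it misses.
#'
#' @return a `synonym_dictionary`.
#' @export
default_statin_dictionary <- function() {
  synonym_dictionary(system.file("extdata", "statin_synonyms.csv",
                                 package = "aersrank", mustWork = TRUE))
}

#' Match one or more verbatim names against a synonym dictionary
#'
#' Exact dictionary hits (after [normalize_name()]) win outright. Otherwise,
#' if `max_distance > 0`, the nearest variant by Levenshtein edit distance is
#' used provided (a) the distance is within `max_distance` and (b) all
#' variants at that minimum distance agree on the canonical drug; a tie
#' between canonical drugs is never guessed and yields `NONE` with a logged
#' ambiguity. Matching is deterministic.
#'
#' @param raw character vector of verbatim names.
#' @param dict a [synonym_dictionary()].
#' @param max_distance maximum Levenshtein distance for a fuzzy match
#'   (default 1; 0 disables fuzzy matching).
#' @return tibble with one row per input: `raw`, `normalized`,
#'   `canonical_drug` (NA if unmatched), `method` (`EXACT`/`FUZZY`/`NONE`),
#'   `distance` (0 for exact, NA for none), `matched_variant`.
#' @export
match_drug <- function(raw, dict, max_distance = 1L) {
  stopifnot(inherits(dict, "synonym_dictionary"), max_distance >= 0)
  norm <- normalize_name(raw)
  out <- tibble::tibble(
    raw = raw, normalized = norm,
    canonical_drug = NA_character_,
    method = "NONE",
    distance = NA_integer_,
    matched_variant = NA_character_
  )
  idx <- match(norm, dict$variant)
  hit <- !is.na(idx) & norm != ""
  out$canonical_drug[hit] <- dict$canonical[idx[hit]]
  out$method[hit] <- "EXACT"
  out$distance[hit] <- 0L
  out$matched_variant[hit] <- dict$variant[idx[hit]]

  todo <- which(!hit & norm != "")
  if (max_distance > 0L && length(todo)) {
    queries <- unique(norm[todo])
    dmat <- utils::adist(queries, dict$variant)  # Levenshtein, unit costs
    for (q in seq_along(queries)) {
      d <- dmat[q, ]
      dmin <- min(d)
      if (dmin > max_distance) next
      cands <- unique(dict$canonical[d == dmin])
      rows <- todo[norm[todo] == queries[q]]
      if (length(cands) > 1L) {
        message(sprintf("ambiguous fuzzy match for '%s' (distance %d): %s — left unmatched",
                        queries[q], dmin, paste(cands, collapse = " | ")))
        next
      }
      out$canonical_drug[rows] <- cands
      out$method[rows] <- "FUZZY"
      out$distance[rows] <- as.integer(dmin)
      out$matched_variant[rows] <- dict$variant[which(d == dmin)[1L]]
    }
  }
  out
}

#' Annotate case reports with canonical drug names
#'
#' Fills `canonical_drug` on every drug mention and returns a consolidation
#' report listing, per canonical drug, the distinct verbatim variants that
#' were consolidated into it and how often each occurred. Unmatched mentions
#' are retained (their canonical stays `NA`) and reported under canonical
#' `NA` so nothing is silently dropped.
#'
#' @param x an `aers_cases` object.
#' @param dict a [synonym_dictionary()].
#' @param max_distance passed to [match_drug()].
#' @return `x` with `canonical_drug` filled; the consolidation report
#'   (tibble: canonical, variant, method, n) is attached as attribute
#'   `consolidation`.
#' @export
annotate_cases <- function(x, dict = default_statin_dictionary(), max_distance = 1L) {
  stopifnot(inherits(x, "aers_cases"))
  lookup <- match_drug(unique(x$drugs$verbatim_name), dict, max_distance)
  x$drugs <- x$drugs |>
    dplyr::select(-"canonical_drug") |>
    dplyr::left_join(dplyr::select(lookup, verbatim_name = "raw",
                                   canonical_drug = "canonical_drug",
                                   match_method = "method"),
                     by = "verbatim_name")
  consolidation <- x$drugs |>
    dplyr::count(canonical = .data$canonical_drug,
                 variant = .data$verbatim_name,
                 method = .data$match_method, name = "n") |>
    dplyr::arrange(.data$canonical, dplyr::desc(.data$n))
  attr(x, "consolidation") <- consolidation
  x
}
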