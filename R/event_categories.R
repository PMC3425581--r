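#' Normalize a reaction term or category term
#'
#' Coded reaction terms are compared case-insensitively with collapsed
#' whitespace; this is the shared normal form used for both report reactions
#' and category term lists.
#'
#' @param x character vector of terms.
#' @return normalized character vector.
#' @export
normalize_term <- function(x) {
  stringr::str_squish(tolower(x))
}

#' Define an adverse-event category
#'
#' A category is a named set of reaction terms plus a match mode.
#' `EXACT_TERM` (the default) requires a report reaction to equal one of the
#' terms — appropriate because AERS reactions are coded preferred terms.
#' `SUBSTRING` counts a reaction that merely \emph{contains} a term, for
#' deliberately broad catch-all categories.
#'
#' @param name category name.
#' @param terms character vector of reaction terms (deduplicated, normalized).
#' @param match_mode `"EXACT_TERM"` or `"SUBSTRING"`.
#' @return an object of class `event_category`.
#' @export
event_category <- function(name, terms, match_mode = c("EXACT_TERM", "SUBSTRING")) {
  match_mode <- match.arg(match_mode)
  terms <- unique(normalize_term(terms))
  terms <- terms[terms != ""]
  if (length(terms) == 0L) {
    stop(sprintf("event category '%s' has no terms", name), call. = FALSE)
  }
  structure(list(name = name, terms = terms, match_mode = match_mode),
            class = "event_category")
}

#' @export
print.event_category <- function(x, ...) {
  cat(sprintf("<event_category> %s (%s): %s\n", x$name, x$match_mode,
              paste(x$terms, collapse = ", ")))
  invisible(x)
}

#' Load adverse-event category definitions from a CSV file
#'
#' Expected columns: `category`, `term`, and optionally `mode`
#' (`EXACT_TERM`/`SUBSTRING`; one mode per category). Duplicate terms within
#' a category collapse; an empty category is a configuration error.
#'
#' @param path CSV file path.
#' @return named list of [event_category()] objects, in file order.
#' @export
load_categories <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  stopifnot(all(c("category", "term") %in% names(df)))
  if (!"mode" %in% names(df)) df$mode <- "EXACT_TERM"
  df$mode[is.na(df$mode) | df$mode == ""] <- "EXACT_TERM"
  split_df <- split(df, factor(df$category, levels = unique(df$category)))
  cats <- lapply(split_df, function(d) {
    modes <- unique(d$mode)
    if (length(modes) > 1L) {
      stop(sprintf("category '%s' declares multiple match modes", d$category[1]),
           call. = FALSE)
    }
    event_category(d$category[1], d$term, modes)
  })
  names(cats) <- vapply(cats, `[[`, character(1), "name")
  cats
}

#' The packaged muscle/tendon adverse-event categories
#'
#' The four single-term muscle categories (myalgia, rhabdomyolysis,
#' myositis, myopathy) plus three deliberately broad grouped categories
#' (joints and tendons; muscle atrophy and injury; muscle coordination and
#' weakness). The broad term lists are editable defaults — category
#' definitions are study choices, not fixed vocabulary — so analyses should
#' load their own file via [load_categories()] when the defaults do not fit.
#'
#' @return named list of `event_category` objects.
#' @export
default_muscle_categories <- function() {
  load_categories(system.file("extdata", "statin_categories.csv",
                              package = "aersrank", mustWork = TRUE))
}

#' Does a set of reaction terms match a category?
#'
#' @param reactions character vector of (normalized) reaction terms from one
#'   report.
#' @param cat an [event_category()].
#' @return single logical: `TRUE` if at least one reaction matches. A report
#'   counts once per category no matter how many of its reactions match.
#' @export
case_matches <- function(reactions, cat) {
  stopifnot(inherits(cat, "event_category"))
  reactions <- normalize_term(reactions)
  if (cat$match_mode == "EXACT_TERM") {
    any(reactions %in% cat$terms)
  } else {
    any(vapply(reactions, function(r) {
      any(stringr::str_detect(r, stringr::fixed(cat$terms)))
    }, logical(1)))
  }
}

#' Flag every report against a category
#'
#' Vectorised form of [case_matches()] over an `aers_cases` object.
#'
#' @param x an `aers_cases` object.
#' @param cat an [event_category()].
#' @return character vector of ISR ids whose reports match the category.
#' @export
matching_isrs <- function(x, cat) {
  stopifnot(inherits(x, "aers_cases"), inherits(cat, "event_category"))
  r <- x$reactions
  if (cat$match_mode == "EXACT_TERM") {
    hit <- r$reaction %in% cat$terms
  } else {
    hit <- vapply(r$reaction, function(t) {
      any(stringr::str_detect(t, stringr::fixed(cat$terms)))
    }, logical(1), USE.NAMES = FALSE)
  }
  unique(r$isr_id[hit])
}
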