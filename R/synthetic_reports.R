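#' Configuration for the synthetic report generator
#'
#' Defines a ground-truth world the generator samples from: per-drug
#' prescribing weights, per-(drug, category) reporting rates, noise
#' processes (name corruption, follow-up versions, duplicate submissions)
#' and reporting demographics. Expected (drug, category) report counts are
#' proportional to `weight × rate`, mirroring how prescription volume and a
#' drug's true event rate jointly drive spontaneous report counts.
#'
#' @param drugs tibble with columns `drug` and `weight` (relative
#'   prescribing volume, arbitrary units).
#' @param rates tibble with columns `drug`, `category`, `rate`: reports per
#'   million prescribing-weight units. Categories must name entries of
#'   `categories`.
#' @param categories named list of [event_category()] objects; a signal
#'   report's reaction list contains one term drawn from its category.
#' @param background_rate per-drug rate for reports unrelated to any study
#'   category (their reactions come entirely from `background_terms`).
#' @param background_terms pool of non-category reaction terms.
#' @param n_reports number of base reports to draw (before follow-ups and
#'   duplicates are added on top).
#' @param duplicate_rate fraction of base reports that also receive an
#'   independent duplicate submission (new ISR and case key, cloned fields,
#'   receipt date shifted 0–7 days).
#' @param followup_rate fraction of base reports that receive a follow-up
#'   version (same case key, new ISR, later receipt date).
#' @param name_corruption list `(prob, max_edits)`: probability a drug name
#'   is emitted corrupted, and the maximum number of random character edits.
#'   Edits never touch the first 3 characters; with probability 1/2 a
#'   corruption is instead a dosage-suffix injection (e.g. `" 20 MG TAB"`),
#'   which name normalization is expected to undo.
#' @param secondary_rate probability a report carries a second, randomly
#'   chosen drug as secondary suspect.
#' @param reporter_mix named probability vector over reporter occupations
#'   (must sum to 1).
#' @param outcome_mix named per-outcome probabilities (non-exclusive; each
#'   outcome flagged independently).
#' @param date_range length-2 Date vector of receipt dates (uniform).
#' @param seed integer seed; the same config (including seed) always
#'   produces byte-identical files.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(drugs = default_sim_drugs(),
                              rates = default_sim_rates(),
                              categories = default_muscle_categories(),
                              background_rate = 40,
                              background_terms = default_background_terms(),
                              n_reports = 2000L,
                              duplicate_rate = 0.05,
                              followup_rate = 0.05,
                              name_corruption = list(prob = 0.2, max_edits = 1L),
                              secondary_rate = 0.1,
                              reporter_mix = c(PHYSICIAN = 0.35, PHARMACIST = 0.1,
                                               OTHER_HEALTH_PROFESSIONAL = 0.15,
                                               CONSUMER = 0.35, LAWYER = 0.02,
                                               UNKNOWN = 0.03),
                              outcome_mix = c(DEATH = 0.03, LIFE_THREATENING = 0.04,
                                              HOSPITALIZATION = 0.25, DISABILITY = 0.05,
                                              REQUIRED_INTERVENTION = 0.04, OTHER = 0.45),
                              date_range = as.Date(c("2005-07-01", "2011-03-31")),
                              seed = 1L) {
  fail <- function(field, why) {
    stop(sprintf("invalid simulation config: %s %s", field, why), call. = FALSE)
  }
  if (!is.data.frame(drugs) || !all(c("drug", "weight") %in% names(drugs)))
    fail("drugs", "needs columns drug, weight")
  if (any(drugs$weight <= 0)) fail("drugs$weight", "must be positive")
  if (!is.data.frame(rates) || !all(c("drug", "category", "rate") %in% names(rates)))
    fail("rates", "needs columns drug, category, rate")
  if (any(rates$rate < 0)) fail("rates$rate", "must be non-negative")
  if (!all(rates$category %in% names(categories)))
    fail("rates$category", "names a category not in `categories`")
  if (n_reports <= 0) fail("n_reports", "must be positive")
  for (nm in c("duplicate_rate", "followup_rate", "secondary_rate")) {
    v <- get(nm)
    if (v < 0 || v > 1) fail(nm, "must be in [0, 1]")
  }
  if (abs(sum(reporter_mix) - 1) > 1e-8) fail("reporter_mix", "must sum to 1")
  if (!all(names(reporter_mix) %in% aers_occupations()))
    fail("reporter_mix", "has unknown occupation names")
  if (any(outcome_mix < 0) || any(outcome_mix > 1))
    fail("outcome_mix", "probabilities must be in [0, 1]")
  if (!all(names(outcome_mix) %in% aers_outcomes()))
    fail("outcome_mix", "has unknown outcome names")
  if (background_rate < 0) fail("background_rate", "must be non-negative")
  if (length(background_terms) < 1) fail("background_terms", "must be non-empty")
  structure(list(drugs = tibble::as_tibble(drugs), rates = tibble::as_tibble(rates),
                 categories = categories, background_rate = background_rate,
                 background_terms = normalize_term(background_terms),
                 n_reports = as.integer(n_reports),
                 duplicate_rate = duplicate_rate, followup_rate = followup_rate,
                 name_corruption = name_corruption, secondary_rate = secondary_rate,
                 reporter_mix = reporter_mix, outcome_mix = outcome_mix,
                 date_range = as.Date(date_range), seed = as.integer(seed)),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_sim_drugs <- function() {
  tibble::tibble(
    drug = c("simvastatin", "atorvastatin", "rosuvastatin",
             "pravastatin", "lovastatin", "fluvastatin"),
    weight = c(122.4, 105.3, 35.5, 27.8, 26.3, 3.2)
  )
}

#' @rdname simulation_config
#' @export
default_sim_rates <- function() {
  # per-million-weight myalgia reporting rates echoing the high
  # (rosuvastatin, fluvastatin), intermediate (atorvastatin, simvastatin),
  # low (pravastatin, lovastatin) risk tiers the analysis is built to detect
  tidyr::crossing(
    tibble::tibble(drug = default_sim_drugs()$drug,
                   base = c(10, 30, 55, 11, 3, 38)),
    tibble::tibble(category = c("Myalgia", "Rhabdomyolysis", "Myopathy", "Myositis"),
                   mult = c(1, 0.35, 0.25, 0.1))
  ) |>
    dplyr::transmute(drug = .data$drug, category = .data$category,
                     rate = .data$base * .data$mult)
}

#' @rdname simulation_config
#' @export
default_background_terms <- function() {
  conditions <- c("nausea", "headache", "dizziness", "fatigue", "rash", "pruritus",
                  "vomiting", "diarrhoea", "constipation", "abdominal pain",
                  "dyspnoea", "cough", "insomnia", "anxiety", "depression",
                  "hypertension", "hypotension", "palpitations", "chest pain",
                  "oedema peripheral", "weight decreased", "weight increased",
                  "vision blurred", "tinnitus", "vertigo", "dry mouth", "dysgeusia",
                  "alopecia", "hyperhidrosis", "flushing", "asthenia", "malaise",
                  "pyrexia", "chills", "influenza", "nasopharyngitis", "back pain",
                  "paraesthesia", "hypoaesthesia", "tremor", "somnolence",
                  "memory impairment", "confusional state", "syncope", "fall",
                  "contusion", "epistaxis", "anaemia", "thrombocytopenia",
                  "hyperglycaemia", "hypoglycaemia", "hepatic enzyme increased",
                  "blood creatinine increased", "renal failure", "urinary retention",
                  "erectile dysfunction", "libido decreased", "hot flush",
                  "dry skin", "urticaria", "photosensitivity reaction",
                  "dyspepsia", "flatulence", "gastrooesophageal reflux disease",
                  "eructation", "dysphagia", "pancreatitis", "cholelithiasis",
                  "arthropathy", "bone pain", "neck pain", "sciatica",
                  "migraine", "sinusitis", "bronchitis", "pneumonia",
                  "urinary tract infection", "cystitis", "conjunctivitis",
                  "cataract", "glaucoma", "hearing impaired", "nightmare",
                  "irritability", "apathy", "restlessness", "drug ineffective",
                  "condition aggravated", "therapeutic response decreased")
  conditions
}

sample_prob <- function(n, names, probs) {
  names[sample.int(length(names), n, replace = TRUE, prob = probs)]
}

# random character edits (substitution/insertion/deletion), sparing the
# first `protect` characters so distance-1 fuzzy matching stays meaningful
corrupt_string <- function(s, n_edits, protect = 3L) {
  letters_pool <- letters
  for (i in seq_len(n_edits)) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    if (length(ch) <= protect) break
    pos <- sample.int(length(ch) - protect, 1L) + protect
    op <- sample(c("sub", "ins", "del"), 1L)
    ch <- switch(op,
      sub = { ch[pos] <- sample(setdiff(letters_pool, ch[pos]), 1L); ch },
      ins = append(ch, sample(letters_pool, 1L), after = pos),
      del = ch[-pos])
    s <- paste(ch, collapse = "")
  }
  s
}

dosage_suffixes <- c(" 10 MG", " 20 MG", " 40 MG TABLET", " 80 MG", " 10MG TAB",
                     " 20 MG CAPSULE", " 5 MG", " TABLET")

#' Generate synthetic AERS-style quarterly files with ground truth
#'
#' Draws `n_reports` base reports with (drug, category) frequencies
#' proportional to prescribing weight times category rate, layers on
#' follow-up versions and duplicate submissions, corrupts drug-name strings,
#' and writes the five dollar-delimited quarterly tables plus a truth table.
#' The same config (including its seed) always yields byte-identical files.
#'
#' Every report's reaction list carries at least one background term in
#' addition to any category term, plus `Poisson(1)` further background
#' terms — reports listing a single coded reaction are rare in spontaneous
#' reporting data, and the extra terms exercise the once-per-case counting
#' rule.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return list: `paths` (named vector of the five table files),
#'   `truth` (tibble: isr_id, case_id, drug, secondary_drug, category,
#'   emitted_name, corrupted, n_edits, is_followup_of, is_duplicate_of),
#'   `truth_path`.
#' @export
generate_reports <- function(config, dir = tempfile("aers_sim_")) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)

  grid <- dplyr::bind_rows(
    dplyr::inner_join(config$rates, config$drugs, by = "drug") |>
      dplyr::transmute(drug = .data$drug, category = .data$category,
                       w = .data$weight * .data$rate),
    config$drugs |>
      dplyr::transmute(drug = .data$drug, category = "background",
                       w = .data$weight * config$background_rate)
  ) |> dplyr::filter(.data$w > 0)
  pick <- sample.int(nrow(grid), config$n_reports, replace = TRUE, prob = grid$w)

  n <- config$n_reports
  days <- as.integer(config$date_range[2] - config$date_range[1])
  base <- tibble::tibble(
    isr_id = sprintf("ISR%07d", seq_len(n)),
    case_id = sprintf("CASE%07d", seq_len(n)),
    drug = grid$drug[pick],
    category = grid$category[pick],
    receipt_date = config$date_range[1] + sample.int(days + 1L, n, replace = TRUE) - 1L,
    age = sample(18:99, n, replace = TRUE),
    sex = sample(c("M", "F"), n, replace = TRUE),
    occupation = sample_prob(n, names(config$reporter_mix), config$reporter_mix)
  )

  # reactions: one category term for signal reports; >=1 background term +
  # Poisson(1) extras for every report
  base$signal_term <- NA_character_
  sig <- base$category != "background"
  base$signal_term[sig] <- vapply(base$category[sig], function(cn) {
    terms <- config$categories[[cn]]$terms
    terms[sample.int(length(terms), 1L)]
  }, character(1))
  base$bg_terms <- lapply(seq_len(n), function(i) {
    k <- 1L + stats::rpois(1L, 1)
    sample(config$background_terms, min(k, length(config$background_terms)))
  })

  # secondary suspect drug
  base$secondary_drug <- NA_character_
  has_sec <- stats::runif(n) < config$secondary_rate & nrow(config$drugs) > 1L
  base$secondary_drug[has_sec] <- vapply(base$drug[has_sec], function(d) {
    others <- setdiff(config$drugs$drug, d)
    others[sample.int(length(others), 1L)]
  }, character(1))

  emit_name <- function(drug_names) {
    out <- toupper(drug_names)
    edits <- integer(length(out))
    corrupt <- stats::runif(length(out)) < config$name_corruption$prob
    for (i in which(corrupt)) {
      if (stats::runif(1) < 0.5) {
        out[i] <- paste0(out[i], sample(dosage_suffixes, 1L))
      } else {
        k <- sample.int(max(1L, config$name_corruption$max_edits), 1L)
        out[i] <- toupper(corrupt_string(tolower(out[i]), k))
        edits[i] <- k
      }
    }
    list(name = out, n_edits = edits)
  }
  em <- emit_name(base$drug)
  base$emitted_name <- em$name
  base$n_edits <- em$n_edits
  base$emitted_secondary <- NA_character_
  if (any(has_sec)) {
    em2 <- emit_name(base$secondary_drug[has_sec])
    base$emitted_secondary[has_sec] <- em2$name
  }

  # outcomes, drawn independently per outcome type
  base$outcomes <- lapply(seq_len(n), function(i) {
    names(config$outcome_mix)[stats::runif(length(config$outcome_mix)) < config$outcome_mix]
  })

  base$is_followup_of <- NA_character_
  base$is_duplicate_of <- NA_character_

  # follow-up versions: same case, later date, same content
  fu_idx <- which(stats::runif(n) < config$followup_rate)
  followups <- base[fu_idx, , drop = FALSE]
  if (nrow(followups)) {
    followups$is_followup_of <- followups$isr_id
    followups$isr_id <- sprintf("ISR%07dF", fu_idx)
    followups$receipt_date <- followups$receipt_date +
      sample(30:180, nrow(followups), replace = TRUE)
  }

  # duplicate submissions: new ISR and case key, cloned fields, small date shift
  dup_idx <- which(stats::runif(n) < config$duplicate_rate)
  dups <- base[dup_idx, , drop = FALSE]
  if (nrow(dups)) {
    dups$is_duplicate_of <- dups$isr_id
    dups$isr_id <- sprintf("ISR%07dD", dup_idx)
    dups$case_id <- sprintf("CASE%07dD", dup_idx)
    dups$receipt_date <- dups$receipt_date + sample(0:7, nrow(dups), replace = TRUE)
  }

  reports <- dplyr::bind_rows(base, followups, dups)
  reports <- reports[order(reports$isr_id), , drop = FALSE]

  # ---- write the five tables -------------------------------------------
  j <- function(...) paste(..., sep = "$")
  demo_lines <- c(j("ISR", "CASE", "FDA_DT", "AGE", "AGE_COD", "GNDR_COD", "OCCP_COD"),
                  j(reports$isr_id, reports$case_id,
                    format(reports$receipt_date, "%Y%m%d"),
                    reports$age, "YR", reports$sex,
                    c(PHYSICIAN = "MD", PHARMACIST = "PH",
                      OTHER_HEALTH_PROFESSIONAL = "OT", CONSUMER = "CN",
                      LAWYER = "LW", UNKNOWN = "")[reports$occupation]))
  drug_rows <- dplyr::bind_rows(
    tibble::tibble(isr = reports$isr_id, seq = "1", role = "PS",
                   name = reports$emitted_name),
    tibble::tibble(isr = reports$isr_id, seq = "2", role = "SS",
                   name = reports$emitted_secondary) |>
      dplyr::filter(!is.na(.data$name))
  ) |> dplyr::arrange(.data$isr, .data$seq)
  drug_lines <- c(j("ISR", "DRUG_SEQ", "ROLE_COD", "DRUGNAME"),
                  j(drug_rows$isr, drug_rows$seq, drug_rows$role, drug_rows$name))
  reac_rows <- reports |>
    dplyr::mutate(terms = purrr::map2(.data$signal_term, .data$bg_terms,
                                      ~ c(.x[!is.na(.x)], .y))) |>
    dplyr::select("isr_id", "terms") |>
    tidyr::unnest("terms")
  reac_lines <- c(j("ISR", "PT"), j(reac_rows$isr_id, toupper(reac_rows$terms)))
  outc_rows <- reports |>
    dplyr::select("isr_id", "outcomes") |>
    tidyr::unnest("outcomes")
  outc_code <- c(DEATH = "DE", LIFE_THREATENING = "LT", HOSPITALIZATION = "HO",
                 DISABILITY = "DS", CONGENITAL_ANOMALY = "CA",
                 REQUIRED_INTERVENTION = "RI", OTHER = "OT")
  outc_lines <- c(j("ISR", "OUTC_COD"),
                  if (nrow(outc_rows)) j(outc_rows$isr_id, outc_code[outc_rows$outcomes]))
  rpsr_lines <- c(j("ISR", "RPSR_COD"),
                  j(reports$isr_id,
                    sample(c("HP", "CSM", "FGN", "LIT", "OTH"), nrow(reports),
                           replace = TRUE, prob = c(0.5, 0.3, 0.1, 0.05, 0.05))))

  paths <- c(DEMO = file.path(dir, "DEMO.txt"), DRUG = file.path(dir, "DRUG.txt"),
             REAC = file.path(dir, "REAC.txt"), OUTC = file.path(dir, "OUTC.txt"),
             RPSR = file.path(dir, "RPSR.txt"))
  writeLines(demo_lines, paths["DEMO"])
  writeLines(drug_lines, paths["DRUG"])
  writeLines(reac_lines, paths["REAC"])
  writeLines(outc_lines, paths["OUTC"])
  writeLines(rpsr_lines, paths["RPSR"])

  truth <- reports |>
    dplyr::transmute(
      isr_id = .data$isr_id, case_id = .data$case_id, drug = .data$drug,
      secondary_drug = .data$secondary_drug, category = .data$category,
      emitted_name = .data$emitted_name, corrupted = .data$n_edits > 0,
      n_edits = .data$n_edits, receipt_date = .data$receipt_date,
      is_followup_of = .data$is_followup_of,
      is_duplicate_of = .data$is_duplicate_of)
  truth_path <- file.path(dir, "truth.csv")
  readr::write_csv(truth, truth_path, na = "")
  list(paths = paths, truth = truth, truth_path = truth_path)
}

#' Compare pipeline output against generator ground truth
#'
#' Scores three recovery tasks as exact true/false-positive counts with
#' precision and recall:
#' \describe{
#'   \item{dedup}{dropped ISRs vs the injected follow-ups and duplicates.}
#'   \item{consolidation}{primary-suspect canonical drug vs the true drug.}
#'   \item{category}{matched categories vs the injected category label.}
#' }
#'
#' @param x the processed `aers_cases` (annotated + deduplicated; its
#'   `dedup_decisions` attribute supplies the drops).
#' @param truth the truth tibble from [generate_reports()].
#' @param categories the category list the pipeline used.
#' @return tibble: task, tp, fp, fn, precision, recall.
#' @export
truth_compare <- function(x, truth, categories) {
  stopifnot(inherits(x, "aers_cases"))
  if (!all(x$cases$isr_id %in% truth$isr_id)) {
    stop("pipeline output contains ISRs absent from the truth table; ",
         "outputs and truth must come from the same generate_reports() run",
         call. = FALSE)
  }
  score <- function(called, actual) {
    tp <- length(intersect(called, actual))
    fp <- length(setdiff(called, actual))
    fn <- length(setdiff(actual, called))
    tibble::tibble(tp = tp, fp = fp, fn = fn,
                   precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                   recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
  }
  decisions <- attr(x, "dedup_decisions") %||%
    tibble::tibble(dropped_isr = character())
  true_redundant <- truth$isr_id[!is.na(truth$is_duplicate_of) |
                                   !is.na(truth$is_followup_of)]
  # the surviving member of each duplicate/follow-up group is interchangeable:
  # count a group as recovered if the pipeline dropped one of its members
  dropped <- decisions$dropped_isr
  grp <- dplyr::coalesce(truth$is_duplicate_of, truth$is_followup_of, truth$isr_id)
  grp_of <- stats::setNames(grp, truth$isr_id)
  redundant_groups <- unique(grp_of[true_redundant])
  dropped_groups <- unique(grp_of[dropped])
  dedup <- score(dropped_groups, redundant_groups)

  prim <- x$drugs |> dplyr::filter(.data$role == "PRIMARY_SUSPECT")
  joined <- dplyr::inner_join(prim, truth, by = "isr_id")
  cons <- tibble::tibble(
    tp = sum(!is.na(joined$canonical_drug) & joined$canonical_drug == joined$drug),
    fp = sum(!is.na(joined$canonical_drug) & joined$canonical_drug != joined$drug),
    fn = sum(is.na(joined$canonical_drug)))
  cons$precision <- with(cons, if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  cons$recall <- with(cons, if (tp + fn > 0) tp / (tp + fn) else NA_real_)

  called_cat <- dplyr::bind_rows(lapply(names(categories), function(cn) {
    tibble::tibble(isr_id = matching_isrs(x, categories[[cn]]), category = cn)
  }))
  truth_cat <- truth |>
    dplyr::filter(.data$isr_id %in% x$cases$isr_id, .data$category != "background") |>
    dplyr::select("isr_id", "category")
  key <- function(d) paste(d$isr_id, d$category)
  cat_score <- score(key(called_cat), key(truth_cat))

  dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(task = "dedup"), dedup),
    dplyr::bind_cols(tibble::tibble(task = "consolidation"), cons),
    dplyr::bind_cols(tibble::tibble(task = "category"), cat_score)
  )
}
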