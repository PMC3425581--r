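# Independent oracles, deliberately naive: these re-derive expected results
# by brute force so the implementation is never checked against itself.

# Textbook dynamic-programming Levenshtein distance (unit costs).
oracle_levenshtein <- function(a, b) {
  a <- strsplit(a, "", fixed = TRUE)[[1]]
  b <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(a); n <- length(b)
  d <- matrix(0L, m + 1L, n + 1L)
  d[, 1L] <- 0:m
  d[1L, ] <- 0:n
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      cost <- if (a[i] == b[j]) 0L else 1L
      d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L,
                               d[i + 1L, j] + 1L,
                               d[i, j] + cost)
    }
  }
  d[m + 1L, n + 1L]
}

# Brute-force best match: all-pairs minimum distance over the dictionary.
oracle_best_match <- function(query, dict_df) {
  d <- vapply(dict_df$variant, oracle_levenshtein, integer(1), a = query)
  dmin <- min(d)
  cands <- unique(dict_df$canonical[d == dmin])
  list(distance = dmin, canonicals = cands)
}

# Brute-force survivor set for version dedup: per case_id keep the latest
# date, ties by largest isr_id.
oracle_dedup_versions <- function(cases_df) {
  out <- character(0)
  for (cid in unique(cases_df$case_id)) {
    g <- cases_df[cases_df$case_id == cid, , drop = FALSE]
    dk <- g$receipt_date
    dk[is.na(dk)] <- as.Date("0001-01-01")
    g <- g[dk == max(dk), , drop = FALSE]
    out <- c(out, max(g$isr_id))
  }
  sort(out)
}

# Random report fixture straight into an aers_cases object (bypasses files)
# for dedup oracle tests: n reports over n_groups case ids.
random_case_fixture <- function(n = 200, n_groups = 40, seed = 1) {
  set.seed(seed)
  case_id <- sprintf("C%03d", sample.int(n_groups, n, replace = TRUE))
  cases <- tibble::tibble(
    isr_id = sprintf("I%04d", sample.int(9999, n)),
    case_id = case_id,
    date_raw = "",
    receipt_date = as.Date("2006-01-01") + sample.int(1500, n, replace = TRUE),
    age = sample(30:90, n, replace = TRUE),
    sex = sample(c("M", "F", "UNK"), n, replace = TRUE, prob = c(.45, .45, .1)),
    reporter_occupation = "UNKNOWN"
  )
  drugs <- tibble::tibble(
    isr_id = cases$isr_id,
    verbatim_name = sample(c("ATORVASTATIN", "SIMVASTATIN"), n, replace = TRUE),
    canonical_drug = NA_character_,
    role = "PRIMARY_SUSPECT"
  )
  drugs$canonical_drug <- tolower(drugs$verbatim_name)
  reactions <- tibble::tibble(
    isr_id = cases$isr_id,
    reaction = sample(c("myalgia", "nausea", "headache"), n, replace = TRUE)
  )
  aersrank:::new_aers_cases(cases, drugs, reactions,
                            tibble::tibble(isr_id = character(),
                                           outcome = character()))
}

# Write a tiny quarter of dollar-delimited files from row strings.
write_fixture_quarter <- function(dir, demo = NULL, drug = NULL, reac = NULL,
                                  outc = NULL, rpsr = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  headers <- list(
    DEMO = "ISR$CASE$FDA_DT$AGE$AGE_COD$GNDR_COD$OCCP_COD",
    DRUG = "ISR$DRUG_SEQ$ROLE_COD$DRUGNAME",
    REAC = "ISR$PT", OUTC = "ISR$OUTC_COD", RPSR = "ISR$RPSR_COD")
  body <- list(DEMO = demo, DRUG = drug, REAC = reac, OUTC = outc, RPSR = rpsr)
  paths <- c()
  for (tn in names(body)) {
    if (is.null(body[[tn]])) next
    p <- file.path(dir, paste0(tn, ".txt"))
    writeLines(c(headers[[tn]], body[[tn]]), p)
    paths[tn] <- p
  }
  paths
}
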