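# Frozen published inputs for the worked example: myalgia counts and the
# six summed NRx totals (July 2005 - March 2011).
published_pr <- c(simvastatin = 1.0000, atorvastatin = 0.8604,
                  rosuvastatin = 0.2901, lovastatin = 0.2153,
                  pravastatin = 0.2275, fluvastatin = 0.0265)

test_that("prescribing ratios reproduce the published values to 4 decimals", {
  pr <- prescribing_ratios(statin_nrx())
  expect_equal(stats::setNames(pr$pr, pr$drug), published_pr[pr$drug])
  expect_equal(sum(pr$pr == 1), 1L)
  expect_true(all(pr$pr > 0 & pr$pr <= 1))
})

test_that("prescribing ratios handle degenerate inputs per contract", {
  expect_equal(prescribing_ratios(c(a = 5))$pr, 1)
  two <- prescribing_ratios(c(a = 7, b = 7))
  expect_equal(two$pr, c(1, 1))
  expect_error(prescribing_ratios(numeric(0)), "empty")
  expect_error(prescribing_ratios(c(a = 0, b = 1)), "positive")
})

test_that("normalized rates match the published table cells", {
  expect_equal(round_half_up(normalized_rate(2751, 0.8604)), 3197)
  expect_equal(round_half_up(normalized_rate(103, 0.0265)), 3887)
  expect_equal(normalized_rate(42, 1.0), 42)
  expect_error(normalized_rate(10, 0), "positive")
})

test_that("ranked risk rescales to the max and matches published integers", {
  counts <- c(rosuvastatin = 1641, fluvastatin = 103, atorvastatin = 2751,
              pravastatin = 257, simvastatin = 1003, lovastatin = 67)
  rates <- normalized_rate(counts, published_pr[names(counts)])
  rr <- ranked_risk(rates)
  expect_equal(rr[["rosuvastatin"]], 100L)
  expect_equal(rr[["atorvastatin"]], 57L)
  expect_equal(rr[["fluvastatin"]], 69L)
  expect_equal(rr[["pravastatin"]], 20L)
  expect_equal(rr[["simvastatin"]], 18L)
  # 5.50 rounding boundary: half-up gives 6 (published value is 5)
  expect_true(rr[["lovastatin"]] %in% c(5L, 6L))

  expect_equal(unname(ranked_risk(c(a = 3))), 100L)
  expect_equal(ranked_risk(rates * 2), rr)   # scale invariance
  expect_warning(z <- ranked_risk(c(a = 0, b = 0)), "zero")
  expect_equal(unname(z), c(0L, 0L))
})

test_that("ranked-risk ordering equals normalized-rate ordering", {
  set.seed(31)
  for (i in 1:20) {
    rates <- stats::setNames(stats::runif(6, 0, 5000), letters[1:6])
    rr <- ranked_risk(rates)
    expect_equal(order(-rr, names(rr)), order(-rates, names(rr)))
  }
})

test_that("scale invariance: rescaling NRx changes no ratio or ranked risk", {
  nrx <- statin_nrx()
  pr1 <- prescribing_ratios(nrx)
  pr2 <- prescribing_ratios(nrx * 7)
  expect_equal(pr1$pr, pr2$pr)
})

test_that("count_reports applies role scoping and counts each case once", {
  x <- random_case_fixture(n = 3, n_groups = 3, seed = 2)
  x$drugs <- tibble::tibble(
    isr_id = x$cases$isr_id,
    verbatim_name = "X",
    canonical_drug = "atorvastatin",
    role = c("PRIMARY_SUSPECT", "SECONDARY_SUSPECT", "CONCOMITANT"))
  x$reactions <- tibble::tibble(isr_id = rep(x$cases$isr_id, each = 2),
                                reaction = rep(c("myalgia", "myalgia"), 3))
  cat <- event_category("Myalgia", "myalgia")
  expect_equal(count_reports(x, "atorvastatin", cat, "PRIMARY"), 1L)
  expect_equal(count_reports(x, "atorvastatin", cat, "ALL_SUSPECT"), 2L)
  expect_equal(count_reports(x, "atorvastatin", cat, "ALL_SUSPECT",
                             include_concomitant = TRUE), 3L)
  expect_warning(n <- count_reports(x, "nosuchdrug", cat, "PRIMARY"), "not present")
  expect_equal(n, 0L)
})

test_that("counts match a brute-force filter oracle on synthetic reports", {
  cfg <- simulation_config(n_reports = 600, duplicate_rate = 0, followup_rate = 0,
                           name_corruption = list(prob = 0, max_edits = 0L),
                           seed = 41)
  gen <- generate_reports(cfg, withr::local_tempdir())
  x <- annotate_cases(assemble_cases(read_quarter(gen$paths)))
  cats <- default_muscle_categories()
  tr <- gen$truth
  for (d in c("rosuvastatin", "simvastatin")) {
    for (cn in c("Myalgia", "Rhabdomyolysis")) {
      expect_equal(count_reports(x, d, cats[[cn]], "PRIMARY"),
                   sum(tr$drug == d & tr$category == cn))
      expect_equal(count_reports(x, d, cats[[cn]], "ALL_SUSPECT"),
                   sum((tr$drug == d | (!is.na(tr$secondary_drug) & tr$secondary_drug == d)) &
                         tr$category == cn))
    }
  }
  # all-suspect counts dominate primary counts everywhere
  for (d in unique(tr$drug)) {
    for (cn in names(cats)) {
      expect_gte(count_reports(x, d, cats[[cn]], "ALL_SUSPECT"),
                 count_reports(x, d, cats[[cn]], "PRIMARY"))
    }
  }
})

test_that("risk_table assembles published counts into the published table", {
  pr <- prescribing_ratios(statin_nrx())
  cts <- statin_myalgia_counts()
  cts <- cts[match(pr$drug, cts$drug), ]
  rt <- build_risk_table("Myalgia", pr$drug, cts$primary_count, cts$all_count, pr$pr)
  published <- tibble::tribble(
    ~drug,          ~primary_rate, ~all_rate, ~ranked_primary, ~ranked_all,
    "rosuvastatin", 5657,          6959,      100,             100,
    "fluvastatin",  3887,          6943,      69,              100,
    "atorvastatin", 3197,          4262,      57,              61,
    "pravastatin",  1130,          2378,      20,              34,
    "simvastatin",  1003,          1827,      18,              26,
    "lovastatin",   311,           878,       5,               13)
  m <- merge(rt, published, by = "drug", suffixes = c("", ".pub"))
  expect_true(all(abs(m$primary_rate - m$primary_rate.pub) <= 1))
  expect_true(all(abs(m$all_rate - m$all_rate.pub) <= 1))
  expect_true(all(abs(m$ranked_primary - m$ranked_primary.pub) <= 1))
  expect_true(all(abs(m$ranked_all - m$ranked_all.pub) <= 1))
  expect_error(build_risk_table("X", "a", 5, 3, 1), "inconsistent")
})

test_that("combined risk reduces to ranked risk for one category and is additive", {
  cfg <- simulation_config(n_reports = 600, duplicate_rate = 0, followup_rate = 0,
                           name_corruption = list(prob = 0, max_edits = 0L),
                           seed = 53)
  gen <- generate_reports(cfg, withr::local_tempdir())
  x <- annotate_cases(assemble_cases(read_quarter(gen$paths)))
  cats <- default_muscle_categories()
  pr <- prescribing_ratios(with(default_sim_drugs(), stats::setNames(weight, drug)))

  one <- combined_risk(x, cats["Myalgia"], pr, "PRIMARY")
  rt <- risk_table(x, cats$Myalgia, pr)
  m <- merge(one, rt, by = "drug")
  expect_true(all(abs(round_half_up(m$percent_of_max) - m$ranked_primary) <= 1))

  # per-category-sum counting: combined count = sum of per-category counts
  two <- combined_risk(x, cats[c("Myalgia", "Rhabdomyolysis")], pr, "PRIMARY")
  for (d in two$drug) {
    expect_equal(two$combined_count[two$drug == d],
                 count_reports(x, d, cats$Myalgia, "PRIMARY") +
                   count_reports(x, d, cats$Rhabdomyolysis, "PRIMARY"))
  }
  # unique-case mode never exceeds the per-category sum
  uniq <- combined_risk(x, cats[c("Myalgia", "Rhabdomyolysis")], pr, "PRIMARY",
                        counting = "unique_case")
  expect_true(all(uniq$combined_count <= two$combined_count[match(uniq$drug, two$drug)]))
})

test_that("combined risk recovers configured 4:2:1 rate ratios at equal weights", {
  drugs <- tibble::tibble(drug = c("a", "b", "c"), weight = c(1, 1, 1))
  rates <- tibble::tibble(drug = c("a", "b", "c"),
                          category = "Myalgia", rate = c(40, 20, 10))
  cats <- list(Myalgia = event_category("Myalgia", "myalgia"))
  pr <- prescribing_ratios(c(a = 1, b = 1, c = 1))
  pcts <- sapply(1:5, function(seed) {
    cfg <- simulation_config(drugs = drugs, rates = rates, categories = cats,
                             background_rate = 10, n_reports = 2000,
                             duplicate_rate = 0, followup_rate = 0,
                             name_corruption = list(prob = 0, max_edits = 0L),
                             secondary_rate = 0, seed = seed)
    gen <- generate_reports(cfg, withr::local_tempdir())
    dict <- synonym_dictionary(entries = data.frame(canonical = c("a", "b", "c"),
                                                    variant = c("a", "b", "c")))
    x <- annotate_cases(assemble_cases(read_quarter(gen$paths)), dict)
    cr <- combined_risk(x, cats, pr, "PRIMARY")
    cr$percent_of_max[match(c("a", "b", "c"), cr$drug)]
  })
  means <- unname(rowMeans(pcts))
  expect_equal(means[1], 100)
  expect_lt(abs(means[2] - 50), 5)
  expect_lt(abs(means[3] - 25), 5)
})

test_that("yearly trend partitions the primary count by receipt year", {
  cfg <- simulation_config(n_reports = 400, duplicate_rate = 0, followup_rate = 0,
                           name_corruption = list(prob = 0, max_edits = 0L),
                           seed = 61)
  gen <- generate_reports(cfg, withr::local_tempdir())
  x <- annotate_cases(assemble_cases(read_quarter(gen$paths)))
  cats <- default_muscle_categories()
  for (d in c("simvastatin", "rosuvastatin")) {
    yt <- yearly_trend(x, d, cats$Myalgia)
    expect_equal(sum(yt$n), count_reports(x, d, cats$Myalgia, "PRIMARY"))
  }
  # undated reports land in an UNKNOWN bucket
  x2 <- x
  x2$cases$receipt_date[1:5] <- as.Date(NA)
  yt2 <- yearly_trend(x2, "simvastatin", cats$Myalgia)
  expect_equal(sum(yt2$n), count_reports(x2, "simvastatin", cats$Myalgia, "PRIMARY"))
})

test_that("outcome strata are non-exclusive, reporter strata partition with percents", {
  x <- random_case_fixture(n = 1, n_groups = 1, seed = 5)
  x$drugs$canonical_drug <- "atorvastatin"
  x$drugs$role <- "PRIMARY_SUSPECT"
  x$reactions$reaction <- "myalgia"
  x$outcomes <- tibble::tibble(isr_id = rep(x$cases$isr_id, 2),
                               outcome = c("DEATH", "HOSPITALIZATION"))
  cat <- event_category("Myalgia", "myalgia")
  so <- stratify(x, "atorvastatin", cat, "OUTCOME")
  expect_setequal(so$stratum, c("DEATH", "HOSPITALIZATION"))
  expect_equal(so$n, c(1L, 1L))

  cfg <- simulation_config(n_reports = 800, duplicate_rate = 0, followup_rate = 0,
                           name_corruption = list(prob = 0, max_edits = 0L),
                           reporter_mix = c(PHYSICIAN = 0.7, CONSUMER = 0.3),
                           seed = 71)
  gen <- generate_reports(cfg, withr::local_tempdir())
  y <- annotate_cases(assemble_cases(read_quarter(gen$paths)))
  sr <- stratify(y, "simvastatin", cat, "REPORTER")
  expect_equal(sum(sr$percent), 100, tolerance = 0.011)
  expect_equal(sum(sr$n), count_reports(y, "simvastatin", cat, "PRIMARY"))
  # 70/30 mix recovered within sampling error across all reports
  all_sr <- dplyr::bind_rows(lapply(default_sim_drugs()$drug, function(d)
    stratify(y, d, cat, "REPORTER")))
  tot <- tapply(all_sr$n, all_sr$stratum, sum)
  p_hat <- tot[["PHYSICIAN"]] / sum(tot)
  expect_lt(abs(p_hat - 0.7), 4 * sqrt(0.7 * 0.3 / sum(tot)))
})

test_that("peak-prescription sensitivity analysis follows the same pipeline", {
  cfg <- simulation_config(n_reports = 400, duplicate_rate = 0, followup_rate = 0,
                           name_corruption = list(prob = 0, max_edits = 0L),
                           seed = 83)
  gen <- generate_reports(cfg, withr::local_tempdir())
  x <- annotate_cases(assemble_cases(read_quarter(gen$paths)))
  cat <- default_muscle_categories()$Myalgia
  drugs <- default_sim_drugs()
  # yearly table whose maxima are proportional to the summed weights
  nrx_by_year <- tidyr::crossing(drug = drugs$drug, year = 2005:2010) |>
    dplyr::left_join(drugs, by = "drug") |>
    dplyr::mutate(nrx = .data$weight * ifelse(.data$year == 2008, 1000, 500))
  sens <- sensitivity_peak_rx(nrx_by_year, x, cat)
  main <- risk_table(x, cat, prescribing_ratios(stats::setNames(drugs$weight, drugs$drug)))
  m <- merge(sens, main, by = "drug")
  expect_equal(m$ranked_primary.x, m$ranked_primary.y)
  expect_equal(unique(sens$variant), "peak_rx")

  # doubling one drug's peak denominator halves its rate
  nrx2 <- dplyr::mutate(nrx_by_year,
                        nrx = ifelse(.data$drug == "rosuvastatin", .data$nrx * 2, .data$nrx))
  sens2 <- sensitivity_peak_rx(nrx2, x, cat)
  r1 <- sens$primary_count[sens$drug == "rosuvastatin"] /
    sens$pr[sens$drug == "rosuvastatin"]
  r2 <- sens2$primary_count[sens2$drug == "rosuvastatin"] /
    sens2$pr[sens2$drug == "rosuvastatin"]
  expect_equal(r2 / r1, 0.5, tolerance = 0.001)
})
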