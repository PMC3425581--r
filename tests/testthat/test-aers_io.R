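test_that("read_quarter yields one raw row per well-formed data line", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_quarter(
    dir,
    drug = c("I1$1$PS$LIPITOR", "I2$1$SS$ZOCOR", "I3$1$C$ASPIRIN"),
    reac = c("I1$MYALGIA", "I2$NAUSEA")
  )
  raw <- read_quarter(paths)
  expect_equal(unname(raw$n_rows[["DRUG"]]), 3L)
  expect_equal(unname(raw$n_rows[["REAC"]]), 2L)
  expect_equal(nrow(raw$rejects), 0L)
  # raw strings preserved exactly
  expect_equal(raw$tables$DRUG$DRUGNAME, c("LIPITOR", "ZOCOR", "ASPIRIN"))
})

test_that("header-only files read as empty tables and missing files are fatal", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_quarter(dir, drug = character(0), reac = character(0))
  raw <- read_quarter(paths)
  expect_equal(unname(raw$n_rows), c(0L, 0L))
  expect_equal(nrow(raw$rejects), 0L)
  expect_error(read_quarter(c(DRUG = file.path(dir, "nope.txt"))), "DRUG")
})

test_that("malformed lines are skipped and logged with their line numbers", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_quarter(
    dir,
    drug = c("I1$1$PS$LIPITOR",
             "I2$1$PS",            # one field short -> reject (file line 3)
             "I3$1$PS$ZOCOR")
  )
  raw <- read_quarter(paths)
  expect_equal(unname(raw$n_rows[["DRUG"]]), 2L)
  expect_equal(raw$rejects$line, 3L)
  expect_match(raw$rejects$reason, "expected 4 fields, got 3")
})

test_that("header mismatch is a fatal, named error", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "DRUG.txt")
  writeLines(c("ISR$ROLE_COD$DRUGNAME", "I1$PS$LIPITOR"), p)
  expect_error(read_quarter(c(DRUG = p)), "DRUG header mismatch")
})

test_that("assemble_cases joins tables on ISR and excludes one-sided reports", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_quarter(
    dir,
    demo = c("I1$C1$20070315$63$YR$F$MD", "I2$C2$20080101$55$YR$M$CN"),
    drug = c("I1$1$PS$LIPITOR", "I2$1$SS$ZOCOR", "I4$1$PS$MEVACOR"),
    reac = c("I1$MYALGIA", "I1$NAUSEA", "I2$RHABDOMYOLYSIS", "I3$HEADACHE"),
    outc = c("I1$DE", "I1$HO", "I1$HO")
  )
  cases <- assemble_cases(read_quarter(paths))
  expect_equal(n_cases(cases), 2L)
  expect_setequal(cases$cases$isr_id, c("I1", "I2"))
  # I3 has reactions only, I4 drugs only
  excl <- attr(cases, "exclusions")
  expect_setequal(excl$isr_id, c("I3", "I4"))
  expect_setequal(excl$reason, c("NO_DRUGS", "NO_REACTIONS"))
  # demographics parsed
  i1 <- cases$cases[cases$cases$isr_id == "I1", ]
  expect_equal(i1$receipt_date, as.Date("2007-03-15"))
  expect_equal(i1$age, 63)
  expect_equal(i1$sex, "F")
  expect_equal(i1$reporter_occupation, "PHYSICIAN")
  # outcomes deduplicated per report
  expect_setequal(cases$outcomes$outcome[cases$outcomes$isr_id == "I1"],
                  c("DEATH", "HOSPITALIZATION"))
})

test_that("DEMO-less reports get unknown demographics, odd codes warn", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_quarter(
    dir,
    drug = c("I9$1$PS$LIPITOR"),
    reac = c("I9$MYALGIA"),
    outc = c("I9$ZZ")
  )
  expect_warning(cases <- assemble_cases(read_quarter(paths)), "unknown outcome")
  row <- cases$cases[1, ]
  expect_equal(row$sex, "UNK")
  expect_equal(row$reporter_occupation, "UNKNOWN")
  expect_true(is.na(row$receipt_date))
  expect_equal(row$case_id, "I9")  # falls back to the report key
  expect_equal(cases$outcomes$outcome, "OTHER")
})

test_that("assembly matches a hand join on a randomized multi-table fixture", {
  set.seed(7)
  dir <- withr::local_tempdir()
  isrs <- sprintf("I%02d", 1:10)
  has_demo <- runif(10) < 0.7
  has_drug <- runif(10) < 0.7
  has_reac <- runif(10) < 0.7
  paths <- write_fixture_quarter(
    dir,
    demo = sprintf("%s$C%s$20080101$60$YR$M$MD", isrs[has_demo], isrs[has_demo]),
    drug = sprintf("%s$1$PS$LIPITOR", isrs[has_drug]),
    reac = sprintf("%s$MYALGIA", isrs[has_reac])
  )
  cases <- assemble_cases(read_quarter(paths))
  expect_setequal(cases$cases$isr_id, isrs[has_drug & has_reac])
  expect_equal(nrow(attr(cases, "exclusions")), sum(xor(has_drug, has_reac)))
})

test_that("assemble_cases is invariant to input row order", {
  dir <- withr::local_tempdir()
  drug_rows <- sprintf("I%d$1$PS$LIPITOR", 1:6)
  reac_rows <- sprintf("I%d$MYALGIA", 1:6)
  p1 <- write_fixture_quarter(file.path(dir, "a"), drug = drug_rows, reac = reac_rows)
  p2 <- write_fixture_quarter(file.path(dir, "b"), drug = rev(drug_rows),
                              reac = sample(reac_rows))
  c1 <- assemble_cases(read_quarter(p1))
  c2 <- assemble_cases(read_quarter(p2))
  expect_equal(c1$cases, c2$cases)
  expect_equal(c1$drugs, c2$drugs)
  expect_equal(c1$reactions, c2$reactions)
})

test_that("date window keeps in-window and undated reports, drops the rest", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_quarter(
    dir,
    demo = c("I1$C1$20040101$60$YR$M$MD",   # before window
             "I2$C2$20070601$60$YR$M$MD",   # inside
             "I3$C3$NOTADATE$60$YR$M$MD"),  # unparseable -> kept, flagged
    drug = sprintf("I%d$1$PS$LIPITOR", 1:3),
    reac = sprintf("I%d$MYALGIA", 1:3)
  )
  cases <- filter_date_window(assemble_cases(read_quarter(paths)))
  expect_setequal(cases$cases$isr_id, c("I2", "I3"))
  expect_equal(attr(cases, "undated"), "I3")
})

test_that("result tables round-trip through CSV", {
  dir <- withr::local_tempdir()
  pr <- prescribing_ratios(statin_nrx())
  path <- file.path(dir, "pr.csv")
  write_result_table(pr, path)
  back <- read_result_table(path)
  expect_equal(as.data.frame(back), as.data.frame(pr))
  # empty table -> header-only file
  empty <- pr[0, ]
  write_result_table(empty, path)
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(read_result_table(path)), 0L)
})

test_that("row conservation holds: read = assembled + excluded + rejected", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_quarter(
    dir,
    drug = c("I1$1$PS$LIPITOR", "I2$1$PS$ZOCOR", "badline", "I3$1$PS$MEVACOR"),
    reac = c("I1$MYALGIA", "I2$NAUSEA")
  )
  raw <- read_quarter(paths)
  cases <- assemble_cases(raw)
  n_drug_lines <- 4L
  expect_equal(n_drug_lines,
               sum(raw$tables$DRUG$ISR %in% cases$cases$isr_id) +
                 sum(raw$tables$DRUG$ISR %in% attr(cases, "exclusions")$isr_id) +
                 nrow(raw$rejects))
})
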