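test_that("a minimal hand fixture parses into one joined record", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "primaryid$caseid$caseversion$fda_dt$event_dt$age$age_cod$wt$wt_cod$sex$occp_cod$reporter_country",
    "101$10$1$20200315$20200301$28$YR$55$KG$F$MD$US"),
    file.path(dir, "DEMO20Q1.txt"))
  writeLines(c(
    "primaryid$caseid$drug_seq$role_cod$drugname",
    "101$10$1$PS$ADALIMUMAB",
    "101$10$2$C$IBUPROFEN"),
    file.path(dir, "DRUG20Q1.txt"))
  writeLines(c(
    "primaryid$caseid$pt",
    "101$10$ABORTION SPONTANEOUS"),
    file.path(dir, "REAC20Q1.txt"))
  writeLines(c(
    "primaryid$caseid$dsg_drug_seq$start_dt",
    "101$10$1$20190601"),
    file.path(dir, "THER20Q1.txt"))
  rec <- parse_quarter(dir)
  expect_equal(nrow(rec$demo), 1)
  expect_equal(nrow(rec$drug), 2)
  expect_equal(nrow(rec$reac), 1)
  expect_equal(rec$drug[drug_seq == 1, start_dt], "20190601")
  expect_equal(rec$drug[drug_seq == 2, start_dt], "")
  expect_equal(rec$demo$age, 28)
})

test_that("missing mandatory columns and orphan rows are handled per contract", {
  dir <- withr::local_tempdir()
  writeLines(c("caseid$fda_dt", "10$20200315"), file.path(dir, "DEMO.txt"))
  writeLines(c("primaryid$caseid$drug_seq$role_cod$drugname",
               "101$10$1$PS$X"), file.path(dir, "DRUG.txt"))
  expect_error(suppressWarnings(parse_quarter(dir)), "primaryid")

  dir2 <- withr::local_tempdir()
  writeLines(c(
    "primaryid$caseid$caseversion$fda_dt",
    "101$10$1$20200315"), file.path(dir2, "DEMO.txt"))
  writeLines(c("primaryid$caseid$drug_seq$role_cod$drugname",
               "101$10$1$PS$X",
               "999$99$1$PS$Y"), file.path(dir2, "DRUG.txt"))
  rec <- suppressWarnings(parse_quarter(dir2))
  expect_equal(nrow(rec$drug), 1)
  expect_equal(unname(attr(rec, "skipped")["drug"]), 1)
})

test_that("a DEMO row with no DRUG rows is kept and counted as drugless", {
  dir <- withr::local_tempdir()
  writeLines(c(
    "primaryid$caseid$caseversion$fda_dt",
    "101$10$1$20200315",
    "102$11$1$20200316"), file.path(dir, "DEMO.txt"))
  writeLines(c("primaryid$caseid$drug_seq$role_cod$drugname",
               "101$10$1$PS$X"), file.path(dir, "DRUG.txt"))
  rec <- suppressWarnings(parse_quarter(dir))
  expect_equal(nrow(rec$demo), 2)
  expect_equal(attr(rec, "n_drugless"), 1)
})

test_that("deduplication applies the four version-selection rules in order", {
  # rule 2: highest case version wins regardless of receipt date
  s <- hand_icsr(list(
    list(primaryid = "1-1", caseid = "1", caseversion = 1L,
         fda_dt = as.IDate("2020-06-01")),
    list(primaryid = "1-2", caseid = "1", caseversion = 2L,
         fda_dt = as.IDate("2020-01-01"))))
  expect_equal(deduplicate(s)$demo$primaryid, "1-2")

  # rule 3: same version, most recent FDA_DT wins
  s <- hand_icsr(list(
    list(primaryid = "1-1", caseid = "1", fda_dt = as.IDate("2020-01-01")),
    list(primaryid = "1-2", caseid = "1", fda_dt = as.IDate("2020-06-01"))))
  expect_equal(deduplicate(s)$demo$primaryid, "1-2")

  # rule 4: identical version + date, fewer missing fields wins
  s <- hand_icsr(list(
    list(primaryid = "1-1", caseid = "1", wt = NA_real_),
    list(primaryid = "1-2", caseid = "1")))
  expect_equal(deduplicate(s)$demo$primaryid, "1-2")
  s <- hand_icsr(list(
    list(primaryid = "1-1", caseid = "1"),
    list(primaryid = "1-2", caseid = "1", wt = NA_real_)))
  expect_equal(deduplicate(s)$demo$primaryid, "1-1")

  # full tie: last in input order wins (deterministic)
  s <- hand_icsr(list(
    list(primaryid = "1-1", caseid = "1"),
    list(primaryid = "1-2", caseid = "1")))
  expect_equal(deduplicate(s)$demo$primaryid, "1-2")

  # rule 1: unrelated CASEIDs untouched; single record identity
  s <- hand_icsr(list(
    list(primaryid = "1-1", caseid = "1"),
    list(primaryid = "2-1", caseid = "2")))
  expect_equal(sort(deduplicate(s)$demo$caseid), c("1", "2"))
})

test_that("deduplication is idempotent and drops linked rows", {
  g <- generate_cohort(small_config(n = 10000, duplicate_rate = 0.2, seed = 2))
  d1 <- deduplicate(g$cohort)
  d2 <- deduplicate(d1)
  expect_equal(d1$demo, d2$demo)
  expect_equal(d1$drug, d2$drug)
  expect_true(all(d1$drug$primaryid %in% d1$demo$primaryid))
  expect_true(all(d1$reac$primaryid %in% d1$demo$primaryid))
  # obsolete-case exclusion: supplied CASEIDs vanish entirely
  drop <- d1$demo$caseid[1:5]
  d3 <- deduplicate(g$cohort, drop_caseids = drop)
  expect_false(any(drop %in% d3$demo$caseid))
})

test_that("cohort filter applies role, occupation and exclusion rules", {
  mk <- function(role, drugname = "ADALIMUMAB", occ = "MD",
                 pt = "ABORTION SPONTANEOUS") {
    hand_icsr(
      list(list(primaryid = "1-1", caseid = "1", occp_cod = occ)),
      list(data.table(primaryid = "1-1", caseid = "1", drug_seq = 1L,
                      role_cod = role, drugname = drugname,
                      start_dt = "20190101")),
      list(data.table(primaryid = "1-1", caseid = "1", pt = pt)))
  }
  # only-concomitant record excluded from the background
  expect_error(filter_cohort(mk("C")), "empty background")
  # PS levonorgestrel excluded under the progestogen list
  expect_error(filter_cohort(mk("PS", "LEVONORGESTREL")), "empty background")
  # lawyer reports dropped by the default occupation filter
  expect_error(filter_cohort(mk("PS", occ = "LW")), "empty background")
  # PS adalimumab + target PT lands in cases
  co <- filter_cohort(mk("PS"))
  expect_equal(nrow(co$demo), 1)
  expect_true(co$demo$is_case)
  # occupation filter is configurable
  co2 <- filter_cohort(mk("PS", occ = "LW"),
                       cohort_filter(occupations_kept = c("MD", "LW")))
  expect_equal(nrow(co2$demo), 1)
})

test_that("case/non-case partition is exact and funnel is monotone", {
  g <- generate_cohort(small_config(n = 20000, seed = 4))
  co <- filter_cohort(deduplicate(g$cohort))
  f <- attr(co, "funnel")
  expect_equal(sum(co$demo$is_case) + sum(!co$demo$is_case), nrow(co$demo))
  expect_true(all(diff(c(f["n_input"], f["n_window"], f["n_occupation"],
                         f["n_background"])) <= 0))
  expect_equal(unname(f["n_cases"]), sum(co$demo$is_case))
})

test_that("miscarriage PT matching is exact, trimmed and case-folded", {
  expect_true(match_miscarriage("Abortion spontaneous"))
  expect_true(match_miscarriage("  ABORTION  "))
  expect_false(match_miscarriage("ABORTION INDUCED"))
  expect_false(match_miscarriage("SPONTANEOUS ABORTION LIKE EVENT"))
  expect_false(match_miscarriage(character(0)))
  expect_true(match_miscarriage(c("HEADACHE", "abortion")))
})

test_that("age and weight unit conversions follow FAERS code conventions", {
  expect_equal(age_years(c(3, 24, 30, 7300.5), c("DEC", "MON", "YR", "DY")),
               c(30, 2, 30, 7300.5 / 365.25))
  expect_true(is.na(age_years(200, "YR")))
  expect_equal(weight_kg(c(100, 70), c("LBS", "KG")), c(45.3592, 70))
  expect_true(is.na(weight_kg(0, "KG")))
  expect_true(is.na(weight_kg(700, "KG")))
})

test_that("demographic summary uses known-value denominators and half-up rounding", {
  demo <- data.table(
    age = c(30, 30, 40, NA), age_cod = c("YR", "YR", "YR", ""),
    wt = c(60, 80, NA, NA), wt_cod = c("KG", "KG", "", ""),
    occp_cod = c("MD", "CN", NA, "MD"),
    reporter_country = c("US", "US", "DE", NA))
  s <- summarize_demographics(demo)
  age <- s$categorical[variable == "age"]
  expect_equal(age[level == "<35 years", n], 2L)
  expect_equal(age[level == "<35 years", pct], 66.67)
  expect_equal(age[level == ">=35 years", pct], 33.33)
  expect_equal(age[level == "missing", n], 1L)
  # percentages over known strata sum to 100 (within rounding)
  for (v in c("age", "weight", "occupation", "country")) {
    known <- s$categorical[variable == v & level != "missing" & !is.na(pct)]
    expect_lt(abs(sum(known$pct) - 100), 0.011)
  }
  expect_equal(s$continuous[variable == "age", median], 30)
})

test_that("a variable with all values missing yields undefined percentages", {
  demo <- data.table(age = rep(NA_real_, 4), age_cod = "",
                     wt = rep(NA_real_, 4), wt_cod = "",
                     occp_cod = "MD", reporter_country = "US")
  s <- summarize_demographics(demo)
  wt <- s$categorical[variable == "weight"]
  expect_true(all(is.na(wt[level != "missing", pct])))
  expect_equal(wt[level == "missing", n], 4L)
})

test_that("country aggregation sums counts into regions", {
  counts <- c(US = 100, CA = 50, DE = 30, FR = 20, JP = 10)
  agg <- aggregate_countries(counts)
  expect_equal(agg[region == "us_canada", n], 150)
  expect_equal(agg[region == "western_europe", n], 50)
  expect_equal(agg[region == "us_canada", pct], 71.43)
})
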