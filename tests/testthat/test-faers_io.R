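# Parsing and writing of the dollar-delimited FAERS ASCII dialect.

test_that("DEMO parsing: row counts, missing-field convention, typing", {
  path <- write_tmp_lines(c(
    "primaryid$caseid$fda_dt$sex$age$age_cod$wt$wt_cod$occp_cod$reporter_country",
    "1001$100$20210101$M$63$YR$80$KG$MD$US",
    "1002$101$20220315$$$$$$$"))
  demo <- parse_faers_table(path, "DEMO")
  expect_equal(nrow(demo), 2L)
  expect_equal(nrow(attr(demo, "parse_report")), 0L)
  expect_equal(demo$primary_id, c("1001", "1002"))
  expect_equal(demo$fda_dt, c(20210101L, 20220315L))
  expect_equal(demo$event_year, c(2021L, 2022L))
  # empty fields become missing
  expect_true(is.na(demo$sex[2]))
  expect_true(is.na(demo$age_value[2]))
  expect_true(is.na(demo$weight_kg[2]))
  expect_equal(demo$sex[1], "M")
  expect_equal(demo$weight_kg[1], 80)
})

test_that("literal NULL and whitespace-only fields are missing", {
  path <- write_tmp_lines(c(
    "primaryid$caseid$fda_dt$sex",
    "1$10$20200101$NULL",
    "2$11$20200102$   "))
  demo <- parse_faers_table(path, "DEMO")
  expect_true(all(is.na(demo$sex)))
})

test_that("weight units are converted to kilograms, unknown units dropped", {
  path <- write_tmp_lines(c(
    "primaryid$caseid$fda_dt$wt$wt_cod",
    "1$10$20200101$150$LBS",
    "2$11$20200101$70000$GMS",
    "3$12$20200101$70$KG",
    "4$13$20200101$70$ST"))
  demo <- parse_faers_table(path, "DEMO")
  expect_equal(demo$weight_kg, c(150 * 0.453592, 70, 70, NA_real_))
})

test_that("columns are located by header name, not position", {
  path <- write_tmp_lines(c(
    "fda_dt$reporter_country$caseid$primaryid",
    "20200101$US$10$1"))
  demo <- parse_faers_table(path, "DEMO")
  expect_equal(demo$primary_id, "1")
  expect_equal(demo$case_id, "10")
  expect_equal(demo$reporter_country, "US")
})

test_that("malformed rows are skipped and reported with line numbers", {
  path <- write_tmp_lines(c(
    "primaryid$caseid$fda_dt",
    "1$10$20200101",
    "2$11$20209901",       # invalid calendar date
    "3$12$20200103$extra", # wrong field count
    "4$13$20200104"))
  demo <- parse_faers_table(path, "DEMO")
  report <- attr(demo, "parse_report")
  expect_equal(nrow(demo), 2L)
  expect_equal(report$line, c(3L, 4L))
  expect_setequal(report$reason, c("invalid fda_dt", "wrong field count"))
  # conservation: records + reported bad lines = data lines
  expect_equal(nrow(demo) + nrow(report), 4L)
})

test_that("DRUG role codes are validated at parse time", {
  path <- write_tmp_lines(c(
    "primaryid$drug_seq$role_cod$drugname$prod_ai",
    "1$1$PS$XPOVIO$SELINEXOR",
    "2$1$XX$ASPIRIN$"))
  drug <- parse_faers_table(path, "DRUG")
  expect_equal(nrow(drug), 1L)
  expect_equal(drug$role_code, "PS")
  expect_equal(attr(drug, "parse_report")$reason, "unknown role code")
})

test_that("OUTC codes restricted to the seven FAERS codes; REAC pt non-empty", {
  outc <- parse_faers_table(write_tmp_lines(c(
    "primaryid$outc_cod", "1$HO", "2$DE", "3$ZZ")), "OUTC")
  expect_equal(outc$outcome_code, c("HO", "DE"))
  expect_equal(attr(outc, "parse_report")$reason, "unknown outcome code")

  reac <- parse_faers_table(write_tmp_lines(c(
    "primaryid$pt", "1$Nausea", "2$  ")), "REAC")
  expect_equal(reac$pt, "Nausea")
  expect_equal(attr(reac, "parse_report")$reason, "empty pt")
})

test_that("missing file and missing required header column are fatal", {
  expect_error(parse_faers_table(tempfile(), "DEMO"), "file not found")
  path <- write_tmp_lines(c("primaryid$caseid", "1$10"))
  expect_error(parse_faers_table(path, "DEMO"), "fda_dt")
})

test_that("round trip: parse(write(x)) equals x for all seven tables", {
  tabs <- generate_faers(synthetic_config(n_cases = 60, seed = 7))
  for (kind in names(tabs)) {
    path <- tempfile(fileext = ".txt")
    write_faers_table(tabs[[kind]], path, table_kind = kind)
    back <- parse_faers_table(path, kind)
    expect_same_records(back, tabs[[kind]])
    expect_equal(nrow(attr(back, "parse_report")), 0L)
  }
})

test_that("empty record list writes a header-only file that parses back", {
  empty <- generate_faers(synthetic_config(n_cases = 0, seed = 1))
  path <- tempfile(fileext = ".txt")
  write_faers_table(empty$DEMO, path, table_kind = "DEMO")
  expect_equal(length(readLines(path)), 1L)
  expect_equal(nrow(parse_faers_table(path, "DEMO")), 0L)
})

test_that("writer rejects the delimiter inside a field", {
  reac <- reac_tbl("1", "Nausea $ vomiting")
  expect_error(write_faers_table(reac, tempfile(), "REAC"), "delimiter")
})

test_that("trailing empty fields survive the round trip", {
  path <- write_tmp_lines(c("primaryid$pt$drug_rec_act", "1$Nausea$"))
  reac <- parse_faers_table(path, "REAC")
  expect_equal(nrow(reac), 1L)
})

test_that("PT->SOC map: lookup, normalization, conflicts", {
  path <- write_tmp_lines(c("pt\tsoc",
                            "Nausea\tGastrointestinal disorders",
                            "NAUSEA \tGastrointestinal disorders",
                            "Fatigue\tGeneral disorders"))
  map <- load_pt_soc_map(path)
  expect_equal(unname(unclass(map)["nausea"]), "Gastrointestinal disorders")
  # duplicate rows with the same SOC collapse; different casings are one key
  expect_equal(sum(names(map) == "nausea"), 1L)

  conflict <- write_tmp_lines(c("Nausea\tGastrointestinal disorders",
                                "nausea\tNervous system disorders"))
  expect_error(load_pt_soc_map(conflict), "nausea")
})
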