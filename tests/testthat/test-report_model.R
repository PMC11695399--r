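test_that("reading joins drug and event rows onto demo-table reports", {
  dir <- withr::local_tempdir()
  writeLines(c("report_id$sex$age_group$year",
               "r1$FEMALE$18-64$2020",
               "r2$MALE$65-85$2021"), file.path(dir, "demo.txt"))
  writeLines(c("report_id$drug_name",
               "r1$hydroxychloroquine"), file.path(dir, "drug.txt"))
  writeLines(c("report_id$event_pt",
               "r1$pemphigus",
               "r2$nausea"), file.path(dir, "reac.txt"))
  rs <- read_reports(file.path(dir, "demo.txt"), file.path(dir, "drug.txt"),
                     file.path(dir, "reac.txt"), dialect = "dollar")
  expect_equal(n_reports(rs), 2L)
  expect_equal(sum(rs$drugs$report_id == "r1"), 1L)
  expect_equal(sum(rs$drugs$report_id == "r2"), 0L)
  expect_equal(nrow(rs$events), 2L)
})

test_that("empty link tables give reports with empty drug/event sets", {
  dir <- withr::local_tempdir()
  writeLines(c("report_id\tsex\tage_group\tyear",
               "r1\tFEMALE\t18-64\t2020",
               "r2\tMALE\t65-85\t2021",
               "r3\t\t\t"), file.path(dir, "demo.tsv"))
  writeLines("report_id\tdrug_name", file.path(dir, "drug.tsv"))
  writeLines("report_id\tevent_pt", file.path(dir, "reac.tsv"))
  rs <- read_reports(file.path(dir, "demo.tsv"), file.path(dir, "drug.tsv"),
                     file.path(dir, "reac.tsv"), dialect = "tab")
  expect_equal(n_reports(rs), 3L)
  expect_equal(nrow(rs$drugs), 0L)
  expect_equal(nrow(rs$events), 0L)
  # out-of-enumeration fields collapse to UNSPECIFIED / NA
  expect_equal(rs$demo$sex[3], "UNSPECIFIED")
  expect_equal(rs$demo$age_group[3], "UNSPECIFIED")
  expect_true(is.na(rs$demo$year[3]))
})

test_that("orphan ids in link tables are warned about and skipped", {
  dir <- withr::local_tempdir()
  writeLines(c("report_id$sex$age_group$year", "r1$FEMALE$18-64$2020"),
             file.path(dir, "demo.txt"))
  writeLines(c("report_id$drug_name", "r1$aspirin", "ghost$aspirin"),
             file.path(dir, "drug.txt"))
  writeLines("report_id$event_pt", file.path(dir, "reac.txt"))
  expect_warning(
    rs <- read_reports(file.path(dir, "demo.txt"), file.path(dir, "drug.txt"),
                       file.path(dir, "reac.txt")),
    "orphan")
  expect_equal(n_reports(rs), 1L)
  expect_false("ghost" %in% rs$drugs$report_id)
})

test_that("malformed inputs raise typed errors", {
  dir <- withr::local_tempdir()
  expect_error(read_reports(file.path(dir, "nope.txt"), "x", "y"),
               class = "pvsignal_input_error")
  writeLines(c("report_id$sex$age_group$year", "r1$F$18-64$2020",
               "r1$F$18-64$2020"), file.path(dir, "demo.txt"))
  writeLines("report_id$drug_name", file.path(dir, "drug.txt"))
  writeLines("report_id$event_pt", file.path(dir, "reac.txt"))
  expect_error(read_reports(file.path(dir, "demo.txt"),
                            file.path(dir, "drug.txt"),
                            file.path(dir, "reac.txt")),
               class = "pvsignal_format_error")
  writeLines(c("report_id$sex$year", "r1$F$2020"), file.path(dir, "demo.txt"))
  expect_error(read_reports(file.path(dir, "demo.txt"),
                            file.path(dir, "drug.txt"),
                            file.path(dir, "reac.txt")),
               class = "pvsignal_format_error", regexp = "age_group")
})

test_that("terms are trimmed, lower-cased and deduplicated per report", {
  rs <- tiny_report_set()
  expect_equal(rs$drugs$drug_name, c("hydroxychloroquine", "hydroxychloroquine"))
  rs2 <- report_set(rs$demo,
                    drugs = data.frame(report_id = c("r1", "r1", "r1"),
                                       drug_name = c("Aspirin ", "aspirin", "ASPIRIN")))
  expect_equal(nrow(rs2$drugs), 1L)
  expect_equal(rs2$drugs$drug_name, "aspirin")
})

test_that("write then read is the identity on report sets", {
  for (dialect in c("dollar", "tab")) {
    sim <- generate_reports(simulation_config(
      n_reports = 1000, p_drug = 0.05, p_event_bg = 0.01, target_ror = 5,
      year_range = c(2016L, 2023L), seed = 301L))
    rs <- sim$reports
    dir <- withr::local_tempdir()
    paths <- write_reports(rs, dir, dialect)
    rs2 <- read_reports(paths["demo"], paths["drug"], paths["reac"], dialect)
    expect_equal(rs2$demo, rs$demo)
    expect_equal(rs2$drugs, rs$drugs)
    expect_equal(rs2$events, rs$events)
  }
})

test_that("rewriting a re-read set reproduces the files byte for byte", {
  sim <- generate_reports(simulation_config(
    n_reports = 10000, p_drug = 0.02, p_event_bg = 0.005, target_ror = 10,
    seed = 302L))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_reports(sim$reports, d1, "dollar")
  rs2 <- read_reports(p1["demo"], p1["drug"], p1["reac"], "dollar")
  p2 <- write_reports(rs2, d2, "dollar")
  for (k in names(p1)) {
    expect_identical(readLines(p2[[k]]), readLines(p1[[k]]))
  }
})

test_that("empty report set writes header-only files and counts survive re-reading", {
  rs <- report_set(data.frame(report_id = character(), sex = character(),
                              age_group = character(), year = integer()))
  dir <- withr::local_tempdir()
  paths <- write_reports(rs, dir, "dollar")
  for (p in paths) expect_length(readLines(p), 1L)
  rs2 <- read_reports(paths["demo"], paths["drug"], paths["reac"], "dollar")
  expect_equal(n_reports(rs2), 0L)
})

test_that("link-table cardinality is preserved on write", {
  rs <- report_set(
    data.frame(report_id = "r1", sex = "FEMALE", age_group = "18-64",
               year = 2020L),
    drugs = data.frame(report_id = "r1", drug_name = c("a", "b")),
    events = data.frame(report_id = "r1", event_pt = c("x", "y", "z")))
  dir <- withr::local_tempdir()
  paths <- write_reports(rs, dir, "tab")
  expect_length(readLines(paths["drug"]), 3L)   # header + 2 rows
  expect_length(readLines(paths["reac"]), 4L)   # header + 3 rows
})

test_that("coding_query rejects empty terms and normalizes case", {
  expect_error(coding_query("", "pemphigus"),
               class = "pvsignal_validation_error")
  expect_error(coding_query("hcq", "  "), class = "pvsignal_validation_error")
  q <- coding_query(" Hydroxychloroquine ", "PEMPHIGUS")
  expect_equal(q$drug_name, "hydroxychloroquine")
  expect_equal(q$event_pt, "pemphigus")
})
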