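test_that("invalid configuration fields are rejected by name", {
  expect_error(simulation_config(n_reports = -1), "n_reports",
               class = "pvsignal_validation_error")
  expect_error(simulation_config(100, p_drug = 1.2), "p_drug",
               class = "pvsignal_validation_error")
  expect_error(simulation_config(100, target_ror = 0), "target_ror",
               class = "pvsignal_validation_error")
  expect_error(simulation_config(100, sex_mix = c(FEMALE = 0.5, MALE = 0.4,
                                                  UNSPECIFIED = 0.2)),
               "sex_mix", class = "pvsignal_validation_error")
  expect_error(simulation_config(100, n_decoy_drugs = 0), "n_decoy_drugs",
               class = "pvsignal_validation_error")
  expect_error(simulation_config(100, year_range = c(2023, 2020)),
               "year_range", class = "pvsignal_validation_error")
  expect_error(simulation_config(100, surge_year_weights = c("1999" = 2)),
               "surge_year_weights", class = "pvsignal_validation_error")
})

test_that("generation is deterministic given the config and seed", {
  cfg <- simulation_config(n_reports = 2000, target_ror = 10, p_drug = 0.05,
                           p_event_bg = 0.01, seed = 99L)
  s1 <- generate_reports(cfg)
  s2 <- generate_reports(cfg)
  expect_identical(s1$reports$demo, s2$reports$demo)
  expect_identical(s1$reports$drugs, s2$reports$drugs)
  expect_identical(s1$reports$events, s2$reports$events)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_reports(s1$reports, d1, "dollar")
  p2 <- write_reports(s2$reports, d2, "dollar")
  for (k in names(p1)) expect_identical(readLines(p1[[k]]), readLines(p2[[k]]))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  x1 <- runif(3)
  set.seed(123)
  invisible(generate_reports(simulation_config(100, seed = 5L)))
  x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("zero reports give an empty set with an all-zero expected table", {
  out <- generate_reports(simulation_config(n_reports = 0))
  expect_equal(n_reports(out$reports), 0L)
  expect_equal(unname(out$truth$expected_table), rep(0, 4))
})

test_that("expected cell counts sum to n and imply the planted odds ratio", {
  cfg <- simulation_config(n_reports = 50000, p_drug = 0.02,
                           p_event_bg = 0.003, target_ror = 25, seed = 1L)
  et <- generate_reports(cfg)$truth$expected_table
  expect_equal(sum(et), 50000)
  implied <- (et[["a"]] * et[["d"]]) / (et[["b"]] * et[["c"]])
  expect_equal(implied, 25, tolerance = 1e-10)
})

test_that("marginal exposure and sex-specific odds match the config", {
  cfg <- simulation_config(n_reports = 200000, p_drug = 0.01,
                           p_event_bg = 0.001, target_ror = 1,
                           sex_exposure_or = 2.82, seed = 77L)
  sim <- generate_reports(cfg)
  odds <- sim$truth$exposure_odds
  # the solved odds satisfy the female:male ratio exactly and reproduce the
  # marginal exposure probability under the sex mix
  expect_equal(odds[["FEMALE"]] / odds[["MALE"]], 2.82, tolerance = 1e-9)
  p_by_sex <- odds / (1 + odds)
  expect_equal(sum(cfg$sex_mix * p_by_sex[names(cfg$sex_mix)]), 0.01,
               tolerance = 1e-9)
  # empirical exposure rate within 3 Monte-Carlo SEs of p_drug
  exposed <- sim$reports$demo$report_id %in%
    sim$reports$drugs$report_id[sim$reports$drugs$drug_name == "hydroxychloroquine"]
  mc_se <- sqrt(0.01 * 0.99 / 200000)
  expect_lt(abs(mean(exposed) - 0.01), 3 * mc_se)
})

test_that("a null planted effect yields a confidence interval containing 1", {
  cfg <- simulation_config(n_reports = 100000, p_drug = 0.05,
                           p_event_bg = 0.01, target_ror = 1, seed = 2024L)
  sim <- generate_reports(cfg)
  r <- ror_estimate(tabulate_reports(sim$reports, HCQ_QUERY))
  expect_lt(r$ci_low, 1)
  expect_gt(r$ci_high, 1)
})

test_that("surge weights shift case years as configured", {
  cfg <- simulation_config(n_reports = 200000, p_drug = 0.05,
                           p_event_bg = 0.01, target_ror = 20,
                           year_range = c(2018L, 2022L),
                           surge_year_weights = c("2021" = 2), seed = 31L)
  sim <- generate_reports(cfg)
  tr <- yearly_trend(sim$reports, HCQ_QUERY)
  c2019 <- tr$count[tr$year == 2019]
  c2021 <- tr$count[tr$year == 2021]
  # 2021 weighted twice as heavily as 2019: ratio 2 within sampling error
  se_ratio <- 2 * sqrt(1 / c2019 + 1 / c2021)
  expect_lt(abs(log(c2021 / c2019) - log(2)), 3 * se_ratio)
})

test_that("the published contingency counts load with their printed margins", {
  t <- hcq_pemphigus_table()
  expect_equal(c(t$a, t$b, t$c, t$d), c(1545, 1003, 61993, 11375215))
  expect_equal(t$n_event, 2548)
  expect_equal(t$n_noevent, 11437208)
  expect_equal(t$n_drug, 63538)
  expect_equal(t$total, 11439756)
})

test_that("scaled fixtures reproduce the table exactly at scale 1", {
  t <- contingency_table(12, 8, 6, 14)
  rs <- scaled_report_set(t, scale = 1, seed = 4L)
  expect_equal(n_reports(rs), 40L)
  rebuilt <- tabulate_reports(rs, HCQ_QUERY)
  expect_equal(as.data.frame(rebuilt), as.data.frame(t))
})

test_that("largest-remainder scaling matches hand-scaled cells", {
  t <- hcq_pemphigus_table()
  rs <- scaled_report_set(t, scale = 1e-3, seed = 9L)
  rebuilt <- tabulate_reports(rs, HCQ_QUERY)
  raw <- c(t$a, t$b, t$c, t$d) * 1e-3
  # total is the rounded scaled total; each cell within 1 of its raw value
  expect_equal(rebuilt$total, round(sum(raw)))
  expect_true(all(abs(c(rebuilt$a, rebuilt$b, rebuilt$c, rebuilt$d) - raw) < 1))
})

test_that("a cell scaled to zero flows through the zero-cell policy", {
  t <- contingency_table(1, 500, 500, 9000)
  rs <- scaled_report_set(t, scale = 0.1, seed = 5L)
  rebuilt <- tabulate_reports(rs, HCQ_QUERY)
  expect_equal(rebuilt$a, 0)
  r <- ror_estimate(rebuilt)
  expect_true(r$correction_applied)
  expect_gt(r$ror, 0)
})

test_that("degenerate scales are rejected", {
  t <- contingency_table(1, 1, 1, 1)
  expect_error(scaled_report_set(t, scale = 0), class = "pvsignal_validation_error")
  expect_error(scaled_report_set(t, scale = 1.5), class = "pvsignal_validation_error")
  expect_error(scaled_report_set(t, scale = 0.1), class = "pvsignal_validation_error")
})
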