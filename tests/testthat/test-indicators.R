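test_that("stock ledger validation reports residuals without fixing them", {
  pass <- validate_ledger(make_report())
  expect_true(pass$pass)
  expect_equal(pass$residual, 0)
  fail <- validate_ledger(make_report(
    oxygen_opening = 1000, oxygen_received = 0, oxygen_consumed = 0,
    oxygen_lost = 0, oxygen_closing = 900
  ))
  expect_false(fail$pass)
  expect_equal(fail$residual, 100)
  # within 1 litre passes
  near <- validate_ledger(make_report(oxygen_closing = 800.5))
  expect_true(near$pass)
})

test_that("report validation enforces structural invariants", {
  expect_silent(validate_reports(make_report()))
  expect_error(validate_reports(make_report(patients_given_oxygen = 60L)),
               "patients_given_oxygen exceeds hypoxaemic_patients")
  expect_error(validate_reports(make_report(staff_trained = 11L)),
               "staff_trained exceeds staff_total")
  expect_error(validate_reports(make_report(oximeters_functional = 9L)),
               "exceeds oximeters_total")
  expect_error(validate_reports(make_report(stockout_days = 32L)),
               "days in month")
  expect_error(validate_reports(make_report(oxygen_received = -5)),
               "oxygen_received")
})

test_that("facility-share and pooled-ratio indicators match hand computation", {
  reports <- dplyr::bind_rows(
    make_report(facility_id = "a", has_hypoxaemia_dept = TRUE),
    make_report(facility_id = "b", has_hypoxaemia_dept = TRUE),
    make_report(facility_id = "c", has_hypoxaemia_dept = TRUE),
    make_report(facility_id = "d", has_hypoxaemia_dept = FALSE)
  )
  expect_equal(pct_with_hypoxaemia_dept(reports)$value, 75)
  reports$has_hypoxaemia_dept <- TRUE
  expect_equal(pct_with_hypoxaemia_dept(reports)$value, 100)

  one <- make_report()
  expect_equal(oxygen_therapy_coverage(one)$value, 80)   # 40 of 50
  expect_equal(therapeutic_success(one)$value, 75)       # 30 of 40
  expect_equal(training_coverage(one)$value, 40)         # 4 of 10
  expect_equal(
    proportion_functional(one, "pulse_oximeter")$value, 75  # 3 of 4
  )
})

test_that("respirator and generator indicators count facilities by category", {
  reports <- dplyr::bind_rows(
    make_report(facility_id = "a", facility_type = "district",
                respirators_functional = 1L),
    make_report(facility_id = "b", facility_type = "district",
                respirators_functional = 0L),
    make_report(facility_id = "c", facility_type = "district",
                respirators_functional = 0L),
    make_report(facility_id = "d", facility_type = "district",
                respirators_functional = 2L),
    make_report(facility_id = "e", facility_type = "district",
                respirators_functional = 0L)
  )
  out <- proportion_functional(reports, "respirator")
  expect_equal(out$key, "4th")  # district maps to 4th category
  expect_equal(out$value, 40)   # 2 of 5 facilities with >= 1 functional
})

test_that("zero denominators yield missing values with a reason", {
  r <- make_report(oximeters_functional = 0L, oximeters_total = 0L)
  out <- proportion_functional(r, "pulse_oximeter")
  expect_true(is.na(out$value))
  expect_match(out$status, "zero denominator")
  r2 <- make_report(hypoxaemic_patients = 0L, patients_given_oxygen = 0L,
                    patients_treatment_success = 0L)
  expect_true(is.na(oxygen_therapy_coverage(r2)$value))
  expect_true(is.na(therapeutic_success(r2)$value))
})

test_that("quarterly stock-out indicator sums months and averages facilities", {
  one <- dplyr::bind_rows(
    make_report(period = "2023-01", stockout_days = 2L),
    make_report(period = "2023-02", stockout_days = 0L),
    make_report(period = "2023-03", stockout_days = 1L)
  )
  expect_equal(mean_stockout_days(one, "2023-Q1")$value, 3)

  two <- dplyr::bind_rows(
    one,
    make_report(facility_id = "hf2", period = "2023-01", stockout_days = 0L),
    make_report(facility_id = "hf2", period = "2023-02", stockout_days = 0L),
    make_report(facility_id = "hf2", period = "2023-03", stockout_days = 0L)
  )
  two$stockout_days[4:6] <- c(4L, 0L, 0L)
  expect_equal(mean_stockout_days(two, "2023-Q1")$value, 3.5)

  # default policy excludes facilities missing a month; "zero" keeps them
  partial <- dplyr::bind_rows(
    one,
    make_report(facility_id = "hf3", period = "2023-01", stockout_days = 6L)
  )
  excl <- mean_stockout_days(partial, "2023-Q1")
  expect_equal(excl$value, 3)
  expect_identical(attr(excl, "missing_policy"), "exclude")
  zero <- mean_stockout_days(partial, "2023-Q1", missing = "zero")
  expect_equal(zero$value, 4.5)
})

test_that("national ratios pool numerators, not regional percentages", {
  # big region with low coverage, tiny region with high coverage: the pooled
  # national value must sit near the big region, not at the midpoint
  reports <- dplyr::bind_rows(
    make_report(facility_id = "big", region = "R01",
                hypoxaemic_patients = 1000L, patients_given_oxygen = 200L,
                patients_treatment_success = 100L),
    make_report(facility_id = "small", region = "R02",
                hypoxaemic_patients = 10L, patients_given_oxygen = 10L,
                patients_treatment_success = 9L)
  )
  nat <- oxygen_therapy_coverage(reports)$value
  expect_equal(nat, 100 * 210 / 1010)
  reg <- oxygen_therapy_coverage(reports, by = "region")
  expect_false(isTRUE(all.equal(nat, mean(reg$value))))
})

test_that("percentage indicators stay within [0, 100] on synthetic panels", {
  cfg <- generator_config(seed = 87)
  roster <- generate_roster(cfg)
  reports <- generate_reports(roster, cfg, months = 3)
  out <- compute_indicators(reports, by = "region")
  pct <- out[out$unit == "%" & !is.na(out$value), ]
  expect_true(all(pct$value >= 0 & pct$value <= 100))
})

test_that("the catalogue covers every computed indicator", {
  cat <- indicator_catalogue()
  expect_equal(anyDuplicated(cat$indicator_id), 0)
  cfg <- generator_config(seed = 6)
  roster <- generate_roster(cfg)
  reports <- generate_reports(roster, cfg, months = 3)
  out <- compute_indicators(reports)
  expect_true(all(out$indicator_id %in% cat$indicator_id))
  expect_setequal(out$indicator_id, cat$indicator_id)
})
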