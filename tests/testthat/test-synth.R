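test_that("largest-remainder apportionment is exact and near-quota", {
  x <- largest_remainder(10, c(1, 1, 1))
  expect_equal(sum(x), 10)
  expect_true(all(abs(x - 10 / 3) < 1))
  shares <- c(0.5, 0.3, 0.2)
  for (total in c(0, 1, 7, 100, 5090)) {
    parts <- largest_remainder(total, shares)
    expect_equal(sum(parts), total)
    expect_true(all(abs(parts - total * shares) < 1))
  }
  expect_error(largest_remainder(10, c(0, 0)), "positive sum")
})

test_that("generated rosters match the configured facility frame exactly", {
  roster <- generate_roster(generator_config(seed = 42))
  counts <- roster |>
    dplyr::distinct(.data$facility_id, .data$facility_type) |>
    dplyr::count(.data$facility_type)
  expect_equal(counts$n[match(c("general", "central", "regional", "district"),
                              counts$facility_type)],
               c(4L, 13L, 15L, 67L))
  expect_equal(length(unique(roster$facility_id)), 99L)
  beds <- roster |>
    dplyr::group_by(.data$facility_type) |>
    dplyr::summarise(beds = sum(.data$beds))
  expect_equal(beds$beds[beds$facility_type == "district"], 5090L)
  expect_equal(sum(beds$beds), sum(default_facility_type_params()$total_beds))
  expect_true(all(roster$region %in% sprintf("R%02d", 1:10)))
})

test_that("the full generation pipeline is deterministic under a fixed seed", {
  run <- function() {
    cfg <- generator_config(seed = 77)
    roster <- generate_roster(cfg)
    inv <- generate_inventory(roster, cfg)
    reports <- generate_reports(roster, cfg, months = 2, inventory = inv)
    list(roster, inv, reports)
  }
  expect_identical(run(), run())
  # and differs under a different seed
  other <- generate_roster(generator_config(seed = 78))
  expect_false(identical(generate_roster(generator_config(seed = 77))$region,
                         other$region))
})

test_that("misconfigured generators are rejected", {
  expect_error(generator_config(ward_shares = c(a = 0.5, b = 0.4)),
               "sum to 1")
  expect_error(
    generator_config(report_params = list(
      stockout_rate = 1.5, coverage_prob = 1.7, success_prob = 0.75,
      training_fraction = 0.5, dept_prob = 0.6, staff_mean = 20,
      stock_buffer = 1.5, loss_rate = 0.02
    )),
    "coverage_prob"
  )
})

test_that("generated reports honour construction guarantees", {
  cfg <- generator_config(seed = 9)
  roster <- generate_roster(cfg)
  reports <- generate_reports(roster, cfg, months = 3)
  # ledger identity holds on every report
  expect_true(all(validate_ledger(reports)$pass))
  expect_equal(nrow(reports), 99 * 3)
  expect_true(all(reports$stockout_days <= 31))

  # degenerate coverage probability: everyone hypoxaemic receives oxygen
  rp <- cfg$report_params
  rp$coverage_prob <- 1
  full <- generate_reports(roster, generator_config(seed = 9, report_params = rp),
                           months = 1)
  expect_equal(full$patients_given_oxygen, full$hypoxaemic_patients)
})

test_that("indicator parameters are recovered from large synthetic panels", {
  cfg <- generator_config(seed = 2024)
  roster <- generate_roster(cfg)
  reports <- generate_reports(roster, cfg, months = 6)  # 594 facility-months
  expect_gte(nrow(reports), 500)

  # oxygen therapy coverage: binomial with p = 0.7 pooled over all patients
  n_hypox <- sum(reports$hypoxaemic_patients)
  se_cov <- 100 * sqrt(0.7 * 0.3 / n_hypox)
  cov <- oxygen_therapy_coverage(reports)$value
  expect_lt(abs(cov - 70), 3 * se_cov)

  # therapeutic success: p = 0.75 over patients given oxygen
  n_given <- sum(reports$patients_given_oxygen)
  se_suc <- 100 * sqrt(0.75 * 0.25 / n_given)
  expect_lt(abs(therapeutic_success(reports)$value - 75), 3 * se_suc)

  # quarterly stock-outs: Poisson(1.5)/month, so quarterly mean 4.5
  se_so <- sqrt(4.5 / 99)
  so <- mean_stockout_days(reports, "2023-Q1")$value
  expect_lt(abs(so - 4.5), 3 * se_so)

  # department flag rate 0.6 over 99 facilities
  se_dept <- 100 * sqrt(0.6 * 0.4 / 99)
  dept <- pct_with_hypoxaemia_dept(reports)$value
  expect_lt(abs(dept - 60), 3 * se_dept)

  # training fraction 0.5 pooled over staff
  n_staff <- sum(reports$staff_total[reports$period == "2023-01"])
  se_tr <- 100 * sqrt(0.5 * 0.5 / n_staff)
  tr <- training_coverage(reports, period = "2023-01")$value
  expect_lt(abs(tr - 50), 3 * se_tr)
})

test_that("national demand on a generated roster matches the share closed form", {
  cfg <- generator_config(seed = 55)
  roster <- generate_roster(cfg)
  national <- rollup_demand(facility_demand(roster,
                                            type_params = cfg$type_params),
                            "national")$annual_litres
  # closed form: sum over types and wards of share-implied beds x turnover x
  # prevalence x per-patient volume; bed allocation rounds per facility, so
  # allow the rounding slack of one bed per facility-ward cell
  a <- default_ward_assumptions()
  shares <- cfg$ward_shares
  closed <- 0
  for (i in seq_len(nrow(cfg$type_params))) {
    tp <- cfg$type_params[i, ]
    for (w in names(shares)) {
      aw <- a[a$ward == w, ]
      closed <- closed + tp$total_beds * shares[[w]] *
        tp$annual_bed_turnover * aw$prevalence *
        per_patient_volume(aw$flow_lpm, aw$duration_hours)
    }
  }
  max_cell <- max(default_facility_type_params()$annual_bed_turnover) *
    max(a$prevalence * per_patient_volume(a$flow_lpm, a$duration_hours))
  slack <- 99 * length(shares) * max_cell  # <= 1 bed per facility-ward
  expect_lt(abs(national - closed), slack)
  expect_lt(abs(national - closed) / closed, 0.05)
})
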