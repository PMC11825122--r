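test_that("per-patient volume is flow x 60 x duration", {
  expect_equal(per_patient_volume(1, 72), 4320)      # 1 L/min for 3 days
  expect_equal(per_patient_volume(10, 168), 100800)  # 10 L/min for 7 days
  expect_equal(per_patient_volume(0, 500), 0)
  expect_equal(per_patient_volume(c(1, 10), c(72, 168)), c(4320, 100800))
  expect_error(per_patient_volume(-1, 10), ">= 0")
})

test_that("expected caseload is prevalence x beds x turnover x occupancy", {
  expect_equal(caseload(0.20, 10, 50), 100)
  expect_equal(caseload(1.00, 5, 25), 125)
  expect_equal(caseload(0, 1000, 100), 0)
  expect_equal(caseload(0.5, 10, 50, occupancy = 0.8), 200)
  # expectations stay fractional
  expect_equal(caseload(0.13, 7, 58), 0.13 * 7 * 58)
  expect_error(caseload(1.5, 10, 50), "fraction")
  expect_error(caseload(0.5, 10, 50, occupancy = 2), "fraction")
})

test_that("ward annual need multiplies volume by caseload", {
  expect_equal(ward_annual_need(4320, 100), 432000)
  expect_equal(ward_annual_need(100800, 125), 12600000)
  expect_equal(ward_annual_need(99999, 0), 0)
})

test_that("monthly and type-level conversions", {
  expect_equal(monthly_litres(12600000), 1050000)
  expect_equal(monthly_litres(432000), 36000)
  expect_equal(monthly_litres(0), 0)
  expect_equal(typelevel_need(67, 100000), 6700000)
  expect_equal(typelevel_need(0, 1e9), 0)
})

test_that("facility demand reproduces the worked quantification example", {
  fac <- facility_demand(example_roster(), example_assumptions(),
                         example_type_params())
  neo <- fac[fac$group_key == "hf_neo", ]
  cov <- fac[fac$group_key == "hf_cov", ]
  expect_identical(neo$annual_litres, 432000)
  expect_identical(neo$expected_hypoxaemic_patients, 100)
  expect_identical(cov$annual_litres, 12600000)
  expect_identical(cov$expected_hypoxaemic_patients, 125)
  national <- rollup_demand(fac, "national")
  expect_identical(national$annual_litres, 13032000)
})

test_that("a facility with only zero-prevalence wards needs no oxygen", {
  roster <- tibble::tibble(
    facility_id = "hf1", facility_type = "district", region = "R01",
    ward = "outpatient", beds = 40L
  )
  fac <- facility_demand(roster)
  expect_equal(fac$annual_litres, 0)
})

test_that("unresolvable labels are reported by name", {
  roster <- tibble::tibble(
    facility_id = "hf1", facility_type = "district", region = "R01",
    ward = "dialysis", beds = 5L
  )
  expect_error(facility_demand(roster), "dialysis")
  roster2 <- tibble::tibble(
    facility_id = "hf1", facility_type = "clinic", region = "R01",
    ward = "maternity", beds = 5L
  )
  expect_error(facility_demand(roster2), "clinic")
})

test_that("demand is linear in each factor and propagates zeros", {
  base_assum <- tibble::tibble(ward = "w", prevalence = 0.3, flow_lpm = 4,
                               duration_hours = 24)
  base_types <- tibble::tibble(type = "t", facility_count = 1L,
                               total_beds = 10L, annual_bed_turnover = 40)
  roster <- tibble::tibble(facility_id = "f", facility_type = "t",
                           region = "R01", ward = "w", beds = 10L)
  need <- function(assum = base_assum, types = base_types, r = roster,
                   occ = 1) {
    facility_demand(r, assum, types, occ)$annual_litres
  }
  base <- need()
  for (col in c("prevalence", "flow_lpm", "duration_hours")) {
    doubled <- base_assum
    doubled[[col]] <- if (col == "prevalence") 0.6 else 2 * doubled[[col]]
    expect_equal(need(assum = doubled), 2 * base)
    zeroed <- base_assum
    zeroed[[col]] <- 0
    expect_equal(need(assum = zeroed), 0)
  }
  types2 <- base_types
  types2$annual_bed_turnover <- 80
  expect_equal(need(types = types2), 2 * base)
  roster2 <- roster
  roster2$beds <- 20L
  expect_equal(need(r = roster2), 2 * base)
  expect_equal(need(occ = 0.5), base / 2)
  types0 <- base_types
  types0$annual_bed_turnover <- 0
  expect_equal(need(types = types0), 0)
})

test_that("roll-ups conserve the national total over any partition", {
  cfg <- generator_config(seed = 101)
  roster <- generate_roster(cfg)
  fac <- facility_demand(roster)
  national <- rollup_demand(fac, "national")$annual_litres
  by_type <- rollup_demand(fac, "facility_type")
  by_region <- rollup_demand(fac, "region")
  expect_equal(sum(by_type$annual_litres), national)
  expect_equal(sum(by_region$annual_litres), national)
  expect_equal(sum(fac$annual_litres), national)
  # monthly is annual / 12 everywhere
  expect_equal(by_type$monthly_litres, by_type$annual_litres / 12)
  # additivity on a trivial pair
  two <- tibble::tibble(
    grouping = "facility", group_key = c("a", "b"),
    annual_litres = c(432000, 432000),
    monthly_litres = c(36000, 36000),
    expected_hypoxaemic_patients = c(100, 100),
    facility_type = c("district", "district"),
    region = c("R01", "R02")
  )
  expect_equal(rollup_demand(two, "national")$annual_litres, 864000)
})

test_that("roll-up totals match the brute-force per-(facility, ward) oracle", {
  assumptions <- default_ward_assumptions()
  type_params <- default_facility_type_params()
  for (seed in c(3, 17)) {
    roster <- generate_roster(generator_config(seed = seed))
    expect_lte(length(unique(roster$facility_id)), 200)
    fac <- facility_demand(roster, assumptions, type_params)
    expect_equal(
      rollup_demand(fac, "national")$annual_litres,
      oracle_national_demand(roster, assumptions, type_params),
      tolerance = 1e-6
    )
    want <- oracle_facility_demand(roster, assumptions, type_params)
    expect_equal(fac$annual_litres[match(names(want), fac$group_key)],
                 unname(want), tolerance = 1e-6)
  }
})

test_that("rollup with an explicit facility index validates coverage", {
  fac <- facility_demand(example_roster(), example_assumptions(),
                         example_type_params())
  idx <- tibble::tibble(facility_id = c("hf_neo", "hf_cov"),
                        facility_type = c("t1", "t2"),
                        region = c("north", "south"))
  by_region <- rollup_demand(fac, "region", facility_index = idx)
  expect_setequal(by_region$group_key, c("north", "south"))
  expect_error(rollup_demand(fac, "region", facility_index = idx[1, ]),
               "missing from index")
})
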