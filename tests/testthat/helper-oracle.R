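# Brute-force oracles, kept independent of the package's vectorised /
# grouped implementations: plain loops with explicit lookups.

# National annual demand by per-(facility, ward) accumulation.
oracle_national_demand <- function(roster, assumptions, type_params,
                                   occupancy = 1) {
  total <- 0
  for (i in seq_len(nrow(roster))) {
    ward <- roster$ward[i]
    type <- roster$facility_type[i]
    a <- assumptions[assumptions$ward == ward, ]
    turnover <- type_params$annual_bed_turnover[type_params$type == type]
    vol <- a$flow_lpm * 60 * a$duration_hours
    patients <- a$prevalence * roster$beds[i] * turnover * occupancy
    total <- total + vol * patients
  }
  total
}

# Per-facility annual demand by the same accumulation.
oracle_facility_demand <- function(roster, assumptions, type_params,
                                   occupancy = 1) {
  ids <- unique(roster$facility_id)
  out <- numeric(length(ids))
  names(out) <- ids
  for (i in seq_len(nrow(roster))) {
    ward <- roster$ward[i]
    type <- roster$facility_type[i]
    a <- assumptions[assumptions$ward == ward, ]
    turnover <- type_params$annual_bed_turnover[type_params$type == type]
    contrib <- a$flow_lpm * 60 * a$duration_hours *
      a$prevalence * roster$beds[i] * turnover * occupancy
    out[roster$facility_id[i]] <- out[roster$facility_id[i]] + contrib
  }
  out
}

# National cylinder volume gap by facility-by-facility accumulation of
# demand and functional cylinder capacity, clamped once at national scope.
oracle_national_cylinder_gap <- function(fac_demand, inventory,
                                         cylinder_size = 7500,
                                         basis = "monthly") {
  demand <- 0
  for (i in seq_len(nrow(fac_demand))) {
    demand <- demand + if (basis == "monthly") {
      fac_demand$monthly_litres[i]
    } else {
      fac_demand$annual_litres[i]
    }
  }
  capacity <- 0
  for (i in seq_len(nrow(inventory))) {
    if (inventory$device_class[i] == "oxygen_cylinder") {
      capacity <- capacity + inventory$functional[i] * cylinder_size
    }
  }
  max(demand - capacity, 0)
}

# Roster holding the two worked wards of the reference quantification
# example: a neonatal ward (1 L/min, 72 h, prevalence 20%, 10 beds,
# turnover 50) and a severe-COVID adult ward (10 L/min, 168 h, prevalence
# 100%, 5 beds, turnover 25).  Turnover is a facility-type property, so the
# two wards sit in two single-ward facilities of distinct types.
example_assumptions <- function() {
  tibble::tibble(
    ward = c("neonatology", "covid"),
    prevalence = c(0.20, 1.00),
    flow_lpm = c(1, 10),
    duration_hours = c(72, 168)
  )
}

example_type_params <- function() {
  tibble::tibble(
    type = c("neonatal_unit", "covid_centre"),
    facility_count = c(1L, 1L),
    total_beds = c(10L, 5L),
    annual_bed_turnover = c(50, 25)
  )
}

example_roster <- function() {
  tibble::tibble(
    facility_id = c("hf_neo", "hf_cov"),
    facility_type = c("neonatal_unit", "covid_centre"),
    region = c("R01", "R01"),
    ward = c("neonatology", "covid"),
    beds = c(10L, 5L)
  )
}

# Minimal single-row monthly report with overridable fields.
make_report <- function(...) {
  base <- tibble::tibble(
    facility_id = "hf1", facility_type = "district", region = "R01",
    period = "2023-01", has_hypoxaemia_dept = TRUE, stockout_days = 0L,
    oxygen_opening = 1000, oxygen_received = 500, oxygen_consumed = 700,
    oxygen_lost = 0, oxygen_closing = 800,
    oximeters_functional = 3L, oximeters_total = 4L,
    respirators_functional = 1L, respirators_total = 2L,
    generators_functional = 0L, generators_total = 0L,
    cylinders_7500 = 5L, staff_trained = 4L, staff_total = 10L,
    hypoxaemic_patients = 50L, patients_given_oxygen = 40L,
    patients_treatment_success = 30L
  )
  dots <- list(...)
  for (nm in names(dots)) base[[nm]] <- dots[[nm]]
  base
}
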