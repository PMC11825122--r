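# Synthetic facility-data generator: rosters, equipment inventories and
# monthly report panels with the statistical structure the analysis
# assumes, so the whole pipeline runs without access to the confidential
# facility-assessment data it was designed for.

#' Default ward shares of facility beds
#'
#' Fraction of a facility's beds allocated to each ward type by the
#' generator.  The mix is a plausible hospital profile weighted towards
#' general medicine, paediatrics, maternity and the operating theatre; it
#' is configuration, not an empirical estimate.
#'
#' @return A named numeric vector over the nine default wards, summing to 1.
#' @export
default_ward_shares <- function() {
  c(outpatient = 0.05, adult_medicine = 0.30, paediatrics = 0.15,
    neonatology = 0.05, intensive_care = 0.04, operating_theatre = 0.10,
    emergency = 0.08, maternity = 0.18, recovery = 0.05)
}

#' Generator configuration
#'
#' Bundles every parameter of the synthetic-data generator.  Defaults give
#' a 99-facility national frame (4 general, 13 central, 15 regional, 67
#' district hospitals over 10 regions) with the shipped clinical
#' assumptions, and report-stream parameters chosen as plausible programme
#' values: a 60% rate of facilities with a hypoxaemia-management
#' department, 1.5 stock-out events per facility-month, 70% oxygen-therapy
#' coverage, 75% therapeutic success, and 50% of staff trained.
#'
#' @param seed Integer seed; a fixed seed makes every generator output
#'   reproducible.
#' @param type_params Facility-type registry
#'   (default [default_facility_type_params()]).
#' @param ward_shares Named fractions over wards, summing to 1
#'   (default [default_ward_shares()]).
#' @param regions Region labels (default `"R01"`–`"R10"`; real names are
#'   configurable because the arithmetic does not depend on them).
#' @param region_weights Facility-allocation weights over regions
#'   (default uniform).
#' @param equipment_rates Per device class, a list
#'   `list(per10beds = , functional_prob = )`: expected device total per 10
#'   beds and the probability each device is functional.
#' @param report_params List of report-stream parameters: `stockout_rate`
#'   (events per facility-month), `coverage_prob`, `success_prob`,
#'   `training_fraction`, `dept_prob`, `staff_mean`, `stock_buffer`
#'   (opening stock as a multiple of expected monthly consumption),
#'   `loss_rate`.
#' @param cylinder_size Litres of gaseous oxygen per cylinder (default 7500).
#' @return A list of class `"oxyplan_generator_config"`.
#' @export
generator_config <- function(seed = 1L,
                             type_params = default_facility_type_params(),
                             ward_shares = default_ward_shares(),
                             regions = sprintf("R%02d", 1:10),
                             region_weights = rep(1, length(regions)),
                             equipment_rates = list(
                               oxygen_concentrator = list(per10beds = 1.0,
                                                          functional_prob = 0.80),
                               pulse_oximeter = list(per10beds = 1.5,
                                                     functional_prob = 0.85),
                               patient_monitor = list(per10beds = 0.8,
                                                      functional_prob = 0.70),
                               oxygen_cylinder = list(per10beds = 1.2,
                                                      functional_prob = 0.90)
                             ),
                             report_params = list(
                               stockout_rate = 1.5,
                               coverage_prob = 0.70,
                               success_prob = 0.75,
                               training_fraction = 0.50,
                               dept_prob = 0.60,
                               staff_mean = 20,
                               stock_buffer = 1.5,
                               loss_rate = 0.02
                             ),
                             cylinder_size = 7500) {
  type_params <- validate_facility_type_params(type_params)
  if (abs(sum(ward_shares) - 1) > 1e-9) {
    abort("generator_config: ward_shares must sum to 1")
  }
  if (any(ward_shares < 0)) {
    abort("generator_config: ward_shares must be non-negative")
  }
  if (length(region_weights) != length(regions) || any(region_weights < 0)) {
    abort("generator_config: region_weights must be non-negative, one per region")
  }
  probs <- c("coverage_prob", "success_prob", "training_fraction", "dept_prob",
             "loss_rate")
  for (p in probs) {
    v <- report_params[[p]]
    if (is.null(v) || v < 0 || v > 1) {
      abort(paste0("generator_config: report_params$", p,
                   " must be a probability in [0, 1]"))
    }
  }
  structure(
    list(seed = as.integer(seed), type_params = type_params,
         ward_shares = ward_shares, regions = regions,
         region_weights = region_weights, equipment_rates = equipment_rates,
         report_params = report_params, cylinder_size = cylinder_size),
    class = "oxyplan_generator_config"
  )
}

#' Largest-remainder integer apportionment
#'
#' Splits an integer total over shares so that the parts are integers, sum
#' exactly to the total, and differ from the exact quotas by less than one
#' unit.  Ties in the fractional remainders break towards earlier
#' positions, deterministically.
#'
#' @param total Non-negative integer to apportion.
#' @param shares Non-negative weights (need not sum to 1).
#' @return Integer vector summing to `total`.
#' @export
largest_remainder <- function(total, shares) {
  stop_if_bad_nonneg(shares, "shares")
  if (length(shares) == 0 || sum(shares) == 0) {
    abort("largest_remainder: shares must have positive sum")
  }
  quota <- total * shares / sum(shares)
  base <- floor(quota)
  left <- round(total - sum(base))
  if (left > 0) {
    pick <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[pick] <- base[pick] + 1
  }
  as.integer(base)
}

#' Generate a synthetic facility roster
#'
#' Produces a long roster (one row per facility-ward) matching the
#' configured facility-type frame exactly: facility counts per type are
#' exact, type-level bed totals are preserved exactly (beds are spread over
#' a type's facilities, then over wards, by largest-remainder
#' apportionment), and regions are assigned by weighted sampling.
#'
#' @param config A [generator_config()].
#' @return A roster tibble `facility_id, facility_type, region, ward, beds`.
#' @examples
#' roster <- generate_roster(generator_config(seed = 42))
#' length(unique(roster$facility_id))  # 99
#' @export
generate_roster <- function(config) {
  stopifnot(inherits(config, "oxyplan_generator_config"))
  withr::with_seed(config$seed, {
    wards <- names(config$ward_shares)
    rows <- purrr::pmap(config$type_params, function(type, facility_count,
                                                     total_beds,
                                                     annual_bed_turnover) {
      if (facility_count == 0) return(NULL)
      fac_beds <- largest_remainder(total_beds, rep(1, facility_count))
      regions <- sample(config$regions, facility_count, replace = TRUE,
                        prob = config$region_weights)
      purrr::map(seq_len(facility_count), function(i) {
        tibble::tibble(
          facility_id = sprintf("%s_%03d", type, i),
          facility_type = type,
          region = regions[i],
          ward = wards,
          beds = largest_remainder(fac_beds[i], config$ward_shares)
        )
      })
    })
    roster <- dplyr::bind_rows(purrr::flatten(rows))
    validate_roster(roster, type_params = config$type_params)
  })
}

#' Generate a synthetic equipment inventory
#'
#' Draws, for each facility and device class, a total device count
#' proportional to the facility's bed complement (Poisson with mean
#' `beds / 10 * per10beds`) and a functional subset (binomial with the
#' configured functionality probability).
#'
#' @param roster A roster from [generate_roster()].
#' @param config The [generator_config()] used for the roster.
#' @return An inventory tibble
#'   `facility_id, device_class, functional, total, cylinder_size`.
#' @export
generate_inventory <- function(roster, config) {
  stopifnot(inherits(config, "oxyplan_generator_config"))
  withr::with_seed(config$seed + 1L, {
    beds <- roster |>
      dplyr::group_by(.data$facility_id) |>
      dplyr::summarise(beds = sum(.data$beds), .groups = "drop")
    rows <- purrr::imap(config$equipment_rates, function(rate, device) {
      total <- rpois(nrow(beds), beds$beds / 10 * rate$per10beds)
      tibble::tibble(
        facility_id = beds$facility_id,
        device_class = device,
        functional = rbinom(nrow(beds), total, rate$functional_prob),
        total = total,
        cylinder_size = ifelse(device == "oxygen_cylinder",
                               config$cylinder_size, NA_real_)
      )
    })
    validate_inventory(dplyr::bind_rows(rows))
  })
}

months_from <- function(start, months) {
  first <- as.Date(paste0(start, "-01"))
  if (is.na(first)) abort("start must be 'YYYY-MM'")
  format(seq(first, by = "month", length.out = months), "%Y-%m")
}

#' Generate a synthetic panel of monthly facility reports
#'
#' Simulates the monthly reporting stream the indicator set consumes.  Per
#' facility, hypoxaemic patient counts are Poisson with mean equal to the
#' facility's expected monthly caseload from the demand model (linking the
#' generator to the quantification engine); patients given oxygen are
#' binomial in the coverage probability and treatment successes binomial in
#' the success probability; stock-out days are Poisson-capped at the month
#' length.  The oxygen stock ledger is built constructively — closing stock
#' is defined as `opening + received - consumed - lost` and carried into
#' the next month — so the ledger identity holds exactly on every report.
#'
#' @param roster A roster from [generate_roster()].
#' @param config The [generator_config()] used for the roster.
#' @param months Number of consecutive months to simulate (>= 1).
#' @param start First period, `"YYYY-MM"` (default `"2023-01"`).
#' @param inventory Optional inventory from [generate_inventory()]; when
#'   given, pulse-oximeter and cylinder columns are taken from it instead
#'   of redrawn.
#' @return A validated report panel (see [validate_reports()]).
#' @export
generate_reports <- function(roster, config, months = 3, start = "2023-01",
                             inventory = NULL) {
  stopifnot(inherits(config, "oxyplan_generator_config"))
  if (months < 1) abort("generate_reports: months must be >= 1")
  rp <- config$report_params
  periods <- months_from(start, months)
  dim_days <- days_in_month(periods)

  fac_demand <- facility_demand(roster, type_params = config$type_params)
  fac <- tibble::tibble(
    facility_id = fac_demand$group_key,
    facility_type = fac_demand$facility_type,
    region = fac_demand$region,
    monthly_patients = fac_demand$expected_hypoxaemic_patients / 12,
    monthly_litres = fac_demand$monthly_litres
  )
  n <- nrow(fac)

  withr::with_seed(config$seed + 2L, {
    # facility-level properties, constant across months
    dept <- rbinom(n, 1, rp$dept_prob) == 1
    staff_total <- rpois(n, rp$staff_mean) + 1L
    staff_trained <- rbinom(n, staff_total, rp$training_fraction)
    if (is.null(inventory)) {
      oxi_rate <- config$equipment_rates$pulse_oximeter
      cyl_rate <- config$equipment_rates$oxygen_cylinder
      beds <- roster |>
        dplyr::group_by(.data$facility_id) |>
        dplyr::summarise(beds = sum(.data$beds), .groups = "drop")
      beds <- beds$beds[match(fac$facility_id, beds$facility_id)]
      oxi_total <- rpois(n, beds / 10 * oxi_rate$per10beds)
      oxi_func <- rbinom(n, oxi_total, oxi_rate$functional_prob)
      cyl_total <- rpois(n, beds / 10 * cyl_rate$per10beds)
    } else {
      inv <- validate_inventory(inventory)
      pick <- function(device, col) {
        sub <- inv[inv$device_class == device, , drop = FALSE]
        out <- sub[[col]][match(fac$facility_id, sub$facility_id)]
        dplyr::coalesce(out, 0L)
      }
      oxi_total <- pick("pulse_oximeter", "total")
      oxi_func <- pick("pulse_oximeter", "functional")
      cyl_total <- pick("oxygen_cylinder", "total")
    }
    resp_total <- rpois(n, 2)
    resp_func <- rbinom(n, resp_total, 0.7)
    gen_total <- rbinom(n, 1, 0.3)
    gen_func <- rbinom(n, gen_total, 0.6)

    opening <- round(rp$stock_buffer * fac$monthly_litres)
    out <- vector("list", months)
    for (m in seq_len(months)) {
      hypox <- rpois(n, fac$monthly_patients)
      given <- rbinom(n, hypox, rp$coverage_prob)
      success <- rbinom(n, given, rp$success_prob)
      received <- round(fac$monthly_litres * runif(n, 0.8, 1.2))
      consumed <- pmin(opening + received,
                       round(fac$monthly_litres * runif(n, 0.7, 1.1)))
      lost <- pmin(round(rp$loss_rate * consumed),
                   opening + received - consumed)
      closing <- opening + received - consumed - lost
      out[[m]] <- tibble::tibble(
        facility_id = fac$facility_id,
        facility_type = fac$facility_type,
        region = fac$region,
        period = periods[m],
        has_hypoxaemia_dept = dept,
        stockout_days = pmin(rpois(n, rp$stockout_rate), dim_days[m]),
        oxygen_opening = opening,
        oxygen_received = received,
        oxygen_consumed = consumed,
        oxygen_lost = lost,
        oxygen_closing = closing,
        oximeters_functional = oxi_func,
        oximeters_total = oxi_total,
        respirators_functional = resp_func,
        respirators_total = resp_total,
        generators_functional = gen_func,
        generators_total = gen_total,
        cylinders_7500 = cyl_total,
        staff_trained = staff_trained,
        staff_total = staff_total,
        hypoxaemic_patients = hypox,
        patients_given_oxygen = given,
        patients_treatment_success = success
      )
      opening <- closing
    }
    validate_reports(dplyr::bind_rows(out))
  })
}
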