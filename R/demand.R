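# Oxygen demand model: per-patient volume, expected hypoxaemic caseload,
# and hierarchical roll-ups from ward to national level.

#' Gaseous oxygen volume for one typical hypoxaemic patient
#'
#' Volume (litres) of gaseous medical oxygen consumed by one typical
#' hypoxaemic patient treated at a constant flow rate for a given duration:
#' `flow_lpm * 60 * duration_hours`.
#'
#' @param flow_lpm Oxygen flow rate in litres per minute (>= 0).
#' @param duration_hours Duration of oxygen therapy in hours (>= 0).
#' @return Volume in litres (vectorised).
#' @examples
#' per_patient_volume(1, 72)    # 4320 L: 1 L/min for 3 days
#' per_patient_volume(10, 168)  # 100800 L: 10 L/min for 7 days
#' @export
per_patient_volume <- function(flow_lpm, duration_hours) {
  stop_if_bad_nonneg(flow_lpm, "flow_lpm")
  stop_if_bad_nonneg(duration_hours, "duration_hours")
  flow_lpm * 60 * duration_hours
}

#' Expected number of hypoxaemic patients per year
#'
#' Expected annual hypoxaemic caseload for a ward:
#' `prevalence * beds * turnover * occupancy`.  The result is an
#' expectation and is deliberately kept fractional.  Occupancy is an
#' optional average bed-occupancy multiplier; the default of 1 treats the
#' turnover rate as already reflecting realised admissions.
#'
#' @param prevalence Hypoxaemia prevalence among the ward's patients,
#'   a fraction in `[0, 1]`.
#' @param beds Number of beds (>= 0).
#' @param turnover Annual bed turnover rate, patients per bed per year (>= 0).
#' @param occupancy Average occupancy rate, a fraction in `[0, 1]`
#'   (default 1).
#' @return Expected patients per year (vectorised).
#' @examples
#' caseload(0.20, 10, 50)  # 100 patients/yr
#' caseload(1.00, 5, 25)   # 125 patients/yr
#' @export
caseload <- function(prevalence, beds, turnover, occupancy = 1) {
  stop_if_bad_fraction(prevalence, "prevalence")
  stop_if_bad_fraction(occupancy, "occupancy")
  stop_if_bad_nonneg(beds, "beds")
  stop_if_bad_nonneg(turnover, "turnover")
  prevalence * beds * turnover * occupancy
}

#' Annual ward-level oxygen need
#'
#' Annual medical oxygen need of a ward: the volume needed by one typical
#' patient multiplied by the expected number of hypoxaemic patients per
#' year.
#'
#' @param volume_litres Per-patient volume in litres
#'   (see [per_patient_volume()]).
#' @param patients_per_year Expected hypoxaemic patients per year
#'   (see [caseload()]).
#' @return Annual need in litres (vectorised).
#' @examples
#' ward_annual_need(4320, 100)     # 432000 L
#' ward_annual_need(100800, 125)   # 12600000 L
#' @export
ward_annual_need <- function(volume_litres, patients_per_year) {
  stop_if_bad_nonneg(volume_litres, "volume_litres")
  stop_if_bad_nonneg(patients_per_year, "patients_per_year")
  volume_litres * patients_per_year
}

#' Monthly litres from an annual volume
#'
#' The model is a static annual expectation; monthly figures are the annual
#' volume divided by 12.
#'
#' @param annual_litres Annual volume in litres (>= 0).
#' @return Monthly volume in litres.
#' @export
monthly_litres <- function(annual_litres) {
  stop_if_bad_nonneg(annual_litres, "annual_litres")
  annual_litres / 12
}

#' Facility-type total from a representative per-facility need
#'
#' Scales the annual need of one representative facility of a type by the
#' number of facilities of that type.
#'
#' @param facility_count Number of facilities of the type (>= 0).
#' @param per_facility_annual Annual need of one facility, litres (>= 0).
#' @return Annual need of the whole facility type, litres.
#' @export
typelevel_need <- function(facility_count, per_facility_annual) {
  stop_if_bad_nonneg(facility_count, "facility_count")
  stop_if_bad_nonneg(per_facility_annual, "per_facility_annual")
  facility_count * per_facility_annual
}

#' Validate a facility roster
#'
#' A roster is a long table with one row per facility-ward:
#' `facility_id, facility_type, region, ward, beds`.  Every `ward` must
#' resolve in the assumption registry and every `facility_type` in the
#' facility-type registry; bed counts must be non-negative integers; a
#' facility must not repeat a ward and must not span several types or
#' regions.
#'
#' @param roster A roster data frame.
#' @param assumptions Ward-assumption registry
#'   (default [default_ward_assumptions()]).
#' @param type_params Facility-type registry
#'   (default [default_facility_type_params()]).
#' @return The validated roster as a tibble.
#' @export
validate_roster <- function(roster,
                            assumptions = default_ward_assumptions(),
                            type_params = default_facility_type_params()) {
  roster <- tibble::as_tibble(roster)
  required <- c("facility_id", "facility_type", "region", "ward", "beds")
  missing <- setdiff(required, names(roster))
  if (length(missing) > 0) {
    abort(paste0("roster: missing column(s): ", paste(missing, collapse = ", ")))
  }
  check_field(roster, "beds", function(v) is.finite(v) & v >= 0 & v == floor(v),
              "must be a non-negative integer", context = "roster",
              label_col = "facility_id")
  unknown_ward <- setdiff(unique(roster$ward), assumptions$ward)
  if (length(unknown_ward) > 0) {
    abort(paste0("roster: ward label(s) not in assumption registry: ",
                 paste(unknown_ward, collapse = ", ")))
  }
  unknown_type <- setdiff(unique(roster$facility_type), type_params$type)
  if (length(unknown_type) > 0) {
    abort(paste0("roster: facility type(s) not in registry: ",
                 paste(unknown_type, collapse = ", ")))
  }
  dup <- roster |>
    dplyr::count(.data$facility_id, .data$ward) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("roster: facility '", dup$facility_id[1],
                 "' repeats ward '", dup$ward[1], "'"))
  }
  multi <- roster |>
    dplyr::distinct(.data$facility_id, .data$facility_type, .data$region) |>
    dplyr::count(.data$facility_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    abort(paste0("roster: facility '", multi$facility_id[1],
                 "' has inconsistent type/region across rows"))
  }
  roster
}

#' Per-(facility, ward) demand components
#'
#' Expands a roster against the assumption and facility-type registries into
#' one row per facility-ward with the per-patient volume, expected annual
#' caseload and annual litres.  This is the elementary table every roll-up
#' sums over; the turnover rate is a facility-type property applied to all
#' wards of the facility.
#'
#' @inheritParams validate_roster
#' @param occupancy Average occupancy multiplier in `[0, 1]` (default 1).
#' @return A tibble with columns `facility_id`, `facility_type`, `region`,
#'   `ward`, `beds`, `per_patient_litres`, `expected_hypoxaemic_patients`,
#'   `annual_litres`.
#' @export
demand_components <- function(roster,
                              assumptions = default_ward_assumptions(),
                              type_params = default_facility_type_params(),
                              occupancy = 1) {
  assumptions <- validate_ward_assumptions(assumptions)
  type_params <- validate_facility_type_params(type_params)
  roster <- validate_roster(roster, assumptions, type_params)
  roster |>
    dplyr::left_join(assumptions, by = "ward") |>
    dplyr::left_join(
      dplyr::select(type_params, "type", "annual_bed_turnover"),
      by = c(facility_type = "type")
    ) |>
    dplyr::mutate(
      per_patient_litres = per_patient_volume(.data$flow_lpm,
                                              .data$duration_hours),
      expected_hypoxaemic_patients = caseload(.data$prevalence, .data$beds,
                                              .data$annual_bed_turnover,
                                              occupancy),
      annual_litres = ward_annual_need(.data$per_patient_litres,
                                       .data$expected_hypoxaemic_patients)
    ) |>
    dplyr::select("facility_id", "facility_type", "region", "ward", "beds",
                  "per_patient_litres", "expected_hypoxaemic_patients",
                  "annual_litres")
}

new_demand_result <- function(grouping, group_key, annual_litres,
                              expected_patients) {
  tibble::tibble(
    grouping = grouping,
    group_key = group_key,
    annual_litres = annual_litres,
    monthly_litres = annual_litres / 12,
    expected_hypoxaemic_patients = expected_patients
  )
}

#' Facility-level annual oxygen demand
#'
#' Sums ward-level annual needs within each facility.
#'
#' @inheritParams demand_components
#' @return A demand-result tibble (`grouping = "facility"`) with columns
#'   `grouping`, `group_key`, `annual_litres`, `monthly_litres`,
#'   `expected_hypoxaemic_patients`, plus the carry-through columns
#'   `facility_type` and `region` used by [rollup_demand()].
#' @examples
#' roster <- tibble::tibble(
#'   facility_id = "hf1", facility_type = "district", region = "R01",
#'   ward = "neonatology", beds = 10L
#' )
#' facility_demand(roster)
#' @export
facility_demand <- function(roster,
                            assumptions = default_ward_assumptions(),
                            type_params = default_facility_type_params(),
                            occupancy = 1) {
  comp <- demand_components(roster, assumptions, type_params, occupancy)
  agg <- comp |>
    dplyr::group_by(.data$facility_id, .data$facility_type, .data$region) |>
    dplyr::summarise(
      annual_litres = sum(.data$annual_litres),
      expected_hypoxaemic_patients = sum(.data$expected_hypoxaemic_patients),
      .groups = "drop"
    )
  dplyr::bind_cols(
    new_demand_result("facility", agg$facility_id, agg$annual_litres,
                      agg$expected_hypoxaemic_patients),
    agg[c("facility_type", "region")]
  )
}

#' Roll facility demand up to facility type, region, or country
#'
#' Groups a facility-level demand table and sums annual litres and expected
#' caseloads.  The national total equals the sum over any complete
#' partition of the facilities (by type or by region).
#'
#' @param demand A facility-level demand table from [facility_demand()].
#' @param grouping One of `"facility_type"`, `"region"`, `"national"`.
#' @param facility_index Optional tibble `facility_id, facility_type,
#'   region` used to resolve groups when `demand` lacks the carry-through
#'   columns.  Every facility in `demand` must appear in it.
#' @return A demand-result tibble, one row per group (one row for
#'   `"national"`, keyed `"national"`).
#' @export
rollup_demand <- function(demand,
                          grouping = c("facility_type", "region", "national"),
                          facility_index = NULL) {
  grouping <- match.arg(grouping)
  demand <- tibble::as_tibble(demand)
  if (!is.null(facility_index)) {
    idx <- dplyr::distinct(
      tibble::as_tibble(facility_index),
      .data$facility_id, .data$facility_type, .data$region
    )
    missing <- setdiff(demand$group_key, idx$facility_id)
    if (length(missing) > 0) {
      abort(paste0("rollup_demand: facility id(s) missing from index: ",
                   paste(head(missing, 5), collapse = ", ")))
    }
    demand <- demand |>
      dplyr::select(-dplyr::any_of(c("facility_type", "region"))) |>
      dplyr::left_join(idx, by = c(group_key = "facility_id"))
  }
  key <- switch(grouping,
    facility_type = demand$facility_type,
    region = demand$region,
    national = rep("national", nrow(demand))
  )
  if (grouping != "national" && (is.null(key) || anyNA(key))) {
    abort(paste0("rollup_demand: cannot resolve ", grouping,
                 " for every facility; supply facility_index"))
  }
  agg <- tibble::tibble(
    key = key,
    annual_litres = demand$annual_litres,
    patients = demand$expected_hypoxaemic_patients
  ) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(
      annual_litres = sum(.data$annual_litres),
      patients = sum(.data$patients),
      .groups = "drop"
    )
  new_demand_result(grouping, agg$key, agg$annual_litres, agg$patients)
}

#' Ward-level national demand
#'
#' Sums the elementary demand table across facilities within each ward
#' type, giving the national demand profile by ward/department.
#'
#' @inheritParams demand_components
#' @return A demand-result tibble (`grouping = "ward"`).
#' @export
ward_demand <- function(roster,
                        assumptions = default_ward_assumptions(),
                        type_params = default_facility_type_params(),
                        occupancy = 1) {
  comp <- demand_components(roster, assumptions, type_params, occupancy)
  agg <- comp |>
    dplyr::group_by(.data$ward) |>
    dplyr::summarise(
      annual_litres = sum(.data$annual_litres),
      patients = sum(.data$expected_hypoxaemic_patients),
      .groups = "drop"
    )
  new_demand_result("ward", agg$ward, agg$annual_litres, agg$patients)
}

stop_if_bad_nonneg <- function(v, name) {
  if (!is.numeric(v) || any(!is.finite(v) | v < 0)) {
    abort(paste0(name, " must be finite and >= 0"))
  }
  invisible(v)
}

stop_if_bad_fraction <- function(v, name) {
  if (!is.numeric(v) || any(!is.finite(v) | v < 0 | v > 1)) {
    abort(paste0(name, " must be a fraction in [0, 1]"))
  }
  invisible(v)
}
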