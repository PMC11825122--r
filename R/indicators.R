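# Hypoxaemia-management and medical-oxygen-use indicators computed from
# monthly facility reports, DHIS-2 style, with stock-ledger validation.
#
# The source indicator list names indicators without formulas; every formula
# here is this package's definition, catalogued in indicator_catalogue() so
# the definitions are auditable and overridable.  Ratio indicators pool
# numerators and denominators across facilities (never the mean of facility
# percentages), which is robust to small denominators.

report_count_cols <- c(
  "stockout_days", "oximeters_functional", "oximeters_total",
  "respirators_functional", "respirators_total", "generators_functional",
  "generators_total", "cylinders_7500", "staff_trained", "staff_total",
  "hypoxaemic_patients", "patients_given_oxygen", "patients_treatment_success"
)
report_litre_cols <- c(
  "oxygen_opening", "oxygen_received", "oxygen_consumed", "oxygen_lost",
  "oxygen_closing"
)

#' Validate a panel of monthly facility reports
#'
#' A report panel has one row per facility-month with stock movements
#' (litres), equipment functionality, staffing and patient counts.
#' Structural invariants are enforced here: non-negative counts,
#' `patients_given_oxygen <= hypoxaemic_patients`,
#' `patients_treatment_success <= patients_given_oxygen`,
#' `staff_trained <= staff_total`, functional counts not exceeding totals,
#' and `stockout_days` bounded by the days in the report's month.  The
#' stock-ledger identity is checked separately by [validate_ledger()]
#' because violations there are reportable data-quality findings, not
#' structural errors.
#'
#' @param reports A data frame of monthly reports; `period` is `"YYYY-MM"`.
#' @return The validated panel as a tibble.
#' @export
validate_reports <- function(reports) {
  reports <- tibble::as_tibble(reports)
  required <- c("facility_id", "facility_type", "region", "period",
                "has_hypoxaemia_dept", report_litre_cols, report_count_cols)
  missing <- setdiff(required, names(reports))
  if (length(missing) > 0) {
    abort(paste0("reports: missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (col in report_count_cols) {
    check_field(reports, col,
                function(v) is.finite(v) & v >= 0 & v == floor(v),
                "must be a non-negative integer", context = "reports",
                label_col = "facility_id")
  }
  for (col in report_litre_cols) {
    check_field(reports, col, function(v) is.finite(v) & v >= 0,
                "must be finite and >= 0", context = "reports",
                label_col = "facility_id")
  }
  pair_le <- function(a, b) {
    bad <- which(reports[[a]] > reports[[b]])
    if (length(bad) > 0) {
      abort(paste0("reports: row '", reports$facility_id[bad[1]], "' (",
                   reports$period[bad[1]], "): ", a, " exceeds ", b))
    }
  }
  pair_le("patients_given_oxygen", "hypoxaemic_patients")
  pair_le("patients_treatment_success", "patients_given_oxygen")
  pair_le("staff_trained", "staff_total")
  pair_le("oximeters_functional", "oximeters_total")
  pair_le("respirators_functional", "respirators_total")
  pair_le("generators_functional", "generators_total")
  dim_days <- days_in_month(reports$period)
  bad <- which(reports$stockout_days > dim_days)
  if (length(bad) > 0) {
    abort(paste0("reports: row '", reports$facility_id[bad[1]], "' (",
                 reports$period[bad[1]],
                 "): stockout_days exceeds days in month"))
  }
  reports
}

#' Days in a "YYYY-MM" period
#' @param period Character vector of `"YYYY-MM"` periods.
#' @return Integer vector of month lengths.
#' @keywords internal
days_in_month <- function(period) {
  first <- as.Date(paste0(period, "-01"))
  if (anyNA(first)) {
    abort("period must be 'YYYY-MM'")
  }
  nxt <- seq_period(first)
  as.integer(nxt - first)
}

seq_period <- function(first) {
  # first day of the following month, vectorised
  y <- as.integer(format(first, "%Y"))
  m <- as.integer(format(first, "%m"))
  y2 <- ifelse(m == 12, y + 1, y)
  m2 <- ifelse(m == 12, 1, m + 1)
  as.Date(sprintf("%04d-%02d-01", y2, m2))
}

#' Validate the oxygen stock ledger of monthly reports
#'
#' Checks the stock identity
#' `opening + received - consumed - lost = closing` for every report, within
#' an absolute tolerance (default 1 litre).  Violations are returned with
#' their residuals, never silently corrected.
#'
#' @param reports A monthly report panel (or a single-row data frame).
#' @param tolerance Absolute tolerance in litres (default 1).
#' @return A tibble `facility_id, period, residual, pass`, where `residual`
#'   is `opening + received - consumed - lost - closing`.
#' @examples
#' r <- tibble::tibble(
#'   facility_id = "hf1", period = "2023-01", oxygen_opening = 1000,
#'   oxygen_received = 500, oxygen_consumed = 700, oxygen_lost = 0,
#'   oxygen_closing = 800
#' )
#' validate_ledger(r)  # passes: 1000 + 500 - 700 - 0 = 800
#' @export
validate_ledger <- function(reports, tolerance = 1) {
  reports <- tibble::as_tibble(reports)
  residual <- reports$oxygen_opening + reports$oxygen_received -
    reports$oxygen_consumed - reports$oxygen_lost - reports$oxygen_closing
  tibble::tibble(
    facility_id = reports$facility_id,
    period = reports$period,
    residual = residual,
    pass = abs(residual) <= tolerance
  )
}

# --- indicator computation ----------------------------------------------

indicator_value <- function(indicator_id, scope, key, period, value, unit,
                            status = "ok") {
  tibble::tibble(
    indicator_id = indicator_id, scope = scope, key = key, period = period,
    value = value, unit = unit, status = status
  )
}

scope_of <- function(by) if (is.null(by)) "national" else by

scope_keys <- function(reports, by) {
  if (is.null(by)) rep("national", nrow(reports)) else reports[[by]]
}

# Pooled percentage num/den per scope group; zero denominators yield a
# missing value with a reason rather than NaN.
pooled_pct <- function(reports, num_col, den_col, by, indicator_id, period) {
  df <- tibble::tibble(
    key = scope_keys(reports, by),
    num = reports[[num_col]],
    den = reports[[den_col]]
  ) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(num = sum(.data$num), den = sum(.data$den),
                     .groups = "drop")
  indicator_value(
    indicator_id, scope_of(by), df$key, period,
    ifelse(df$den > 0, 100 * df$num / df$den, NA_real_), "%",
    ifelse(df$den > 0, "ok", "undefined: zero denominator")
  )
}

filter_period <- function(reports, period) {
  if (is.null(period)) return(reports)
  out <- reports[reports$period == period, , drop = FALSE]
  if (nrow(out) == 0) {
    abort(paste0("no reports for period ", period))
  }
  out
}

#' Percentage of facilities with a hypoxaemia-management department
#'
#' `100 * (reporting facilities flagged as having a hypoxaemia/hypoxia
#' management department) / (reporting facilities)`, per scope group.
#'
#' @param reports A monthly report panel.
#' @param by Grouping column (`"region"`, `"facility_type"`) or `NULL` for
#'   national.
#' @param period Optional `"YYYY-MM"` filter; with `NULL`, each facility
#'   counts once (its flag is a facility property).
#' @return An indicator-value tibble.
#' @export
pct_with_hypoxaemia_dept <- function(reports, by = NULL, period = NULL) {
  reports <- filter_period(tibble::as_tibble(reports), period)
  if (nrow(reports) == 0) abort("pct_with_hypoxaemia_dept: empty report set")
  fac <- tibble::tibble(
    facility_id = reports$facility_id,
    key = scope_keys(reports, by),
    flag = reports$has_hypoxaemia_dept
  ) |>
    dplyr::group_by(.data$facility_id, .data$key) |>
    dplyr::summarise(flag = any(.data$flag), .groups = "drop")
  agg <- fac |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(value = 100 * mean(.data$flag), .groups = "drop")
  indicator_value("hf_with_hypoxaemia_dept_pct", scope_of(by), agg$key,
                  period %||% "all", agg$value, "%")
}

#' Average medical-oxygen stock-out days during a quarter
#'
#' For each facility, stock-out days are summed over the quarter's three
#' months; the indicator is the mean of those facility sums per scope
#' group.  Facilities missing one of the quarter's months are excluded by
#' default (`missing = "exclude"`); `missing = "zero"` treats unreported
#' months as zero stock-out days.  The policy used is recorded in the
#' result's `missing_policy` attribute.
#'
#' @param reports A monthly report panel.
#' @param quarter Quarter label `"YYYY-Qn"`, e.g. `"2023-Q1"`.
#' @param by Grouping column or `NULL` for national.
#' @param missing `"exclude"` (default) or `"zero"`.
#' @return An indicator-value tibble (unit: days).
#' @export
mean_stockout_days <- function(reports, quarter, by = NULL,
                               missing = c("exclude", "zero")) {
  missing <- match.arg(missing)
  reports <- tibble::as_tibble(reports)
  months <- quarter_months(quarter)
  q <- reports[reports$period %in% months, , drop = FALSE]
  if (nrow(q) == 0) abort(paste0("no reports for quarter ", quarter))
  fac <- tibble::tibble(
    facility_id = q$facility_id,
    key = scope_keys(q, by),
    stockout_days = q$stockout_days
  ) |>
    dplyr::group_by(.data$facility_id, .data$key) |>
    dplyr::summarise(total = sum(.data$stockout_days),
                     n_months = dplyr::n(), .groups = "drop")
  if (missing == "exclude") {
    fac <- fac[fac$n_months == length(months), , drop = FALSE]
    if (nrow(fac) == 0) {
      abort(paste0("mean_stockout_days: no facility reported all months of ",
                   quarter))
    }
  }
  agg <- fac |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(value = mean(.data$total), .groups = "drop")
  out <- indicator_value("stockout_days_quarterly_mean", scope_of(by),
                         agg$key, quarter, agg$value, "days")
  attr(out, "missing_policy") <- missing
  out
}

quarter_months <- function(quarter) {
  m <- regmatches(quarter, regexec("^([0-9]{4})-Q([1-4])$", quarter))[[1]]
  if (length(m) != 3) abort("quarter must be 'YYYY-Qn' with n in 1..4")
  first <- (as.integer(m[3]) - 1) * 3 + 1
  sprintf("%s-%02d", m[2], first:(first + 2))
}

#' Proportion of functioning oxygen-related devices
#'
#' Two conventions, following the indicator set's phrasing:
#' * `pulse_oximeter` — device-level pooling:
#'   `100 * sum(functional) / sum(total)` per scope group.
#' * `respirator`, `generator` — facility-level, stratified by facility
#'   category: `100 * (facilities with >= 1 functional device) /
#'   (facilities)`, one value per category (the `by` argument is ignored
#'   for these; the category is the scope).
#'
#' Zero denominators are emitted as missing values with a reason.
#'
#' @param reports A monthly report panel.
#' @param device `"pulse_oximeter"`, `"respirator"` or `"generator"`.
#' @param by Grouping column or `NULL` (pulse oximeters only).
#' @param period Optional `"YYYY-MM"` filter.
#' @param category_map Named character vector mapping `facility_type` to a
#'   category label (default: general = "1st", central = "2nd",
#'   regional = "3rd", district = "4th"; unmapped types keep their own
#'   name).
#' @return An indicator-value tibble.
#' @export
proportion_functional <- function(reports,
                                  device = c("pulse_oximeter", "respirator",
                                             "generator"),
                                  by = NULL, period = NULL,
                                  category_map = default_category_map()) {
  device <- match.arg(device)
  reports <- filter_period(tibble::as_tibble(reports), period)
  period_lab <- period %||% "all"
  if (device == "pulse_oximeter") {
    return(
      pooled_pct(reports, "oximeters_functional", "oximeters_total", by,
                 "oximeters_functional_pct", period_lab)
    )
  }
  func_col <- paste0(device, "s_functional")
  id <- paste0("hf_with_functional_", device, "_pct")
  cat <- category_map[reports$facility_type]
  cat[is.na(cat)] <- reports$facility_type[is.na(cat)]
  fac <- tibble::tibble(
    facility_id = reports$facility_id,
    key = unname(cat),
    func = reports[[func_col]]
  ) |>
    dplyr::group_by(.data$facility_id, .data$key) |>
    dplyr::summarise(has_func = any(.data$func >= 1), .groups = "drop")
  agg <- fac |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(value = 100 * mean(.data$has_func), .groups = "drop")
  indicator_value(id, "facility_category", agg$key, period_lab, agg$value, "%")
}

#' Default facility-type to category mapping
#'
#' Maps the four shipped hospital types to the 1st-4th facility categories
#' used by the category-stratified indicators.  The mapping is
#' configuration, not data: override it where the national classification
#' differs.
#'
#' @return A named character vector.
#' @export
default_category_map <- function() {
  c(general = "1st", central = "2nd", regional = "3rd", district = "4th")
}

#' Oxygen therapy coverage among hypoxaemic patients
#'
#' `100 * sum(patients_given_oxygen) / sum(hypoxaemic_patients)` pooled per
#' scope group.
#'
#' @inheritParams pct_with_hypoxaemia_dept
#' @return An indicator-value tibble.
#' @export
oxygen_therapy_coverage <- function(reports, by = NULL, period = NULL) {
  reports <- filter_period(tibble::as_tibble(reports), period)
  pooled_pct(reports, "patients_given_oxygen", "hypoxaemic_patients", by,
             "oxygen_therapy_coverage_pct", period %||% "all")
}

#' Therapeutic success rate of oxygen therapy
#'
#' `100 * sum(patients_treatment_success) / sum(patients_given_oxygen)`
#' pooled per scope group.
#'
#' @inheritParams pct_with_hypoxaemia_dept
#' @return An indicator-value tibble.
#' @export
therapeutic_success <- function(reports, by = NULL, period = NULL) {
  reports <- filter_period(tibble::as_tibble(reports), period)
  pooled_pct(reports, "patients_treatment_success", "patients_given_oxygen",
             by, "therapeutic_success_pct", period %||% "all")
}

#' Proportion of health workers trained in hypoxaemia management
#'
#' `100 * sum(staff_trained) / sum(staff_total)` pooled per scope group.
#'
#' @inheritParams pct_with_hypoxaemia_dept
#' @return An indicator-value tibble.
#' @export
training_coverage <- function(reports, by = NULL, period = NULL) {
  reports <- filter_period(tibble::as_tibble(reports), period)
  pooled_pct(reports, "staff_trained", "staff_total", by,
             "staff_trained_pct", period %||% "all")
}

#' Monthly stock and count indicators
#'
#' Sums, per scope group and period, the four stock-movement quantities
#' (litres of oxygen available at the start of the month, received,
#' consumed, and lost or damaged) and the total number of 7500 L cylinders
#' (containing medical oxygen or not — empties included).
#'
#' @inheritParams pct_with_hypoxaemia_dept
#' @param period A `"YYYY-MM"` period (required: stock levels are monthly
#'   states and must not be summed across months).
#' @return An indicator-value tibble with one row per quantity and group.
#' @export
stock_indicators <- function(reports, period, by = NULL) {
  reports <- filter_period(tibble::as_tibble(reports), period)
  cols <- c(oxygen_opening_litres = "oxygen_opening",
            oxygen_received_litres = "oxygen_received",
            oxygen_consumed_litres = "oxygen_consumed",
            oxygen_lost_litres = "oxygen_lost")
  key <- scope_keys(reports, by)
  rows <- purrr::imap(cols, function(col, id) {
    agg <- tibble::tibble(key = key, v = reports[[col]]) |>
      dplyr::group_by(.data$key) |>
      dplyr::summarise(value = sum(.data$v), .groups = "drop")
    indicator_value(id, scope_of(by), agg$key, period, agg$value, "litres")
  })
  cyl <- tibble::tibble(key = key, v = reports$cylinders_7500) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(value = sum(.data$v), .groups = "drop")
  dplyr::bind_rows(
    dplyr::bind_rows(rows),
    indicator_value("cylinders_7500_total", scope_of(by), cyl$key, period,
                    cyl$value, "count")
  )
}

#' The shipped indicator catalogue
#'
#' Machine-readable definitions of the hypoxaemia-management and
#' medical-oxygen-use indicator set: identifier, human-readable name, the
#' report fields pooled as numerator and denominator (where applicable),
#' the aggregation rule and the unit.  The catalogue is the single place
#' the definitions live, so they can be audited or overridden.
#'
#' @return A tibble with columns `indicator_id`, `name`, `numerator`,
#'   `denominator`, `aggregation`, `unit`.
#' @export
indicator_catalogue <- function() {
  tibble::tribble(
    ~indicator_id, ~name, ~numerator, ~denominator, ~aggregation, ~unit,
    "hf_with_hypoxaemia_dept_pct",
    "Percentage of facilities with a hypoxaemia/hypoxia management department",
    "has_hypoxaemia_dept", "facilities reporting", "facility share", "%",
    "stockout_days_quarterly_mean",
    "Average number of medical-oxygen stock-out days during the quarter",
    "stockout_days", NA, "mean of facility quarterly sums", "days",
    "oxygen_opening_litres",
    "Total medical oxygen available at the beginning of the month",
    "oxygen_opening", NA, "sum", "litres",
    "oxygen_received_litres",
    "Total medical oxygen received during the month",
    "oxygen_received", NA, "sum", "litres",
    "oxygen_consumed_litres",
    "Total medical oxygen consumed during the month",
    "oxygen_consumed", NA, "sum", "litres",
    "oxygen_lost_litres",
    "Total medical oxygen lost or damaged during the month",
    "oxygen_lost", NA, "sum", "litres",
    "oximeters_functional_pct",
    "Proportion of functioning pulse oximeters during the month",
    "oximeters_functional", "oximeters_total", "pooled ratio", "%",
    "hf_with_functional_respirator_pct",
    "Proportion of 1st-4th category facilities with functioning respirators",
    "respirators_functional >= 1", "facilities", "facility share by category",
    "%",
    "hf_with_functional_generator_pct",
    "Proportion of 1st-4th category facilities with a functioning oxygen generator",
    "generators_functional >= 1", "facilities", "facility share by category",
    "%",
    "cylinders_7500_total",
    "Total 7500 L medical oxygen cylinders (full or empty)",
    "cylinders_7500", NA, "sum", "count",
    "staff_trained_pct",
    "Proportion of health workers who received capacity building in hypoxaemia management",
    "staff_trained", "staff_total", "pooled ratio", "%",
    "oxygen_therapy_coverage_pct",
    "Proportion of hypoxaemic patients who received oxygen therapy",
    "patients_given_oxygen", "hypoxaemic_patients", "pooled ratio", "%",
    "therapeutic_success_pct",
    "Therapeutic success rate of oxygen therapy",
    "patients_treatment_success", "patients_given_oxygen", "pooled ratio", "%"
  )
}

#' Compute the full indicator set from a report panel
#'
#' Runs every indicator in [indicator_catalogue()] over a validated report
#' panel: monthly indicators for each period present, and the quarterly
#' stock-out indicator for each complete quarter covered by the panel.
#'
#' @param reports A monthly report panel.
#' @param by Grouping column (`"region"`, `"facility_type"`) or `NULL` for
#'   national values.
#' @return A tibble of indicator values (`indicator_id, scope, key, period,
#'   value, unit, status`).
#' @export
compute_indicators <- function(reports, by = NULL) {
  reports <- validate_reports(reports)
  periods <- sort(unique(reports$period))
  monthly <- purrr::map(periods, function(p) {
    dplyr::bind_rows(
      pct_with_hypoxaemia_dept(reports, by, p),
      proportion_functional(reports, "pulse_oximeter", by, p),
      proportion_functional(reports, "respirator", period = p),
      proportion_functional(reports, "generator", period = p),
      oxygen_therapy_coverage(reports, by, p),
      therapeutic_success(reports, by, p),
      training_coverage(reports, by, p),
      stock_indicators(reports, p, by)
    )
  })
  quarters <- unique(sprintf(
    "%s-Q%d",
    substr(periods, 1, 4),
    (as.integer(substr(periods, 6, 7)) - 1) %/% 3 + 1
  ))
  complete <- quarters[purrr::map_lgl(quarters, function(q) {
    all(quarter_months(q) %in% periods)
  })]
  quarterly <- purrr::map(complete, function(q) {
    mean_stockout_days(reports, q, by)
  })
  dplyr::bind_rows(dplyr::bind_rows(monthly), dplyr::bind_rows(quarterly))
}
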