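# Domain registries: ward-level clinical assumptions and facility-type
# parameters, with CSV I/O and validation.

#' Built-in ward-level clinical assumptions
#'
#' Returns the default registry of clinical assumptions used to quantify
#' medical oxygen needs: for each ward/department, the prevalence of
#' hypoxaemia among admitted patients, the typical oxygen flow rate
#' prescribed to a hypoxaemic patient, and the duration of oxygen therapy
#' for a typical case.  The nine shipped wards and their values follow the
#' UNICEF-style oxygen system planning assumptions used in national
#' quantification exercises.
#'
#' Prevalence is stored as a fraction in `[0, 1]` (the percentage scale used
#' in source tables is divided by 100 on load); duration is stored in hours.
#'
#' @return A tibble with columns `ward` (character), `prevalence`
#'   (fraction), `flow_lpm` (litres per minute) and `duration_hours`.
#' @examples
#' default_ward_assumptions()
#' @export
default_ward_assumptions <- function() {
  x <- tibble::tribble(
    ~ward,               ~prevalence, ~flow_lpm, ~duration_hours,
    "outpatient",               0.00,         5,               1,
    "adult_medicine",           0.06,         6,             144,
    "paediatrics",              0.10,         2,              72,
    "neonatology",              0.20,         2,              72,
    "intensive_care",           1.00,         6,              96,
    "operating_theatre",        1.00,         8,               6,
    "emergency",                0.40,         6,              16,
    "maternity",                0.13,         5,              12,
    "recovery",                 1.00,         5,               6
  )
  validate_ward_assumptions(x)
}

#' Built-in facility-type parameters
#'
#' Default registry of hospital categories for the 99-facility national
#' assessment frame: number of facilities, total bed complement, and annual
#' bed turnover rate (admitted patients per bed per year) for each of the
#' four hospital types.
#'
#' @return A tibble with columns `type`, `facility_count`, `total_beds`,
#'   `annual_bed_turnover`.
#' @examples
#' default_facility_type_params()
#' sum(default_facility_type_params()$facility_count)  # 99
#' @export
default_facility_type_params <- function() {
  x <- tibble::tribble(
    ~type,      ~facility_count, ~total_beds, ~annual_bed_turnover,
    "general",               4L,        919L,                   41,
    "central",              13L,       2595L,                   96,
    "regional",             15L,       2487L,                   72,
    "district",             67L,       5090L,                   58
  )
  validate_facility_type_params(x)
}

#' Validate a ward-assumption registry
#'
#' Checks column presence and types, range constraints (prevalence in
#' `[0, 1]`, non-negative finite flow and duration) and ward-name
#' uniqueness.  Errors name the offending row and field.
#'
#' @param x A data frame with columns `ward`, `prevalence`, `flow_lpm`,
#'   `duration_hours`.
#' @return The validated registry as a tibble, invisibly usable in pipes.
#' @export
validate_ward_assumptions <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("ward", "prevalence", "flow_lpm", "duration_hours")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("ward assumptions: missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  check_field(x, "prevalence", function(v) is.finite(v) & v >= 0 & v <= 1,
              "must be a fraction in [0, 1]", context = "ward assumptions",
              label_col = "ward")
  check_field(x, "flow_lpm", function(v) is.finite(v) & v >= 0,
              "must be finite and >= 0", context = "ward assumptions",
              label_col = "ward")
  check_field(x, "duration_hours", function(v) is.finite(v) & v >= 0,
              "must be finite and >= 0", context = "ward assumptions",
              label_col = "ward")
  if (anyDuplicated(x$ward)) {
    dup <- unique(x$ward[duplicated(x$ward)])
    abort(paste0("ward assumptions: duplicate ward name(s): ",
                 paste(dup, collapse = ", ")))
  }
  x
}

#' Validate a facility-type parameter registry
#'
#' @param x A data frame with columns `type`, `facility_count`,
#'   `total_beds`, `annual_bed_turnover`.
#' @return The validated registry as a tibble.
#' @export
validate_facility_type_params <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("type", "facility_count", "total_beds", "annual_bed_turnover")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("facility-type params: missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  for (col in c("facility_count", "total_beds")) {
    check_field(x, col, function(v) is.finite(v) & v >= 0 & v == floor(v),
                "must be a non-negative integer",
                context = "facility-type params", label_col = "type")
  }
  check_field(x, "annual_bed_turnover", function(v) is.finite(v) & v >= 0,
              "must be finite and >= 0",
              context = "facility-type params", label_col = "type")
  if (anyDuplicated(x$type)) {
    dup <- unique(x$type[duplicated(x$type)])
    abort(paste0("facility-type params: duplicate type name(s): ",
                 paste(dup, collapse = ", ")))
  }
  x$facility_count <- as.integer(x$facility_count)
  x$total_beds <- as.integer(x$total_beds)
  x
}

# Shared range check: errors name row label and field.
check_field <- function(x, col, ok, msg, context, label_col) {
  if (nrow(x) == 0) return(invisible(x))
  if (!is.numeric(x[[col]])) {
    abort(paste0(context, ": column '", col, "' must be numeric"))
  }
  bad <- which(!ok(x[[col]]))
  if (length(bad) > 0) {
    label <- x[[label_col]][bad[1]]
    abort(paste0(context, ": row '", label, "', field '", col, "' ", msg,
                 " (got ", format(x[[col]][bad[1]]), ")"))
  }
  invisible(x)
}

#' Load ward assumptions from a CSV file or data frame
#'
#' Reads an assumption table with columns
#' `ward,prevalence_pct,flow_lpm,duration,duration_unit`
#' (`duration_unit` is `"hours"` or `"days"`; days are converted to hours by
#' multiplying by 24).  Prevalence is given in percent and stored as a
#' fraction.  With `source = NULL` the built-in defaults are returned.
#'
#' @param source Path to a CSV file, a data frame in the external schema, or
#'   `NULL` for the shipped defaults.
#' @return A validated ward-assumption registry
#'   (see [default_ward_assumptions()]).
#' @examples
#' load_ward_assumptions()  # defaults
#' @export
load_ward_assumptions <- function(source = NULL) {
  if (is.null(source)) {
    return(default_ward_assumptions())
  }
  raw <- read_table_source(source, context = "ward assumptions")
  required <- c("ward", "prevalence_pct", "flow_lpm", "duration", "duration_unit")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("ward assumptions: missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad_unit <- !raw$duration_unit %in% c("hours", "days")
  if (any(bad_unit)) {
    abort(paste0("ward assumptions: row '", raw$ward[which(bad_unit)[1]],
                 "', field 'duration_unit' must be 'hours' or 'days' (got '",
                 raw$duration_unit[which(bad_unit)[1]], "')"))
  }
  check_field(raw, "prevalence_pct",
              function(v) is.finite(v) & v >= 0 & v <= 100,
              "must be a percentage in [0, 100]",
              context = "ward assumptions", label_col = "ward")
  x <- tibble::tibble(
    ward = as.character(raw$ward),
    prevalence = raw$prevalence_pct / 100,
    flow_lpm = as.numeric(raw$flow_lpm),
    duration_hours = as.numeric(raw$duration) *
      ifelse(raw$duration_unit == "days", 24, 1)
  )
  validate_ward_assumptions(x)
}

#' Write ward assumptions in the external CSV schema
#'
#' Inverse of [load_ward_assumptions()]: prevalence is written in percent and
#' duration in hours, so a write/load round trip reproduces the registry.
#'
#' @param x A ward-assumption registry.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ward_assumptions <- function(x, path) {
  x <- validate_ward_assumptions(x)
  out <- tibble::tibble(
    ward = x$ward,
    prevalence_pct = x$prevalence * 100,
    flow_lpm = x$flow_lpm,
    duration = x$duration_hours,
    duration_unit = "hours"
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Load facility-type parameters from a CSV file or data frame
#'
#' Reads a table with columns
#' `type,facility_count,total_beds,annual_bed_turnover`.  With
#' `source = NULL` the built-in defaults are returned.  An empty source (a
#' header-only file) yields an empty registry.
#'
#' @inheritParams load_ward_assumptions
#' @return A validated facility-type registry
#'   (see [default_facility_type_params()]).
#' @export
load_facility_type_params <- function(source = NULL) {
  if (is.null(source)) {
    return(default_facility_type_params())
  }
  raw <- read_table_source(source, context = "facility-type params")
  validate_facility_type_params(raw)
}

#' Write facility-type parameters in the external CSV schema
#'
#' @param x A facility-type registry.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_facility_type_params <- function(x, path) {
  x <- validate_facility_type_params(x)
  readr::write_csv(x, path)
  invisible(path)
}

#' Mean annual bed turnover across facility types
#'
#' The headline turnover summary is the unweighted arithmetic mean of the
#' per-type annual bed turnover rates (each hospital category counts once,
#' regardless of its bed complement); a bed-weighted mean is available via
#' `weight = "beds"`.
#'
#' @param params A facility-type registry.
#' @param weight `"none"` (default, unweighted mean) or `"beds"`
#'   (weighted by `total_beds`).
#' @return A single numeric turnover rate (patients per bed per year).
#' @examples
#' mean_turnover(default_facility_type_params())  # 66.75
#' @export
mean_turnover <- function(params, weight = c("none", "beds")) {
  params <- validate_facility_type_params(params)
  weight <- match.arg(weight)
  if (nrow(params) == 0) {
    abort("mean_turnover: empty facility-type registry")
  }
  if (weight == "none") {
    mean(params$annual_bed_turnover)
  } else {
    sum(params$annual_bed_turnover * params$total_beds) / sum(params$total_beds)
  }
}

# Accept a file path or a data frame for any tabular source.
read_table_source <- function(source, context) {
  if (is.data.frame(source)) {
    return(tibble::as_tibble(source))
  }
  if (is.character(source) && length(source) == 1) {
    if (!file.exists(source)) {
      abort(paste0(context, ": file not found: ", source))
    }
    return(readr::read_csv(source, show_col_types = FALSE, progress = FALSE))
  }
  abort(paste0(context, ": source must be a file path or a data frame"))
}
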