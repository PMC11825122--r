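# Equipment gap analysis: coverage of requirements by functional equipment,
# cylinder-equivalent volume conversion, and scoped gap reports.

#' Equipment coverage and absolute gap
#'
#' Compares available functional equipment against a required count.
#' Coverage is `available / required` and may exceed 1 (a surplus); the
#' absolute gap is `max(required - available, 0)`.  With no requirement and
#' nothing available, coverage is 1 (a vacuously met need); a surplus
#' against a zero requirement is reported as `Inf` with a zero gap.
#'
#' @param available Functional units available (>= 0, vectorised).
#' @param required Units required (>= 0, vectorised).
#' @return A tibble with columns `available`, `required`, `coverage`,
#'   `absolute_gap`.
#' @examples
#' coverage(50, 100)   # half the need met, gap 50
#' coverage(108, 100)  # 8% surplus, gap 0
#' @export
coverage <- function(available, required) {
  stop_if_bad_nonneg(available, "available")
  stop_if_bad_nonneg(required, "required")
  n <- max(length(available), length(required))
  available <- rep_len(available, n)
  required <- rep_len(required, n)
  cov <- ifelse(required > 0, available / required,
                ifelse(available > 0, Inf, 1))
  tibble::tibble(
    available = available,
    required = required,
    coverage = cov,
    absolute_gap = pmax(required - available, 0)
  )
}

#' Convert an oxygen volume to cylinder equivalents
#'
#' Expresses a gaseous-oxygen volume as a number of standard cylinders.
#' Three conventions are supported: `"exact"` (the real-valued ratio),
#' `"procurement"` (ceiling — you cannot buy a fraction of a cylinder), and
#' `"reporting"` (the exact ratio rounded to 3 significant figures, the
#' convention used in headline summaries).
#'
#' @param volume_litres Volume of gaseous oxygen in litres (>= 0).
#' @param cylinder_size Capacity of one cylinder in litres of gaseous
#'   oxygen (> 0, default 7500, a large "J-size" cylinder).
#' @param mode `"exact"`, `"procurement"` or `"reporting"`.
#' @return Cylinder count (real for `"exact"`/`"reporting"`, integer-valued
#'   for `"procurement"`).
#' @examples
#' cylinder_equivalents(140e6, 7500, "reporting")    # 18700
#' cylinder_equivalents(140e6, 7500, "procurement")  # 18667
#' @export
cylinder_equivalents <- function(volume_litres, cylinder_size = 7500,
                                 mode = c("exact", "procurement", "reporting")) {
  mode <- match.arg(mode)
  stop_if_bad_nonneg(volume_litres, "volume_litres")
  if (!is.numeric(cylinder_size) || any(!is.finite(cylinder_size) | cylinder_size <= 0)) {
    abort("cylinder_size must be finite and > 0")
  }
  exact <- volume_litres / cylinder_size
  switch(mode,
    exact = exact,
    procurement = ceiling(exact),
    reporting = signif(exact, 3)
  )
}

#' Volume gap left by a cylinder inventory
#'
#' Volume of demand (litres) not covered by the functional cylinder stock,
#' clamped at zero: `max(demand - functional * cylinder_size, 0)`.
#'
#' @param demand_litres Demand volume in litres (>= 0).
#' @param functional_cylinders Functional cylinders available (>= 0).
#' @param cylinder_size Litres of gaseous oxygen per cylinder (default 7500).
#' @return Uncovered volume in litres (vectorised).
#' @examples
#' cylinder_volume_gap(150000, 10)  # 75000 L short
#' @export
cylinder_volume_gap <- function(demand_litres, functional_cylinders,
                                cylinder_size = 7500) {
  stop_if_bad_nonneg(demand_litres, "demand_litres")
  stop_if_bad_nonneg(functional_cylinders, "functional_cylinders")
  stop_if_bad_nonneg(cylinder_size, "cylinder_size")
  pmax(demand_litres - functional_cylinders * cylinder_size, 0)
}

#' Validate an equipment inventory table
#'
#' One row per facility and device class:
#' `facility_id, device_class, functional, total, cylinder_size`
#' (`cylinder_size` is used for `oxygen_cylinder` rows and may be `NA`
#' elsewhere).  Functional counts may not exceed totals.
#'
#' @param inventory An inventory data frame.
#' @return The validated inventory as a tibble.
#' @export
validate_inventory <- function(inventory) {
  inventory <- tibble::as_tibble(inventory)
  required <- c("facility_id", "device_class", "functional", "total")
  missing <- setdiff(required, names(inventory))
  if (length(missing) > 0) {
    abort(paste0("inventory: missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"cylinder_size" %in% names(inventory)) {
    inventory$cylinder_size <- ifelse(
      inventory$device_class == "oxygen_cylinder", 7500, NA_real_)
  }
  known <- c("oxygen_concentrator", "pulse_oximeter", "patient_monitor",
             "oxygen_cylinder")
  unknown <- setdiff(unique(inventory$device_class), known)
  if (length(unknown) > 0) {
    abort(paste0("inventory: unknown device class(es): ",
                 paste(unknown, collapse = ", ")))
  }
  for (col in c("functional", "total")) {
    check_field(inventory, col,
                function(v) is.finite(v) & v >= 0 & v == floor(v),
                "must be a non-negative integer", context = "inventory",
                label_col = "facility_id")
  }
  bad <- which(inventory$functional > inventory$total)
  if (length(bad) > 0) {
    abort(paste0("inventory: row '", inventory$facility_id[bad[1]],
                 "' (", inventory$device_class[bad[1]],
                 "): functional exceeds total"))
  }
  inventory
}

#' Scoped equipment gap report
#'
#' Aggregates functional equipment to a scope (national, region, or
#' facility type), compares it with required counts, and, for cylinders,
#' converts the uncovered demand volume into litres and cylinder
#' equivalents.  Gaps are clamped at zero *within* each scope group:
#' surpluses in one group never offset deficits in another, so clamped gaps
#' are not additive across scopes (the sum of regional gaps is >= the
#' national gap).
#'
#' @param demand A facility-level demand table from [facility_demand()]
#'   (used for the cylinder volume requirement).
#' @param inventory An equipment inventory (see [validate_inventory()]).
#' @param requirements Device requirements from planning norms: a tibble
#'   `scope, key, device_class, required` giving required counts per scope
#'   group for non-cylinder devices.  May be `NULL` (cylinders only).
#' @param scope `"national"`, `"region"` or `"facility_type"`.
#' @param cylinder_size Litres per cylinder for requirement conversion
#'   (default 7500).
#' @param demand_basis `"monthly"` (default) or `"annual"`: which demand
#'   volume the cylinder stock is required to hold.  The shipped convention
#'   sizes cylinder stock to one month of consumption.
#' @return A tibble `scope, key, device_class, required,
#'   available_functional, coverage, absolute_gap, volume_gap_litres`
#'   (volume columns are `NA` for non-cylinder devices).
#' @export
gap_report <- function(demand, inventory, requirements = NULL,
                       scope = c("national", "region", "facility_type"),
                       cylinder_size = 7500,
                       demand_basis = c("monthly", "annual")) {
  scope <- match.arg(scope)
  demand_basis <- match.arg(demand_basis)
  inventory <- validate_inventory(inventory)
  demand <- tibble::as_tibble(demand)

  idx <- dplyr::distinct(demand, .data$group_key, .data$facility_type,
                         .data$region)
  scope_key <- function(df) {
    switch(scope,
      national = rep("national", nrow(df)),
      region = df$region,
      facility_type = df$facility_type
    )
  }

  demand_vol <- switch(demand_basis,
    monthly = demand$monthly_litres,
    annual = demand$annual_litres
  )
  demand_by_key <- tibble::tibble(key = scope_key(demand), vol = demand_vol) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(demand_litres = sum(.data$vol), .groups = "drop")

  inv <- inventory |>
    dplyr::left_join(idx, by = c(facility_id = "group_key"))
  if (anyNA(inv$facility_type)) {
    missing <- unique(inv$facility_id[is.na(inv$facility_type)])
    abort(paste0("gap_report: inventory facility id(s) not in demand table: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  inv$key <- scope_key(inv)

  # Cylinder rows: requirement is the demand volume expressed in cylinders.
  cyl <- inv |>
    dplyr::filter(.data$device_class == "oxygen_cylinder") |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(available_functional = sum(.data$functional),
                     .groups = "drop") |>
    dplyr::right_join(demand_by_key, by = "key") |>
    dplyr::mutate(
      available_functional = dplyr::coalesce(.data$available_functional, 0L),
      required = .data$demand_litres / cylinder_size,
      device_class = "oxygen_cylinder",
      volume_gap_litres = cylinder_volume_gap(.data$demand_litres,
                                              .data$available_functional,
                                              cylinder_size)
    )
  cyl_cov <- coverage(cyl$available_functional, cyl$required)
  cyl <- cyl |>
    dplyr::mutate(coverage = cyl_cov$coverage,
                  absolute_gap = cyl_cov$absolute_gap) |>
    dplyr::select("key", "device_class", "required", "available_functional",
                  "coverage", "absolute_gap", "volume_gap_litres")

  out <- cyl
  if (!is.null(requirements)) {
    req <- tibble::as_tibble(requirements) |>
      dplyr::filter(.data$scope == !!scope,
                    .data$device_class != "oxygen_cylinder")
    if (nrow(req) > 0) {
      avail <- inv |>
        dplyr::filter(.data$device_class != "oxygen_cylinder") |>
        dplyr::group_by(.data$key, .data$device_class) |>
        dplyr::summarise(available_functional = sum(.data$functional),
                         .groups = "drop")
      dev <- req |>
        dplyr::left_join(avail, by = c("key", "device_class")) |>
        dplyr::mutate(
          available_functional = dplyr::coalesce(.data$available_functional, 0L)
        )
      dev_cov <- coverage(dev$available_functional, dev$required)
      dev <- dev |>
        dplyr::mutate(coverage = dev_cov$coverage,
                      absolute_gap = dev_cov$absolute_gap,
                      volume_gap_litres = NA_real_) |>
        dplyr::select("key", "device_class", "required",
                      "available_functional", "coverage", "absolute_gap",
                      "volume_gap_litres")
      out <- dplyr::bind_rows(cyl, dev)
    }
  }
  out |>
    dplyr::mutate(scope = scope, .before = 1) |>
    dplyr::arrange(.data$device_class, .data$key)
}
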