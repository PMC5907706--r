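# Scenario file I/O. One schema, two carriers: YAML (.yaml/.yml) and JSON
# (.json). Every field is optional in a scenario file; omitted fields take the
# packaged base-case defaults, so a file containing only the inputs that
# differ from the base case is a complete scenario.

scenario_to_list <- function(config) {
  arm_to_list <- function(arm) {
    out <- unclass(arm)
    out$drug_unit_costs <- as.list(out$drug_unit_costs)
    out
  }
  bounds <- config$dsa_bounds
  list(
    n_patients = config$n_patients,
    nurse_rate = config$nurse_rate,
    surgeon_rate = config$surgeon_rate,
    revenue_per_operation = config$revenue_per_operation,
    intervention = arm_to_list(config$intervention),
    reference = arm_to_list(config$reference),
    rescue = purrr::pmap(config$rescue, function(component, prob, cost,
                                                 prob_low, prob_high) {
      list(component = component, prob = prob, cost = cost,
           prob_low = prob_low, prob_high = prob_high)
    }),
    dsa_bounds = purrr::pmap(bounds, function(parameter, path, low, high, type) {
      list(parameter = parameter, path = as.list(path), low = low, high = high,
           type = type)
    })
  )
}

arm_from_list <- function(lst) {
  arm_parameters(
    name = lst$name,
    p_failure = lst$p_failure,
    wait_before_surgery_min = lst$wait_before_surgery_min,
    n_instillation_sessions = lst$n_instillation_sessions,
    session_duration_min = lst$session_duration_min,
    surgeon_working_time_min = lst$surgeon_working_time_min,
    or_occupancy_min = lst$or_occupancy_min,
    extra_time_failure_min = lst$extra_time_failure_min,
    between_op_loss_min = lst$between_op_loss_min,
    drug_unit_costs = unlist(lst$drug_unit_costs),
    patients_per_vial = lst$patients_per_vial
  )
}

scenario_from_list <- function(lst) {
  scenario_config(
    n_patients = lst$n_patients,
    nurse_rate = lst$nurse_rate,
    surgeon_rate = lst$surgeon_rate,
    rescue = dplyr::bind_rows(purrr::map(lst$rescue, tibble::as_tibble)),
    intervention = arm_from_list(lst$intervention),
    reference = arm_from_list(lst$reference),
    revenue_per_operation = lst$revenue_per_operation,
    dsa_bounds = as_dsa_bounds(lst$dsa_bounds)
  )
}

read_scenario_file <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Scenario file not found: %s", path),
                 class = "bim_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    abort_validation(path, "scenario files must be .yaml, .yml or .json")
  }
}

merge_arm <- function(default, given, role) {
  allowed <- c("name", .arm_scalar_fields, "drug_unit_costs")
  unknown <- setdiff(names(given), allowed)
  if (length(unknown) > 0L) {
    abort_validation(paste(role, unknown[1], sep = "."), "unknown field")
  }
  # drug_unit_costs is replaced wholesale (element-wise merging would union
  # the default products with the file's).
  merged <- utils::modifyList(default,
                              given[setdiff(names(given), "drug_unit_costs")])
  if ("drug_unit_costs" %in% names(given)) {
    merged$drug_unit_costs <- given$drug_unit_costs
  }
  merged
}

#' Load a scenario file
#'
#' Reads a YAML or JSON scenario file, fills any omitted field with the
#' packaged base-case default, validates everything, and returns the
#' configuration. Unknown field names raise a validation error naming the
#' field; out-of-range values (e.g. a failure probability above 1) raise a
#' range error.
#'
#' Default sensitivity bounds that no longer resolve after user overrides
#' (e.g. renamed drugs) are dropped with a warning; bounds supplied by the
#' file itself must resolve.
#'
#' @param path Path to a `.yaml`, `.yml` or `.json` scenario file.
#' @return A validated `bim_scenario`.
#' @seealso [write_scenario()], [base_case()]
#' @export
load_scenario <- function(path) {
  raw <- read_scenario_file(path)
  defaults <- table1_plain()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0L) abort_validation(unknown[1], "unknown field")

  merged <- defaults
  for (f in .shared_fields) {
    if (f %in% names(raw)) merged[[f]] <- raw[[f]]
  }
  for (role in c("intervention", "reference")) {
    if (role %in% names(raw)) {
      merged[[role]] <- merge_arm(defaults[[role]], raw[[role]], role)
    }
  }
  if ("rescue" %in% names(raw)) merged$rescue <- raw$rescue
  bounds_from_file <- "dsa_bounds" %in% names(raw)
  if (bounds_from_file) merged$dsa_bounds <- raw$dsa_bounds %||% list()

  # Build without bounds first so default bounds that no longer resolve can
  # be dropped rather than invalidating the whole scenario.
  bounds <- as_dsa_bounds(merged$dsa_bounds)
  merged$dsa_bounds <- list()
  config <- scenario_from_list(merged)

  if (nrow(bounds) > 0L) {
    resolves <- purrr::map_lgl(seq_len(nrow(bounds)), function(i) {
      if (bounds$type[i] == "mixture") return(TRUE)
      all(purrr::map_lgl(bounds$path[[i]], function(p) {
        !inherits(try(get_parameter(config, p), silent = TRUE), "try-error")
      }))
    })
    if (any(!resolves)) {
      if (bounds_from_file) {
        bad <- bounds[!resolves, ]
        for (i in seq_len(nrow(bad))) {
          for (p in bad$path[[i]]) get_parameter(config, p) # signals lookup error
        }
      }
      rlang::warn(sprintf(
        "Dropping %d default sensitivity bound(s) that do not resolve in this scenario.",
        sum(!resolves)
      ))
      bounds <- bounds[resolves, ]
    }
  }
  config$dsa_bounds <- bounds
  validate_scenario(config)
  config
}

#' Write a scenario file
#'
#' Serialises a scenario to YAML or JSON (chosen by file extension) such that
#' [load_scenario()] recovers it field by field.
#'
#' @param config A `bim_scenario`.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(config, path) {
  validate_scenario(config)
  lst <- scenario_to_list(config)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(lst, path, precision = 15L)
  } else if (ext == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    abort_validation(path, "scenario files must be .yaml, .yml or .json")
  }
  invisible(path)
}
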