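# Scenario parameters: constructors, validation, dotted-path access, and
# YAML/JSON (de)serialization. A scenario holds everything the model needs:
# cohort size, staff hourly rates, the rescue-treatment mixture, two arms
# (intervention = intracameral injection, reference = topical eye drops), the
# revenue assumption for the throughput benefit, and the one-way sensitivity
# bounds.

.arm_scalar_fields <- c(
  "p_failure", "wait_before_surgery_min", "n_instillation_sessions",
  "session_duration_min", "surgeon_working_time_min", "or_occupancy_min",
  "extra_time_failure_min", "between_op_loss_min", "patients_per_vial"
)

.shared_fields <- c(
  "n_patients", "nurse_rate", "surgeon_rate", "revenue_per_operation"
)

check_arm_field <- function(field, value, label = field) {
  switch(field,
    p_failure = check_prob(value, label),
    patients_per_vial = check_min1(value, label),
    check_nonneg(value, label)
  )
}

check_shared_field <- function(field, value, label = field) {
  # n_patients >= 0: a zero-patient scenario is legal and yields all-zero
  # summaries (useful as a degenerate check).
  check_nonneg(value, label)
}

#' Per-arm model parameters
#'
#' Bundles every input specific to one mydriasis strategy: the probability of
#' intra-operative mydriasis failure, pre-operative waiting time, nurse
#' instillation workload, per-operation surgeon and operating-room times, the
#' extra time a failure costs (during the operation and between operations),
#' and drug acquisition inputs.
#'
#' @param name Label for the arm (free text, e.g. `"intracameral"`).
#' @param p_failure Probability of mydriasis failure per operation, in `[0, 1]`.
#' @param wait_before_surgery_min Patient waiting time before surgery
#'   (minutes/patient).
#' @param n_instillation_sessions Number of eye-drop instillation sessions
#'   performed by nurses (0 for an injectable arm).
#' @param session_duration_min Duration of one instillation session
#'   (minutes/session).
#' @param surgeon_working_time_min Surgeon working time per operation with no
#'   mydriasis failure (minutes).
#' @param or_occupancy_min Operating-room occupancy per operation with no
#'   mydriasis failure (minutes). Kept distinct from
#'   `surgeon_working_time_min` even when numerically equal.
#' @param extra_time_failure_min Additional intra-operative time per mydriasis
#'   failure (minutes).
#' @param between_op_loss_min Surgeon time lost between operations per
#'   mydriasis failure (minutes).
#' @param drug_unit_costs Named numeric vector of unit costs (GBP) for the
#'   products this arm acquires per patient (e.g.
#'   `c(tropicamide = 0.54, phenylephrine = 0.57)`).
#' @param patients_per_vial Number of patients sharing one vial of each
#'   product (>= 1).
#'
#' @return An object of class `bim_arm` (a validated named list).
#' @seealso [scenario_config()], [base_case()]
#' @export
arm_parameters <- function(name, p_failure, wait_before_surgery_min,
                           n_instillation_sessions, session_duration_min,
                           surgeon_working_time_min, or_occupancy_min,
                           extra_time_failure_min, between_op_loss_min,
                           drug_unit_costs, patients_per_vial = 1) {
  arm <- structure(
    list(
      name = as.character(name)[1],
      p_failure = p_failure,
      wait_before_surgery_min = wait_before_surgery_min,
      n_instillation_sessions = n_instillation_sessions,
      session_duration_min = session_duration_min,
      surgeon_working_time_min = surgeon_working_time_min,
      or_occupancy_min = or_occupancy_min,
      extra_time_failure_min = extra_time_failure_min,
      between_op_loss_min = between_op_loss_min,
      drug_unit_costs = drug_unit_costs,
      patients_per_vial = patients_per_vial
    ),
    class = "bim_arm"
  )
  validate_arm(arm)
  arm
}

validate_arm <- function(arm, prefix = arm$name %||% "arm") {
  for (f in .arm_scalar_fields) {
    check_arm_field(f, arm[[f]], paste(prefix, f, sep = "."))
  }
  costs <- arm$drug_unit_costs
  lab <- paste(prefix, "drug_unit_costs", sep = ".")
  if (!is.numeric(costs) || length(costs) == 0L ||
      is.null(names(costs)) || any(!nzchar(names(costs)))) {
    abort_validation(lab, "must be a non-empty named numeric vector")
  }
  for (d in names(costs)) check_nonneg(costs[[d]], paste(lab, d, sep = "."))
  invisible(arm)
}

#' Rescue mydriatic mixture
#'
#' The mixture of additional treatments applied when initial mydriasis fails
#' intra-operatively. Component probabilities are marginal frequencies of use
#' per failure and may sum to more than 1 (several rescue treatments can be
#' used on the same patient); they are never renormalised. `prob_low` /
#' `prob_high` hold the two alternative whole-mixture scenarios used by the
#' sensitivity analysis and default to `prob`.
#'
#' @param components A data frame with columns `component` (unique labels),
#'   `prob` (frequency of use per failure, in `[0, 1]`), `cost` (unit cost,
#'   GBP) and optionally `prob_low`, `prob_high`.
#'
#' @return A validated tibble with columns `component`, `prob`, `cost`,
#'   `prob_low`, `prob_high`.
#' @export
rescue_mixture <- function(components) {
  df <- tibble::as_tibble(components)
  needed <- c("component", "prob", "cost")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    abort_validation("rescue", paste0(
      "missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  if (nrow(df) == 0L) abort_validation("rescue", "must have at least one component")
  if (anyDuplicated(df$component) || any(!nzchar(df$component))) {
    abort_validation("rescue.component", "labels must be unique and non-empty")
  }
  if (!"prob_low" %in% names(df)) df$prob_low <- df$prob
  if (!"prob_high" %in% names(df)) df$prob_high <- df$prob
  for (i in seq_len(nrow(df))) {
    comp <- df$component[i]
    check_prob(df$prob[i], paste0("rescue.", comp, ".prob"))
    check_prob(df$prob_low[i], paste0("rescue.", comp, ".prob_low"))
    check_prob(df$prob_high[i], paste0("rescue.", comp, ".prob_high"))
    check_nonneg(df$cost[i], paste0("rescue.", comp, ".cost"))
  }
  df[, c("component", "prob", "cost", "prob_low", "prob_high")]
}

empty_dsa_bounds <- function() {
  tibble::tibble(
    parameter = character(),
    path = list(),
    low = double(),
    high = double(),
    type = character()
  )
}

as_dsa_bounds <- function(entries) {
  if (is.null(entries) || length(entries) == 0L) return(empty_dsa_bounds())
  if (is.data.frame(entries)) {
    df <- tibble::as_tibble(entries)
    if (!is.list(df$path)) df$path <- as.list(df$path)
    if (!"type" %in% names(df)) df$type <- "scalar"
    return(df[, c("parameter", "path", "low", "high", "type")])
  }
  tibble::tibble(
    parameter = purrr::map_chr(entries, ~ as.character(.x$parameter)),
    path = purrr::map(entries, ~ as.character(unlist(.x$path))),
    low = purrr::map_dbl(entries, ~ as.numeric(.x$low %||% NA_real_)),
    high = purrr::map_dbl(entries, ~ as.numeric(.x$high %||% NA_real_)),
    type = purrr::map_chr(entries, ~ as.character(.x$type %||% "scalar"))
  )
}

#' Full scenario configuration
#'
#' Assembles the complete set of model inputs: cohort size, staff hourly
#' rates, the rescue mixture, the two arms, the revenue assumption used by the
#' throughput benefit, and the one-way sensitivity bounds.
#'
#' @param n_patients Number of operations per year (>= 0).
#' @param nurse_rate Nurse cost per hour (GBP).
#' @param surgeon_rate Surgeon cost per hour (GBP).
#' @param rescue A rescue mixture, see [rescue_mixture()].
#' @param intervention,reference Arm parameters, see [arm_parameters()].
#' @param revenue_per_operation Revenue per additional operation (GBP). The
#'   packaged default (744.70) is a back-derived constant, not a published
#'   input; see `vignette("budget-impact-model")`.
#' @param dsa_bounds Optional tibble of one-way sensitivity bounds with
#'   columns `parameter` (label), `path` (list of dotted parameter paths all
#'   set together), `low`, `high`, `type` (`"scalar"` or `"mixture"`). Default:
#'   no bounds.
#'
#' @return An object of class `bim_scenario`.
#' @seealso [load_scenario()], [set_parameter()], [base_case()]
#' @export
scenario_config <- function(n_patients, nurse_rate, surgeon_rate, rescue,
                            intervention, reference,
                            revenue_per_operation = 744.70,
                            dsa_bounds = NULL) {
  cfg <- structure(
    list(
      n_patients = n_patients,
      nurse_rate = nurse_rate,
      surgeon_rate = surgeon_rate,
      revenue_per_operation = revenue_per_operation,
      intervention = intervention,
      reference = reference,
      rescue = rescue_mixture(rescue),
      dsa_bounds = as_dsa_bounds(dsa_bounds)
    ),
    class = "bim_scenario"
  )
  validate_scenario(cfg)
  cfg
}

validate_scenario <- function(config) {
  for (f in .shared_fields) check_shared_field(f, config[[f]], f)
  for (role in c("intervention", "reference")) {
    arm <- config[[role]]
    if (!inherits(arm, "bim_arm")) {
      abort_validation(role, "must be built with arm_parameters()")
    }
    validate_arm(arm, prefix = role)
  }
  config$rescue <- rescue_mixture(config$rescue)
  bounds <- config$dsa_bounds
  if (nrow(bounds) > 0L) {
    for (i in seq_len(nrow(bounds))) {
      if (bounds$type[i] == "mixture") next
      for (p in bounds$path[[i]]) get_parameter(config, p) # errors if unresolvable
      if (!is.finite(bounds$low[i]) || !is.finite(bounds$high[i])) {
        abort_validation(paste0("dsa_bounds.", bounds$parameter[i]),
                         "low/high must be finite for scalar entries")
      }
    }
  }
  invisible(config)
}

# ---- dotted-path access -----------------------------------------------------

split_path <- function(path) {
  if (!is.character(path) || length(path) != 1L || !nzchar(path)) {
    abort_lookup(paste(format(path), collapse = ","))
  }
  strsplit(path, ".", fixed = TRUE)[[1]]
}

#' Read one scalar parameter by dotted path
#'
#' Paths address every scalar in a scenario uniformly:
#' * shared inputs: `"n_patients"`, `"nurse_rate"`, `"surgeon_rate"`,
#'   `"revenue_per_operation"` (optionally prefixed `"shared."`);
#' * arm fields: `"intervention.p_failure"`, `"reference.session_duration_min"`, ...;
#' * drug unit costs: `"intervention.drug.mydrane"`, `"reference.drug.tropicamide"`;
#' * rescue components: `"rescue.adrenaline.prob"`, `"rescue.mechanical_tools.cost"`.
#'
#' @param config A `bim_scenario`.
#' @param path A dotted parameter path.
#' @return The scalar value at `path`.
#' @export
get_parameter <- function(config, path) {
  p <- split_path(path)
  if (length(p) == 2L && p[1] == "shared") p <- p[2]
  if (length(p) == 1L && p %in% .shared_fields) return(config[[p]])
  if (p[1] %in% c("intervention", "reference")) {
    arm <- config[[p[1]]]
    if (length(p) == 2L && p[2] %in% .arm_scalar_fields) return(arm[[p[2]]])
    if (length(p) == 3L && p[2] == "drug" && p[3] %in% names(arm$drug_unit_costs)) {
      return(unname(arm$drug_unit_costs[[p[3]]]))
    }
  }
  if (p[1] == "rescue" && length(p) == 3L && p[3] %in% c("prob", "cost")) {
    i <- match(p[2], config$rescue$component)
    if (!is.na(i)) return(config$rescue[[p[3]]][i])
  }
  abort_lookup(path)
}

#' Return a copy of a scenario with one parameter changed
#'
#' Pure update: the input configuration is untouched and the returned one
#' differs only at `path`. The new value is validated against the field's
#' invariant (probabilities in `[0, 1]`, durations and costs non-negative,
#' vial sharing >= 1).
#'
#' @inheritParams get_parameter
#' @param value New scalar value.
#' @return A new `bim_scenario`.
#' @export
set_parameter <- function(config, path, value) {
  check_scalar_number(value, path)
  p <- split_path(path)
  if (length(p) == 2L && p[1] == "shared") p <- p[2]
  if (length(p) == 1L && p %in% .shared_fields) {
    check_shared_field(p, value, path)
    config[[p]] <- value
    return(config)
  }
  if (p[1] %in% c("intervention", "reference")) {
    if (length(p) == 2L && p[2] %in% .arm_scalar_fields) {
      check_arm_field(p[2], value, path)
      config[[p[1]]][[p[2]]] <- value
      return(config)
    }
    if (length(p) == 3L && p[2] == "drug" &&
        p[3] %in% names(config[[p[1]]]$drug_unit_costs)) {
      check_nonneg(value, path)
      config[[p[1]]]$drug_unit_costs[[p[3]]] <- value
      return(config)
    }
  }
  if (p[1] == "rescue" && length(p) == 3L && p[3] %in% c("prob", "cost")) {
    i <- match(p[2], config$rescue$component)
    if (!is.na(i)) {
      if (p[3] == "prob") check_prob(value, path) else check_nonneg(value, path)
      config$rescue[[p[3]]][i] <- value
      return(config)
    }
  }
  abort_lookup(path)
}

#' @exportS3Method generics::tidy
tidy.bim_scenario <- function(x, ...) {
  paths <- c(
    .shared_fields,
    unlist(lapply(c("intervention", "reference"), function(role) {
      c(
        paste(role, .arm_scalar_fields, sep = "."),
        paste(role, "drug", names(x[[role]]$drug_unit_costs), sep = ".")
      )
    })),
    paste("rescue", rep(x$rescue$component, 2L),
          rep(c("prob", "cost"), each = nrow(x$rescue)), sep = ".")
  )
  tibble::tibble(
    path = paths,
    value = purrr::map_dbl(paths, ~ get_parameter(x, .x))
  )
}

#' @export
print.bim_scenario <- function(x, ...) {
  cat(sprintf(
    "<bim_scenario> %d patients/year | %s vs %s | %d DSA bounds | hash %s\n",
    x$n_patients, x$intervention$name, x$reference$name,
    nrow(x$dsa_bounds), substr(scenario_hash(x), 1, 8)
  ))
  invisible(x)
}

#' Fingerprint of a scenario
#'
#' A short stable hash of all scenario inputs, used for provenance logging and
#' to refuse oracle comparisons across different scenarios.
#'
#' @param config A `bim_scenario`.
#' @return A character hash.
#' @export
scenario_hash <- function(config) {
  rlang::hash(scenario_to_list(config))
}
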