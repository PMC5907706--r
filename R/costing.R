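# Costing: convert annual resource use into annual costs per arm, incremental
# differences between arms, and the hospital throughput benefit of freed
# surgeon time. All arithmetic is full precision; rendering rounds.

#' Expected rescue cost per mydriasis failure
#'
#' Sum over mixture components of (frequency of use) x (unit cost). The
#' frequencies are marginal probabilities that may total more than 1 (several
#' rescue treatments can be applied to one patient) and are deliberately not
#' renormalised.
#'
#' @param mix A rescue mixture tibble, see [rescue_mixture()].
#' @return Expected cost (GBP) per failure.
#' @examples
#' expected_rescue_cost_per_failure(base_case()$rescue)
#' @export
expected_rescue_cost_per_failure <- function(mix) {
  mix <- rescue_mixture(mix)
  sum(mix$prob * mix$cost)
}

#' Annual drug acquisition cost for one arm
#'
#' One vial of each of the arm's products per patient, divided by the number
#' of patients sharing a vial.
#'
#' @param arm A `bim_arm`.
#' @param n_patients Operations per year.
#' @return Annual acquisition cost (GBP).
#' @export
drug_acquisition_cost <- function(arm, n_patients) {
  validate_arm(arm)
  check_nonneg(n_patients, "n_patients")
  n_patients * sum(arm$drug_unit_costs) / arm$patients_per_vial
}

#' Annual costs for one arm
#'
#' @param resource A one-row resource-use tibble for the arm (a row of
#'   [resource_use()]).
#' @param arm The matching `bim_arm`.
#' @param config The `bim_scenario` both came from.
#' @return A one-row cost tibble. Identities hold exactly:
#'   `work_related_cost = nurse_cost + surgeon_cost`,
#'   `treatment_related_cost = drug_acquisition_cost + rescue_cost`,
#'   `total_cost = work_related_cost + treatment_related_cost`,
#'   `cost_per_patient * n_patients = total_cost`.
#' @export
arm_costs <- function(resource, arm, config) {
  n <- config$n_patients
  nurse_cost <- resource$nurse_hours * config$nurse_rate
  surgeon_cost <- resource$total_surgeon_hours * config$surgeon_rate
  drug <- drug_acquisition_cost(arm, n)
  rescue <- resource$expected_failures *
    expected_rescue_cost_per_failure(config$rescue)
  work <- nurse_cost + surgeon_cost
  treatment <- drug + rescue
  total <- work + treatment
  tibble::tibble(
    arm = resource$arm,
    nurse_cost = nurse_cost,
    surgeon_cost = surgeon_cost,
    work_related_cost = work,
    drug_acquisition_cost = drug,
    rescue_cost = rescue,
    treatment_related_cost = treatment,
    total_cost = total,
    cost_per_patient = if (n > 0) total / n else 0
  )
}

#' Annual costs per arm
#'
#' @param config A `bim_scenario`.
#' @return A tibble with one row per arm.
#' @examples
#' cost_summary(base_case())
#' @export
cost_summary <- function(config) {
  validate_scenario(config)
  ru <- resource_use(config)
  dplyr::bind_rows(
    arm_costs(ru[ru$arm == "intervention", ], config$intervention, config),
    arm_costs(ru[ru$arm == "reference", ], config$reference, config)
  )
}

#' Incremental result (intervention minus reference)
#'
#' Exact field-wise differences across all resource-use and cost fields.
#' Negative cost differences are savings from adopting the intervention.
#'
#' @param config A `bim_scenario`.
#' @return A one-row tibble of differences.
#' @examples
#' incremental(base_case())$total_cost
#' @export
incremental <- function(config) {
  joined <- dplyr::inner_join(resource_use(config), cost_summary(config),
                              by = "arm")
  num <- joined[, setdiff(names(joined), "arm")]
  diff <- unlist(num[joined$arm == "intervention", ]) -
    unlist(num[joined$arm == "reference", ])
  tibble::as_tibble(as.list(diff))
}

#' Hospital throughput benefit of freed surgeon time
#'
#' Surgeon time saved by the intervention is converted into additional
#' operations by dividing by the intervention arm's expected per-operation
#' surgeon time (working time plus expected failure delay), then into revenue
#' via `revenue_per_operation`. The expected net benefit applies a
#' configurable rule; the default subtracts the intervention's per-patient
#' cost of each additional operation from its revenue. Both the revenue
#' constant and the rule are explicit modelling choices, not published inputs
#' (see `vignette("budget-impact-model")`).
#'
#' @param config A `bim_scenario`.
#' @param net_benefit Optional function
#'   `function(additional_revenue, operations_gained, cost_per_patient)`
#'   returning the expected net benefit (GBP/year).
#' @return A one-row tibble: `surgeon_minutes_saved`, `operations_gained`,
#'   `additional_revenue`, `expected_net_benefit`.
#' @examples
#' throughput_benefit(base_case())
#' @export
throughput_benefit <- function(config, net_benefit = NULL) {
  ru <- resource_use(config)
  cs <- cost_summary(config)
  saved_min <- -(ru$total_surgeon_hours[ru$arm == "intervention"] -
                   ru$total_surgeon_hours[ru$arm == "reference"]) * 60
  arm <- config$intervention
  per_op_min <- arm$surgeon_working_time_min +
    arm$p_failure * (arm$extra_time_failure_min + arm$between_op_loss_min)
  if (per_op_min <= 0) {
    rlang::abort(
      "Per-operation surgeon time is zero; operations gained are undefined.",
      class = "bim_config_error"
    )
  }
  ops <- saved_min / per_op_min
  revenue <- ops * config$revenue_per_operation
  cpp <- cs$cost_per_patient[cs$arm == "intervention"]
  rule <- net_benefit %||%
    function(additional_revenue, operations_gained, cost_per_patient) {
      additional_revenue - operations_gained * cost_per_patient
    }
  tibble::tibble(
    surgeon_minutes_saved = saved_min,
    operations_gained = ops,
    additional_revenue = revenue,
    expected_net_benefit = rule(revenue, ops, cpp)
  )
}
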