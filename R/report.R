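# Model report: full-precision record of the base-case run plus rendering
# helpers. Rendering rounds pounds to the nearest integer, per-patient costs
# to pence, and hours/counts to two decimals; the underlying record always
# keeps full precision.

#' Run the full budget impact model
#'
#' Computes per-arm resource use and costs, the incremental result
#' (intervention minus reference) and the hospital throughput benefit, and
#' bundles them with the scenario fingerprint.
#'
#' @param config A `bim_scenario`.
#' @param net_benefit Optional net-benefit rule passed to
#'   [throughput_benefit()].
#' @return A `bim_report` with elements `config`, `config_hash`, `resource`,
#'   `costs`, `incremental`, `throughput`.
#' @examples
#' report <- bim_run(base_case())
#' glance(report)
#' @export
bim_run <- function(config, net_benefit = NULL) {
  validate_scenario(config)
  structure(
    list(
      config = config,
      config_hash = scenario_hash(config),
      resource = resource_use(config),
      costs = cost_summary(config),
      incremental = incremental(config),
      throughput = throughput_benefit(config, net_benefit = net_benefit)
    ),
    class = "bim_report"
  )
}

report_section <- function(report, which = c("resource", "costs")) {
  which <- match.arg(which)
  wide <- report[[which]]
  metrics <- setdiff(names(wide), "arm")
  tibble::tibble(
    section = if (which == "resource") "resource_use" else "costs",
    metric = metrics,
    intervention = unlist(wide[wide$arm == "intervention", metrics]),
    reference = unlist(wide[wide$arm == "reference", metrics]),
    difference = unlist(report$incremental[, metrics])
  )
}

#' @exportS3Method generics::tidy
tidy.bim_report <- function(x, ...) {
  dplyr::bind_rows(report_section(x, "resource"), report_section(x, "costs"))
}

#' @exportS3Method generics::glance
glance.bim_report <- function(x, ...) {
  cs <- x$costs
  tibble::tibble(
    n_patients = x$config$n_patients,
    total_cost_intervention = cs$total_cost[cs$arm == "intervention"],
    total_cost_reference = cs$total_cost[cs$arm == "reference"],
    incremental_total_cost = x$incremental$total_cost,
    surgeon_minutes_saved = x$throughput$surgeon_minutes_saved,
    operations_gained = x$throughput$operations_gained,
    additional_revenue = x$throughput$additional_revenue,
    expected_net_benefit = x$throughput$expected_net_benefit
  )
}

# Rounding rules for rendered views (full precision stays in the record):
# annual pounds to the nearest pound, per-patient pounds to pence,
# hours/counts/minutes to 2 decimals.
round_metric <- function(metric, value) {
  pounds0 <- c(
    "nurse_cost", "surgeon_cost", "work_related_cost", "drug_acquisition_cost",
    "rescue_cost", "treatment_related_cost", "total_cost",
    "additional_revenue", "expected_net_benefit"
  )
  ifelse(metric %in% pounds0, round(value),
         ifelse(metric == "cost_per_patient", round(value, 2), round(value, 2)))
}

render_section <- function(section_df) {
  dplyr::mutate(
    section_df,
    dplyr::across(
      dplyr::all_of(c("intervention", "reference", "difference")),
      ~ round_metric(.data$metric, .x)
    )
  )
}

rendered_tables <- function(report) {
  tp <- report$throughput
  list(
    resource_use = render_section(report_section(report, "resource"))[, -1],
    costs = render_section(report_section(report, "costs"))[, -1],
    throughput = tibble::tibble(
      metric = names(tp),
      value = round_metric(names(tp), unlist(tp))
    )
  )
}

#' @export
print.bim_report <- function(x, ...) {
  tabs <- rendered_tables(x)
  cat(sprintf("Budget impact report | scenario %s | %d patients/year\n",
              substr(x$config_hash, 1, 8), x$config$n_patients))
  cat(sprintf("Arms: %s (intervention) vs %s (reference)\n\n",
              x$config$intervention$name, x$config$reference$name))
  cat("Annual resource use (hours; failures as counts):\n")
  print(as.data.frame(tabs$resource_use), row.names = FALSE)
  cat("\nAnnual costs (GBP; cost_per_patient in GBP/patient):\n")
  print(as.data.frame(tabs$costs), row.names = FALSE)
  cat("\nHospital throughput benefit:\n")
  print(as.data.frame(tabs$throughput), row.names = FALSE)
  invisible(x)
}
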