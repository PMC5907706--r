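# Builders for small custom scenarios and randomized valid configurations.
# All randomness is driven by the caller's seed (tests set one explicitly).

make_arm <- function(name = "arm", p_failure = 0.1, wait = 10, sessions = 0,
                     session_min = 0, swt = 10, or = 10, extra = 5,
                     between = 5, drugs = c(drug_a = 1), vial = 1) {
  arm_parameters(
    name = name, p_failure = p_failure, wait_before_surgery_min = wait,
    n_instillation_sessions = sessions, session_duration_min = session_min,
    surgeon_working_time_min = swt, or_occupancy_min = or,
    extra_time_failure_min = extra, between_op_loss_min = between,
    drug_unit_costs = drugs, patients_per_vial = vial
  )
}

make_rescue <- function(probs = c(0.5, 0.2), costs = c(2, 10)) {
  data.frame(
    component = paste0("comp_", seq_along(probs)),
    prob = probs, cost = costs
  )
}

make_config <- function(n = 100, nurse_rate = 10, surgeon_rate = 20,
                        intervention = make_arm("int"),
                        reference = make_arm("ref", sessions = 2, session_min = 3),
                        rescue = make_rescue(), revenue = 100,
                        dsa_bounds = NULL) {
  scenario_config(
    n_patients = n, nurse_rate = nurse_rate, surgeon_rate = surgeon_rate,
    rescue = rescue, intervention = intervention, reference = reference,
    revenue_per_operation = revenue, dsa_bounds = dsa_bounds
  )
}

random_arm <- function(name) {
  make_arm(
    name = name,
    p_failure = stats::runif(1),
    wait = stats::runif(1, 0, 60),
    sessions = sample(0:4, 1),
    session_min = stats::runif(1, 0, 10),
    swt = stats::runif(1, 5, 30),
    or = stats::runif(1, 5, 30),
    extra = stats::runif(1, 0, 30),
    between = stats::runif(1, 0, 30),
    drugs = stats::setNames(stats::runif(2, 0, 20), c("drug_a", "drug_b")),
    vial = sample(1:5, 1)
  )
}

random_scenario <- function() {
  make_config(
    n = sample(1:5000, 1),
    nurse_rate = stats::runif(1, 0, 100),
    surgeon_rate = stats::runif(1, 0, 300),
    intervention = random_arm("int"),
    reference = random_arm("ref"),
    rescue = make_rescue(probs = stats::runif(3), costs = stats::runif(3, 0, 60)),
    revenue = stats::runif(1, 0, 1000)
  )
}

swap_arms <- function(config) {
  scenario_config(
    n_patients = config$n_patients, nurse_rate = config$nurse_rate,
    surgeon_rate = config$surgeon_rate, rescue = config$rescue,
    intervention = config$reference, reference = config$intervention,
    revenue_per_operation = config$revenue_per_operation
  )
}

write_tmp_scenario <- function(lines, ext = ".yaml",
                               env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ext, .local_envir = env)
  writeLines(lines, path)
  path
}

numeric_row <- function(df, role) {
  unlist(df[df$arm == role, setdiff(names(df), "arm")])
}
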