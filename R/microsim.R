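# Patient-level microsimulation: a stochastic realisation of the decision
# tree whose expectation is exactly the deterministic cohort model.
# Stochasticity enters only through the Bernoulli failure draw and the
# independent Bernoulli rescue-component draws per failure; all times are
# deterministic given the failure flag (no time variances are modelled).

# Scoped seeding: set the RNG seed for the calling frame and restore the
# caller's random state (or its absence) on exit.
local_seed <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = envir)
  set.seed(seed)
}

.deterministic_fields <- c(
  "waiting_room_hours", "surgeon_in_operation_hours", "nurse_hours",
  "nurse_cost", "drug_acquisition_cost"
)

.microsim_fields <- c(
  "waiting_room_hours", "or_occupancy_hours", "expected_failures",
  "surgeon_in_operation_hours", "surgeon_delay_hours", "total_surgeon_hours",
  "nurse_hours", "nurse_cost", "surgeon_cost", "work_related_cost",
  "drug_acquisition_cost", "rescue_cost", "treatment_related_cost",
  "total_cost", "cost_per_patient"
)

sim_arm_raw <- function(arm, config, n) {
  failed <- stats::rbinom(n, 1L, arm$p_failure) == 1L
  k <- nrow(config$rescue)
  usage <- matrix(FALSE, nrow = n, ncol = k,
                  dimnames = list(NULL, config$rescue$component))
  nf <- sum(failed)
  if (nf > 0L) {
    usage[failed, ] <- matrix(
      stats::rbinom(nf * k, 1L, rep(config$rescue$prob, each = nf)) == 1L,
      nrow = nf, ncol = k
    )
  }
  extra_min <- ifelse(failed,
                      arm$extra_time_failure_min + arm$between_op_loss_min, 0)
  list(
    failed = failed,
    usage = usage,
    rescue_cost = as.numeric(usage %*% config$rescue$cost),
    extra_min = extra_min,
    wait_min = rep(arm$wait_before_surgery_min, n),
    nurse_min = rep(arm$n_instillation_sessions * arm$session_duration_min, n),
    surgeon_min = arm$surgeon_working_time_min + extra_min,
    or_min = arm$or_occupancy_min + extra_min,
    drug_cost = rep(sum(arm$drug_unit_costs) / arm$patients_per_vial, n)
  )
}

aggregate_raw <- function(raw, config) {
  n <- length(raw$failed)
  in_op <- sum(raw$surgeon_min - raw$extra_min) / 60
  delay <- sum(raw$extra_min) / 60
  total_surgeon <- in_op + delay
  nurse_h <- sum(raw$nurse_min) / 60
  nurse_cost <- nurse_h * config$nurse_rate
  surgeon_cost <- total_surgeon * config$surgeon_rate
  drug <- sum(raw$drug_cost)
  rescue <- sum(raw$rescue_cost)
  work <- nurse_cost + surgeon_cost
  treatment <- drug + rescue
  total <- work + treatment
  c(
    waiting_room_hours = sum(raw$wait_min) / 60,
    or_occupancy_hours = sum(raw$or_min) / 60,
    expected_failures = sum(raw$failed),
    surgeon_in_operation_hours = in_op,
    surgeon_delay_hours = delay,
    total_surgeon_hours = total_surgeon,
    nurse_hours = nurse_h,
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

#' Simulate individual patients through the decision tree
#'
#' Draws mydriasis failure as Bernoulli(`p_failure`); for each failure, every
#' rescue component is used independently with its mixture probability, its
#' cost accrues, and the failure's extra intra-operative plus
#' between-operation minutes are added to surgeon and theatre time. All other
#' quantities are copied deterministically from the arm parameters.
#'
#' @param config A `bim_scenario`.
#' @param arm `"intervention"` or `"reference"`.
#' @param n Number of patients (default: the scenario's `n_patients`).
#' @param seed Optional integer seed (applied locally; the caller's random
#'   state is untouched).
#' @return A tibble with one row per patient: `arm`, `failed_mydriasis`,
#'   `wait_min`, `nurse_min`, `surgeon_min`, `or_min`, `drug_cost`,
#'   `rescue_cost`, and `rescue_components_used` (list of component labels,
#'   empty unless the patient failed).
#' @examples
#' simulate_patients(base_case(), "reference", n = 10, seed = 1)
#' @export
simulate_patients <- function(config, arm = c("intervention", "reference"),
                              n = NULL, seed = NULL) {
  validate_scenario(config)
  role <- match.arg(arm)
  n <- n %||% config$n_patients
  check_nonneg(n, "n")
  if (!is.null(seed)) local_seed(seed)
  raw <- sim_arm_raw(config[[role]], config, n)
  tibble::tibble(
    arm = rep(role, n),
    failed_mydriasis = raw$failed,
    wait_min = raw$wait_min,
    nurse_min = raw$nurse_min,
    surgeon_min = raw$surgeon_min,
    or_min = raw$or_min,
    drug_cost = raw$drug_cost,
    rescue_cost = raw$rescue_cost,
    rescue_components_used = purrr::map(seq_len(n), function(i) {
      colnames(raw$usage)[raw$usage[i, ]]
    })
  )
}

#' Monte Carlo replication of the annual cohort
#'
#' Runs `n_replicates` independent replicates of `n_patients` simulated
#' patients per arm, aggregates each replicate to the same annual totals the
#' cohort engine computes, and summarises every field by its mean and standard
#' error over replicates. Identical `(config, n_replicates, seed)` give a
#' bit-identical summary.
#'
#' @param config A `bim_scenario`.
#' @param n_replicates Number of replicates (>= 1). With a single replicate
#'   standard errors are undefined and reported as `NA`.
#' @param seed Integer seed (applied locally).
#' @return A `bim_microsim` object: a list with `fields` (tibble of `arm`,
#'   `field`, `mean`, `se`, `deterministic`), `n_patients`, `n_replicates`,
#'   `seed` and the scenario `config_hash`.
#' @examples
#' simulate_cohort(base_case(), n_replicates = 5, seed = 1)
#' @export
simulate_cohort <- function(config, n_replicates, seed) {
  validate_scenario(config)
  check_min1(n_replicates, "n_replicates")
  check_scalar_number(seed, "seed")
  local_seed(seed)
  roles <- c("intervention", "reference")
  totals <- purrr::map(seq_len(n_replicates), function(r) {
    purrr::map(roles, function(role) {
      aggregate_raw(sim_arm_raw(config[[role]], config, config$n_patients),
                    config)
    }) |> setNames(roles)
  })
  fields <- purrr::map_dfr(roles, function(role) {
    mat <- do.call(rbind, purrr::map(totals, role))
    tibble::tibble(
      arm = role,
      field = colnames(mat),
      mean = unname(colMeans(mat)),
      se = unname(apply(mat, 2L, stats::sd)) / sqrt(n_replicates),
      deterministic = colnames(mat) %in% .deterministic_fields
    )
  })
  structure(
    list(
      fields = fields,
      n_patients = config$n_patients,
      n_replicates = n_replicates,
      seed = seed,
      config_hash = scenario_hash(config)
    ),
    class = "bim_microsim"
  )
}

#' @exportS3Method generics::tidy
tidy.bim_microsim <- function(x, ...) x$fields

#' @export
print.bim_microsim <- function(x, ...) {
  cat(sprintf(
    "<bim_microsim> %d replicates x %d patients/arm | seed %s | scenario %s\n",
    x$n_replicates, x$n_patients, format(x$seed), substr(x$config_hash, 1, 8)
  ))
  print(x$fields, n = Inf)
  invisible(x)
}

cohort_expectations_long <- function(config) {
  joined <- dplyr::inner_join(resource_use(config), cost_summary(config),
                              by = "arm")
  tidyr::pivot_longer(joined, -"arm", names_to = "field",
                      values_to = "expected")
}

#' Validate the cohort engine against the microsimulation
#'
#' Compares every cohort expectation with the corresponding microsimulation
#' mean: deterministic fields must match exactly (to numerical precision);
#' stochastic fields pass when the expectation lies within
#' `se_multiplier` standard errors of the Monte Carlo mean. The comparison is
#' refused when the summary was produced from a different scenario.
#'
#' @param config The `bim_scenario` the summary was produced from.
#' @param summary A `bim_microsim` from [simulate_cohort()].
#' @param se_multiplier Width of the acceptance band in standard errors
#'   (default 3).
#' @return A `bim_oracle_check` tibble (`arm`, `field`, `expected`, `mean`,
#'   `se`, `deterministic`, `pass`) with attribute `"pass"` (all fields pass).
#' @export
oracle_check <- function(config, summary, se_multiplier = 3) {
  if (!inherits(summary, "bim_microsim")) {
    abort_validation("summary", "must be a bim_microsim from simulate_cohort()")
  }
  if (!identical(scenario_hash(config), summary$config_hash)) {
    rlang::abort(
      "Summary was produced from a different scenario; comparison refused.",
      class = "bim_hash_error"
    )
  }
  chk <- dplyr::inner_join(cohort_expectations_long(config), summary$fields,
                           by = c("arm", "field"))
  tol <- 1e-8
  chk$pass <- ifelse(
    chk$deterministic,
    abs(chk$mean - chk$expected) <= tol * pmax(1, abs(chk$expected)),
    # NA standard errors (single replicate) leave the band unbounded; a zero
    # standard error makes the stochastic field degenerate, so require
    # exactness there too.
    dplyr::case_when(
      is.na(chk$se) ~ TRUE,
      chk$se > 0 ~ abs(chk$mean - chk$expected) <= se_multiplier * chk$se,
      .default = abs(chk$mean - chk$expected) <= tol * pmax(1, abs(chk$expected))
    )
  )
  out <- tibble::as_tibble(chk)
  attr(out, "pass") <- all(out$pass)
  class(out) <- c("bim_oracle_check", class(out))
  out
}

#' @export
print.bim_oracle_check <- function(x, ...) {
  verdict <- if (isTRUE(attr(x, "pass"))) "PASS" else "FAIL"
  cat(sprintf("<bim_oracle_check> overall: %s (%d/%d fields)\n",
              verdict, sum(x$pass), nrow(x)))
  NextMethod()
}
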