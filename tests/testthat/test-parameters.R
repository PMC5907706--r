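test_that("packaged base case carries every published input verbatim", {
  cfg <- base_case()

  expect_equal(cfg$n_patients, 3000)
  expect_equal(cfg$nurse_rate, 43.12)
  expect_equal(cfg$surgeon_rate, 147.26)

  int <- cfg$intervention
  ref <- cfg$reference
  expect_equal(int$p_failure, 0.011)
  expect_equal(ref$p_failure, 0.053)
  expect_equal(int$wait_before_surgery_min, 8.70)
  expect_equal(ref$wait_before_surgery_min, 37.90)
  expect_equal(int$n_instillation_sessions, 0)
  expect_equal(ref$n_instillation_sessions, 3)
  expect_equal(ref$session_duration_min, 3)
  expect_equal(ref$patients_per_vial, 1)
  # Stored at full precision (back-derived from the annual hour totals); the
  # two-decimal renderings are the published per-operation times.
  expect_equal(int$surgeon_working_time_min, 12.025)
  expect_equal(ref$surgeon_working_time_min, 11.335)
  expect_equal(round(int$surgeon_working_time_min, 2), 12.03)
  expect_equal(round(ref$surgeon_working_time_min, 2), 11.34)
  expect_equal(int$or_occupancy_min, int$surgeon_working_time_min)
  expect_equal(ref$or_occupancy_min, ref$surgeon_working_time_min)
  expect_equal(int$extra_time_failure_min, 10)
  expect_equal(ref$extra_time_failure_min, 10)
  expect_equal(int$between_op_loss_min, 10)
  expect_equal(ref$between_op_loss_min, 10)
  expect_equal(int$drug_unit_costs, c(mydrane = 6.00))
  expect_equal(ref$drug_unit_costs, c(tropicamide = 0.54, phenylephrine = 0.57))

  expect_equal(cfg$rescue$component,
               c("adrenaline", "phenylephrine", "tropicamide",
                 "mechanical_tools", "cyclopentolate", "others"))
  expect_equal(cfg$rescue$prob, c(0.04, 0.93, 0.14, 0.04, 0.32, 0))
  expect_equal(cfg$rescue$cost, c(4.95, 0.57, 0.54, 56.80, 0.56, 0))
  # Alternative whole-mixture profiles, stored as published (low adrenaline use
  # 39% exceeds its base 4%; the high profile equals the base).
  expect_equal(cfg$rescue$prob_low, c(0.39, 0.57, 0.00, 0.05, 0.01, 0))
  expect_equal(cfg$rescue$prob_high, cfg$rescue$prob)

  b <- cfg$dsa_bounds
  expect_equal(nrow(b), 24)
  bound <- function(parameter) as.list(b[b$parameter == parameter, c("low", "high")])
  expect_equal(bound("p_failure_intracameral"), list(low = 0.002, high = 0.032))
  expect_equal(bound("p_failure_eye_drops"), list(low = 0.030, high = 0.087))
  expect_equal(bound("n_instillation_sessions"), list(low = 2, high = 4))
  expect_equal(bound("session_duration"), list(low = 1.5, high = 5))
  expect_equal(bound("patients_per_vial"), list(low = 1, high = 5))
  expect_equal(bound("nurse_rate"), list(low = 35.76, high = 59.95))
  expect_equal(bound("surgeon_rate"), list(low = 105.18, high = 189.33))
  expect_equal(bound("cost_intracameral_product"), list(low = 3, high = 9))
  expect_equal(bound("surgeon_time_intracameral"), list(low = 11.51, high = 12.52))
  expect_equal(bound("surgeon_time_eye_drops"), list(low = 10.64, high = 12.04))
  # Stored verbatim although internally odd (high bound below the base 10.0).
  expect_equal(bound("failure_extra_time_eye_drops"), list(low = 2.5, high = 7.5))
  expect_equal(bound("cost_adrenaline"), list(low = 0.39, high = 8.31))
  expect_equal(bound("cost_tropicamide"), list(low = 0.50, high = 1.60))
  expect_equal(bound("cost_cyclopentolate"), list(low = 0.50, high = 12.96))
  expect_equal(bound("cost_mechanical_tools"), list(low = 28.40, high = 85.20))
  # A single published price feeds both the acquisition and rescue uses.
  expect_setequal(
    b$path[b$parameter == "cost_tropicamide"][[1]],
    c("reference.drug.tropicamide", "rescue.tropicamide.cost")
  )
  expect_equal(b$type[b$parameter == "rescue_distribution"], "mixture")

  # The packaged file and the in-code defaults are the same scenario.
  expect_equal(cfg, default_scenario())
})

test_that("scenarios round-trip through YAML and JSON field by field", {
  cfg <- base_case()
  for (ext in c(".yaml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_scenario(cfg, path)
    expect_equal(load_scenario(path), cfg, label = ext)
  }

  set.seed(7)
  for (i in 1:3) {
    rnd <- random_scenario()
    path <- withr::local_tempfile(fileext = ".yaml")
    write_scenario(rnd, path)
    expect_equal(load_scenario(path), rnd)
  }
})

test_that("omitted fields take the packaged base-case defaults", {
  path <- write_tmp_scenario("n_patients: 6000")
  cfg <- load_scenario(path)
  base <- base_case()
  expect_equal(cfg$n_patients, 6000)
  expect_equal(cfg$nurse_rate, base$nurse_rate)
  expect_equal(cfg$reference, base$reference)
  expect_equal(cfg$rescue, base$rescue)
  expect_equal(cfg$dsa_bounds, base$dsa_bounds)

  # Partial arm override keeps the remaining arm fields at their defaults.
  path2 <- write_tmp_scenario(c("intervention:", "  p_failure: 0.02"))
  cfg2 <- load_scenario(path2)
  expect_equal(cfg2$intervention$p_failure, 0.02)
  expect_equal(cfg2$intervention$drug_unit_costs, c(mydrane = 6))
})

test_that("invalid scenario files fail with errors naming the field", {
  bad_prob <- write_tmp_scenario(c("intervention:", "  p_failure: 1.5"))
  expect_error(load_scenario(bad_prob), "p_failure", class = "bim_range_error")

  unknown_top <- write_tmp_scenario("discount_rate: 0.035")
  expect_error(load_scenario(unknown_top), "discount_rate",
               class = "bim_validation_error")

  unknown_arm <- write_tmp_scenario(c("reference:", "  bogus_field: 1"))
  expect_error(load_scenario(unknown_arm), "bogus_field",
               class = "bim_validation_error")

  expect_error(load_scenario(withr::local_tempfile(fileext = ".yaml")),
               class = "bim_io_error")

  txt <- write_tmp_scenario("n_patients: 10", ext = ".txt")
  expect_error(load_scenario(txt), class = "bim_validation_error")

  # File-supplied sensitivity bounds must resolve.
  bad_bounds <- write_tmp_scenario(c(
    "dsa_bounds:",
    "- parameter: ghost",
    "  path: [intervention.nonexistent]",
    "  low: 1",
    "  high: 2"
  ))
  expect_error(load_scenario(bad_bounds), class = "bim_lookup_error")
})

test_that("set_parameter returns a modified copy, validates, and is idempotent", {
  base <- base_case()
  snapshot <- tidy(base)

  up <- set_parameter(base, "intervention.drug.mydrane", 9)
  expect_equal(get_parameter(up, "intervention.drug.mydrane"), 9)
  # Only that one scalar differs.
  changed <- dplyr::anti_join(tidy(up), snapshot, by = c("path", "value"))
  expect_equal(changed$path, "intervention.drug.mydrane")
  # The original is untouched.
  expect_equal(tidy(base), snapshot)

  # Idempotence and identity.
  expect_equal(set_parameter(up, "intervention.drug.mydrane", 9), up)
  expect_equal(set_parameter(base, "nurse_rate",
                             get_parameter(base, "nurse_rate")), base)

  # Shared prefix alias and rescue paths.
  expect_equal(get_parameter(base, "shared.nurse_rate"), 43.12)
  expect_equal(get_parameter(base, "rescue.mechanical_tools.cost"), 56.80)
  down <- set_parameter(base, "rescue.adrenaline.prob", 0.39)
  expect_equal(down$rescue$prob[down$rescue$component == "adrenaline"], 0.39)

  expect_error(set_parameter(base, "nonexistent.path", 1),
               class = "bim_lookup_error")
  expect_error(set_parameter(base, "reference.p_failure", 1.5),
               class = "bim_range_error")
  expect_error(set_parameter(base, "reference.patients_per_vial", 0.5),
               class = "bim_range_error")
  expect_error(set_parameter(base, "intervention.wait_before_surgery_min", -1),
               class = "bim_range_error")
})
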