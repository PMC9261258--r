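# a minimal one-scenario step used across these tests: calibrate k_div
# against an in vitro radius series generated from a known value
known_truth_step <- function(max_generations = 40L, extra_free = NULL,
                             n_restarts = 1L) {
  p_true <- growth_params(k_div = 0.15, k_q = 1, k_n = 0.3, k_lys = 0.1,
                          L_p = 1e7, L_v = 1e7)
  sc <- growth_scenario("in_vitro", n0 = 1000, horizon = 10,
                        grid = seq(0, 10, 2))
  tr <- simulate_growth(p_true, sc)
  series <- data.frame(time = tr$t, mean = tr$radius_um,
                       sd = 0.02 * tr$radius_um)
  step <- calibration_step(
    "fit_kdiv", scenarios = list(main = sc),
    free = c("k_div", extra_free),
    constraints = objective_spec(list(
      data_constraint("radius", "radius_um", series, scenario = "main"))),
    stop_threshold = 0.9999, max_generations = max_generations,
    n_restarts = n_restarts)
  list(step = step, p_true = p_true,
       base = growth_params(k_div = 0.05, k_q = 1, k_n = 0.3,
                            k_lys = 0.1, L_p = 1e7, L_v = 1e7),
       specs = list(k_div = parameter_spec("k_div", 0.01, 0.5, init = 0.05),
                    k_lys = parameter_spec("k_lys", 0.01, 0.5, init = 0.1)))
}

test_that("a single-step plan recovers a known parameter", {
  fx <- known_truth_step()
  res <- run_plan(list(fx$step), fx$specs, fx$base, seed = 1)
  expect_s3_class(res, "plan_result")
  expect_gte(res$steps$fit_kdiv$objective, 0.9999)
  expect_equal(unname(res$merged[["k_div"]]), 0.15, tolerance = 0.1)
  expect_equal(res$params$k_div, unname(res$merged[["k_div"]]))
})

test_that("plans are reproducible under a fixed master seed", {
  fx <- known_truth_step(max_generations = 15L)
  r1 <- run_plan(list(fx$step), fx$specs, fx$base, seed = 7)
  r2 <- run_plan(list(fx$step), fx$specs, fx$base, seed = 7)
  expect_identical(r1$merged, r2$merged)
  expect_identical(r1$steps$fit_kdiv$result$history,
                   r2$steps$fit_kdiv$result$history)
})

test_that("unknown free parameters are configuration errors", {
  fx <- known_truth_step()
  bad <- fx$step
  bad$free <- c("k_div", "not_a_parameter")
  expect_error(run_plan(list(bad), fx$specs, fx$base, seed = 1),
               "unknown parameters")
  bad2 <- fx$step
  bad2$free <- "k_q" # known to the model but absent from the spec list
  expect_error(run_plan(list(bad2), fx$specs, fx$base, seed = 1),
               "unknown parameters")
})

test_that("narrow_ranges freezes or shrinks solved parameters", {
  specs <- list(a = parameter_spec("a", 0, 10, init = 5),
                b = parameter_spec("b", 1, 100, init = 10,
                                   log_scale = TRUE))
  fake <- list(best_par = c(a = 4, b = 20),
               final_sd = c(a = 0.5, b = NA),
               final_sd_internal = c(a = 0.05, b = 0.02))
  frozen <- narrow_ranges(fake, specs, "freeze")
  expect_equal(frozen$a$lower, 4)
  expect_equal(frozen$a$upper, 4)

  shrunk <- narrow_ranges(fake, specs, "interval", k = 3)
  expect_equal(shrunk$a$lower, 2.5)
  expect_equal(shrunk$a$upper, 5.5)
  expect_lte(shrunk$b$upper, 100) # never widens beyond original bounds
  expect_gte(shrunk$b$lower, 1)
  expect_lt(shrunk$b$lower, 20)

  # zero final spread degenerates to a freeze
  fake0 <- list(best_par = c(a = 4), final_sd = c(a = 0),
                final_sd_internal = c(a = 0))
  expect_equal(narrow_ranges(fake0, specs["a"], "interval")$a$upper, 4)
  # interval edges clamp at the original bounds
  fake_edge <- list(best_par = c(a = 9.9), final_sd = c(a = 1),
                    final_sd_internal = c(a = 0.1))
  expect_equal(narrow_ranges(fake_edge, specs["a"], "interval")$a$upper, 10)
})

test_that("carry-over verification re-simulates earlier steps", {
  fx <- known_truth_step()
  # empty earlier-step list gives an empty report
  empty <- verify_carryover(c(k_div = 0.15), list(), fx$base)
  expect_equal(nrow(empty), 0)

  report_good <- verify_carryover(c(k_div = 0.15), list(fx$step), fx$base)
  expect_true(all(report_good$pass))
  # an adversarial merged set violating the earlier constraint fails
  report_bad <- verify_carryover(c(k_div = 0.45), list(fx$step), fx$base)
  expect_false(any(report_bad$pass))
})

test_that("two-step plans freeze step-1 solutions and guard carry-over", {
  fx <- known_truth_step()
  # step 2 frees an unrelated parameter; step-1 result must be frozen and
  # its constraint still satisfied
  step2 <- fx$step
  step2$name <- "second"
  step2$free <- "k_lys"
  res <- run_plan(list(fx$step, step2), fx$specs, fx$base, seed = 3)
  expect_named(res$steps, c("fit_kdiv", "second"))
  expect_true(all(res$carryover$pass))
  expect_equal(unname(res$merged[["k_div"]]), 0.15, tolerance = 0.1)
  # search dimensionality never grew: each step searched one parameter
  expect_length(res$steps$second$solved, 1L)
})

test_that("steps re-freeing an earlier parameter stay guarded", {
  fx <- known_truth_step()
  step2 <- fx$step
  step2$name <- "refree"
  step2$free <- c("k_div", "k_lys") # re-frees the step-1 parameter
  res <- run_plan(list(fx$step, step2), fx$specs, fx$base, seed = 4)
  expect_true(all(res$carryover$pass))
  # the re-freed parameter is genuinely searched again over its original
  # bounds, not left frozen at the step-1 value
  expect_setequal(res$steps$refree$result$state$free, c("k_div", "k_lys"))
})

test_that("gefitinib exposure routes into dosed scenarios", {
  p <- surrogate_base_params()
  step <- calibration_step(
    "dose", scenarios = list(gef = xenograft_scenario("egfr_gefitinib",
                                                      conc_nM = 1)),
    free = "gef_conc_nM",
    constraints = objective_spec(list(
      binary_constraint("shrinks", "volume_mm3", "less", 190,
                        time_window = "final", scenario = "gef"))))
  trajs_low <- simulate_step_scenarios(step, p, c(gef_conc_nM = 0))
  trajs_high <- simulate_step_scenarios(step, p, c(gef_conc_nM = 100))
  v_low <- trajs_low$gef$volume_mm3
  v_high <- trajs_high$gef$volume_mm3
  expect_lt(v_high[length(v_high)], v_low[length(v_low)])
})

test_that("invalid parameter regions score zero instead of crashing", {
  p <- surrogate_base_params()
  step <- calibration_step(
    "geom", scenarios = list(s = spheroid_scenario()),
    free = c("L_p", "L_v"),
    constraints = objective_spec(list(
      binary_constraint("alive", "radius_um", "greater", 0,
                        time_window = "final", scenario = "s"))))
  fn <- stepcal:::step_objective_fn(step, p)
  expect_equal(fn(c(L_p = 300, L_v = 100)), 0) # L_p > L_v
  expect_gt(fn(c(L_p = 100, L_v = 300)), 0)
})
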