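#' Worked example: stepwise lung-adenocarcinoma calibration
#'
#' The package's end-to-end example calibrates the rim-structured growth
#' model in three ordered steps, mirroring how multiscale tumor models
#' are calibrated against data of different grain:
#'
#' * **Step 1 (in vitro):** spheroid radius dynamics of a KRAS-mutant
#'   line — frees the core growth/geometry parameters (`k_div`, `k_q`,
#'   `k_n`, `k_lys`, `L_p`, `L_v`) against the synthetic spheroid radius
#'   series, knowledge anchors on the reported radii, and a loose
#'   viable-fraction rule.
#' * **Step 2 (in vivo growth):** both untreated mouse-xenograft volume
#'   arms (EGFR exon-19-deletion and EGFR+PIK3CA lines under placebo) —
#'   frees the vascular, immune and cell-line parameters and re-frees
#'   the weakly in-vitro-identified `L_v`, `k_n`, `k_lys`, with the
#'   spheroid constraints kept inside the objective.
#' * **Step 3 (treatment):** all four arms with gefitinib dosing active
#'   — frees the treatment pharmacodynamics (`k_apo`, `gef_conc_nM`,
#'   clearance capacity `N_lys`) and re-frees `d_ang`, `a_ang`, `k_n`,
#'   `k_lys`; earlier constraints stay in the objective and carry-over
#'   verification re-checks steps 1-2 afterwards.
#'
#' Rates are calibrated at the 2.63 g in vitro reference mass and
#' transferred to the 23 g mouse allometrically (exponent -1/4) inside
#' the simulator.
#'
#' @name luad_surrogate
NULL

#' Baseline growth parameters of the worked example
#'
#' The pre-calibration state: literature-plausible orders of magnitude,
#' deliberately not fitted (the in vitro radius slope they produce is
#' well below the measured one).
#'
#' @return A [growth_params()] object.
#' @export
surrogate_base_params <- function() {
  growth_params(k_div = 0.05, k_q = 0.5, k_n = 0.3, k_lys = 0.2,
                L_p = 150, L_v = 300, d_ang = 0.1, a_ang = 12,
                N_half = 5e6, N_lys = 1e8, e_imm = 0.01, I_max = 0.95,
                k_apo = 1, egfr_prolif_mult = 1.2,
                pik3ca_prolif_mult = 0.6, ref_mass_g = 2.63)
}

#' Search space of the worked example
#'
#' @return Named list of [parameter_spec()]s for every parameter either
#'   calibration step frees.
#' @export
surrogate_parameter_specs <- function() {
  specs <- list(
    parameter_spec("k_div", 0.01, 0.3, init = 0.05, unit = "1/day",
                   allometric = TRUE),
    parameter_spec("k_q", 0.05, 3, init = 0.5, unit = "1/day",
                   log_scale = TRUE, allometric = TRUE),
    parameter_spec("k_n", 0.02, 1.5, init = 0.3, unit = "1/day",
                   log_scale = TRUE, allometric = TRUE),
    parameter_spec("k_lys", 0.02, 1.5, init = 0.2, unit = "1/day",
                   log_scale = TRUE, allometric = TRUE),
    parameter_spec("L_p", 40, 400, init = 150, unit = "um"),
    parameter_spec("L_v", 80, 800, init = 300, unit = "um"),
    parameter_spec("egfr_prolif_mult", 0.8, 4, init = 1.2),
    parameter_spec("pik3ca_prolif_mult", 0.2, 1.2, init = 0.6),
    parameter_spec("a_ang", 0.5, 40, init = 15, log_scale = TRUE),
    parameter_spec("d_ang", 0.03, 0.8, init = 0.1, unit = "1/day",
                   log_scale = TRUE, allometric = TRUE),
    parameter_spec("N_lys", 1e7, 1e10, init = 1e8, log_scale = TRUE),
    parameter_spec("e_imm", 0.001, 0.06, init = 0.01, unit = "1/day",
                   log_scale = TRUE, allometric = TRUE),
    parameter_spec("I_max", 0.6, 1, init = 0.95),
    parameter_spec("k_apo", 0.05, 4, init = 1, unit = "1/day",
                   log_scale = TRUE, allometric = TRUE),
    parameter_spec("gef_conc_nM", 1, 200, init = 30, log_scale = TRUE)
  )
  names(specs) <- vapply(specs, `[[`, character(1L), "name")
  specs
}

#' In vitro spheroid scenario of the worked example
#'
#' KRAS-mutant line, 150 um initial radius, 30-day horizon, no
#' treatment.
#'
#' @param grid Output times (days).
#' @return A [growth_scenario()].
#' @export
spheroid_scenario <- function(grid = seq(0, 30, by = 1)) {
  growth_scenario("in_vitro", mutation_profile(kras = TRUE),
                  horizon = 30, grid = grid,
                  n0 = cells_from_radius(150))
}

#' Xenograft scenario for one study arm
#'
#' 200 mm^3 established tumor at day 0, 30-day horizon, 23 g mouse.
#' Treated arms receive a constant effective gefitinib exposure
#' (calibrated surrogate of the 25 mg/kg oral dose) from day 0.
#'
#' @param arm One of `"egfr_placebo"`, `"egfr_gefitinib"`,
#'   `"egfr_pik3ca_placebo"`, `"egfr_pik3ca_gefitinib"`.
#' @param conc_nM Gefitinib exposure for treated arms (overridden by the
#'   calibrated `gef_conc_nM` during plan evaluation).
#' @param grid Output times (days).
#' @return A [growth_scenario()].
#' @export
xenograft_scenario <- function(arm, conc_nM = 10,
                               grid = seq(0, 30, by = 1)) {
  arm <- match.arg(arm, c("egfr_placebo", "egfr_gefitinib",
                          "egfr_pik3ca_placebo", "egfr_pik3ca_gefitinib"))
  pik <- grepl("pik3ca", arm)
  treated <- grepl("gefitinib", arm)
  growth_scenario(
    "xenograft",
    mutation_profile(egfr_ex19del = TRUE, pik3ca = pik),
    dosing = if (treated) list(conc_nM = conc_nM) else NULL,
    horizon = 30, grid = grid, n0 = cells_from_volume(200)
  )
}

#' Build the three-step calibration plan
#'
#' @param spheroid_data `synthetic_dataset` from
#'   [generate_spheroid_series()] (or a compatible series).
#' @param xenograft_data Named list of the four arm datasets from
#'   [generate_xenograft_arms()].
#' @param max_generations_1,max_generations_2 Per-step generation
#'   budgets.
#' @param n_restarts Independent CMA-ES restarts per step.
#' @return List of three [calibration_step()]s.
#' @export
surrogate_plan <- function(spheroid_data, xenograft_data,
                           max_generations_1 = 120L,
                           max_generations_2 = 100L,
                           n_restarts = 2L) {
  radius_con <- data_constraint("spheroid_radius", "radius_um",
                                spheroid_data$series, weight = 1,
                                scenario = "spheroid")
  # viable-fraction knowledge rule: by day 30 a spheroid has a necrotic
  # core but keeps a living rim (thresholds are placeholders, user-set)
  viable_con <- binary_constraint("viable_rim", "prolif_fraction",
                                  "between", c(0.01, 0.9),
                                  time_window = "final", weight = 0.25,
                                  scenario = "spheroid")
  # anchor constraints encoding the reported growth descriptors (~12.5
  # um/day over days 0-20 reaching ~400 um, then plateau onset): tight
  # single-point data rules whose 2-SD half-width is 2.5% of the value
  known1 <- list(
    anchor_constraint("radius_anchors", "radius_um",
                      times = c(5, 10, 20, 30),
                      values = c(212.5, 275, 400, 450),
                      rel_2sd = 0.025, weight = 1.5, scenario = "spheroid")
  )
  step1 <- calibration_step(
    "invitro_spheroid",
    scenarios = list(spheroid = spheroid_scenario()),
    free = c("k_div", "k_q", "k_n", "k_lys", "L_p", "L_v"),
    constraints = objective_spec(c(list(radius_con, viable_con), known1)),
    carryover = objective_spec(list(radius_con, viable_con)),
    stop_threshold = 0.999, max_generations = max_generations_1,
    n_restarts = n_restarts,
    priority_notes = paste(
      "first: best documented data, lowest granularity (single avascular",
      "spheroid), least connected (no vascular/immune/drug coupling)")
  )

  arms <- names(xenograft_data)
  arm_cons <- lapply(arms, function(a) {
    # the treated sensitive arm carries the richest dynamics (shrink +
    # plateau); it gets double weight
    w <- if (a == "egfr_gefitinib") 2 else 1
    data_constraint(a, "volume_mm3", xenograft_data[[a]]$series,
                    weight = w, scenario = a)
  })
  names(arm_cons) <- arms
  scen <- lapply(arms, xenograft_scenario)
  names(scen) <- arms
  # anchor constraints from the reported arm behaviors: +20 mm^3/day to
  # ~600 mm^3 (EGFR placebo), -16 mm^3/day to ~40 mm^3 then plateau
  # (EGFR gefitinib), +7.5 mm^3/day (both PIK3CA arms)
  plc_anchor <- anchor_constraint("plc_anchors", "volume_mm3",
                                  times = c(10, 20), values = c(400, 600),
                                  rel_2sd = 0.025, weight = 1,
                                  scenario = "egfr_placebo")
  gef_anchor <- anchor_constraint("gef_anchors", "volume_mm3",
                                  times = c(5, 10, 28),
                                  values = c(120, 40, 40),
                                  rel_2sd = 0.1, weight = 1.5,
                                  scenario = "egfr_gefitinib")
  pik_anchor <- anchor_constraint("pik_anchors", "volume_mm3",
                                  times = c(10, 20), values = c(275, 350),
                                  rel_2sd = 0.025, weight = 1,
                                  scenario = "egfr_pik3ca_placebo")

  # step 2: untreated in vivo growth (both placebo arms), spheroid fit
  # carried inside the objective
  step2 <- calibration_step(
    "invivo_growth",
    scenarios = c(scen[c("egfr_placebo", "egfr_pik3ca_placebo")],
                  list(spheroid = spheroid_scenario())),
    free = c("egfr_prolif_mult", "pik3ca_prolif_mult", "a_ang",
             "e_imm", "L_v", "k_n", "k_lys"),
    constraints = objective_spec(list(
      arm_cons$egfr_placebo, arm_cons$egfr_pik3ca_placebo,
      plc_anchor, pik_anchor, radius_con)),
    carryover = objective_spec(list(arm_cons$egfr_placebo,
                                    arm_cons$egfr_pik3ca_placebo)),
    stop_threshold = 0.999, max_generations = max_generations_2,
    n_restarts = n_restarts, init_sd_frac = 0.2,
    priority_notes = "second: adds vascular and immune couplings"
  )

  # step 3: treatment response (both treated arms); the untreated arms
  # and the spheroid stay in the objective because the re-freed
  # vascular/death parameters touch them too
  step3 <- calibration_step(
    "invivo_treatment",
    scenarios = c(scen, list(spheroid = spheroid_scenario())),
    free = c("k_apo", "gef_conc_nM", "d_ang", "a_ang",
             "k_n", "k_lys", "N_lys"),
    constraints = objective_spec(c(
      arm_cons, list(gef_anchor, plc_anchor, pik_anchor, radius_con))),
    stop_threshold = 0.92, max_generations = max_generations_2,
    n_restarts = n_restarts, init_sd_frac = 0.15,
    prescreen = c(k_apo = 4L, d_ang = 3L, k_lys = 4L, N_lys = 3L),
    priority_notes = "third: treatment pharmacodynamics, most connected"
  )
  list(step1, step2, step3)
}

#' Run the full stepwise calibration on synthetic data
#'
#' Generates the synthetic datasets (seeded), builds the plan and runs
#' it. This is the package's end-to-end worked example.
#'
#' @param seed Master seed (datasets and optimizer).
#' @param ... Passed to [surrogate_plan()].
#' @return List: `plan_result` ([run_plan()] output), `datasets`, the
#'   calibrated `params`, and the calibrated gefitinib exposure.
#' @export
calibrate_surrogate <- function(seed = 1L, ...) {
  spheroid <- generate_spheroid_series(seed)
  xeno <- generate_xenograft_arms(seed)
  plan <- surrogate_plan(spheroid, xeno, ...)
  res <- run_plan(plan, surrogate_parameter_specs(),
                  surrogate_base_params(), seed = seed)
  list(plan_result = res, datasets = list(spheroid = spheroid,
                                          xenograft = xeno),
       params = res$params,
       gef_conc_nM = unname(res$merged[["gef_conc_nM"]]))
}
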