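test_that("geometry formulas are exact", {
  expect_equal(tumor_volume(2.8e8, 0, 0, 2.8e8), 1)
  expect_equal(tumor_volume(0, 0, 0, 2.8e8), 0)
  expect_equal(tumor_volume(1e6, 2e6, 3e6, 2.8e8),
               tumor_volume(1e6, 0, 0, 2.8e8) +
                 tumor_volume(0, 2e6, 3e6, 2.8e8))
  expect_error(tumor_volume(1, 1, 1, 0), "positive")

  expect_equal(tumor_radius(4 * pi / 3), 1)
  expect_equal(tumor_radius(0), 0)
  v <- 0.37
  expect_equal(tumor_radius(8 * v), 2 * tumor_radius(v))
  expect_error(tumor_radius(-1), "nonnegative")

  # round trip through the initial-count helpers
  expect_equal(tumor_radius(cells_from_radius(150) / 2.8e8) * 1e4, 150,
               tolerance = 1e-9)
  expect_equal(cells_from_volume(200) / 2.8e8 * 1e3, 200)
})

test_that("stored literature constants match the published values", {
  lit <- mutation_literature()
  expect_identical(lit$kras_hydrolysis_reduction, 0.98)
  expect_identical(lit$egfr_atp_km_wt_uM, 5.0)
  expect_identical(lit$egfr_atp_km_mut_uM, 129)
  expect_identical(lit$gefitinib_ki_wt_nM, 16.4)
  expect_identical(lit$gefitinib_ki_mut_nM, 0.833)
  expect_identical(lit$gefitinib_ic50_mut_nM, 6)
  expect_identical(lit$pik3ca_pi3k_fold, 2.7)
})

test_that("mutation profiles map onto effective parameters", {
  p <- growth_params(egfr_prolif_mult = 1.4, pik3ca_prolif_mult = 0.6)
  wt <- apply_mutations(p, mutation_profile())
  expect_equal(wt$pd$ki_nM, 16.4)
  expect_false(wt$pd$sensitive)
  expect_equal(wt$params$prolif_mult, 1)

  egfr <- apply_mutations(p, mutation_profile(egfr_ex19del = TRUE))
  expect_equal(egfr$pd$ki_nM, 0.833)
  expect_true(egfr$pd$sensitive)
  expect_equal(egfr$params$prolif_mult, 1.4)

  pik <- apply_mutations(p, mutation_profile(egfr_ex19del = TRUE,
                                             pik3ca = TRUE))
  expect_equal(pik$pd$b_res, 1) # constitutive PI3K: full resistance
  expect_equal(pik$params$prolif_mult, 1.4 * 0.6)
  expect_equal(pik$literature$pik3ca_pi3k_fold, 2.7)

  kras <- apply_mutations(p, mutation_profile(kras = TRUE))
  expect_equal(kras$params$prolif_mult, 1 + 0.98)
})

test_that("gefitinib inhibition saturates and respects resistance", {
  expect_equal(gefitinib_inhibition(0, 1), 0)
  expect_equal(gefitinib_inhibition(5, 5, b_res = 0, I_max = 1), 0.5)
  expect_equal(gefitinib_inhibition(1e6, 1, b_res = 1, I_max = 1), 0)
  expect_equal(gefitinib_inhibition(1e9, 0.833, b_res = 0, I_max = 0.9),
               0.9, tolerance = 1e-6)
})

test_that("unlimited in vitro growth is exponential at k_div", {
  p <- growth_params(k_div = 0.2, k_q = 1, k_n = 0.5, k_lys = 0.1,
                     L_p = 1e7, L_v = 1e7) # rims never bind
  sc <- growth_scenario("in_vitro", n0 = 1000, horizon = 20,
                        grid = seq(0, 20, 5))
  tr <- simulate_growth(p, sc)
  expect_equal(tr$nb_pc, 1000 * exp(0.2 * tr$t), tolerance = 1e-5)
  # radius grows as exp(k_div t / 3)
  expect_equal(tr$radius_um / tr$radius_um[1],
               exp(0.2 * tr$t / 3), tolerance = 1e-5)
  expect_true(all(tr$A == 0))
  expect_true(all(tr$prolif_fraction == 1))
})

test_that("all-zero rates leave the state constant", {
  p <- growth_params(k_div = 0, k_q = 0, k_n = 0, k_lys = 0, A_max = 0,
                     d_ang = 0, a_ang = 0, e_imm = 0)
  tr <- simulate_growth(p, growth_scenario("in_vitro", n0 = 5000,
                                           horizon = 10))
  expect_equal(tr$nb_pc, rep(5000, nrow(tr)), tolerance = 1e-8)
  expect_equal(tr$nb_qc, rep(0, nrow(tr)))
})

test_that("compartments stay nonnegative across random parameter draws", {
  set.seed(21)
  for (i in 1:8) {
    p <- growth_params(k_div = runif(1, 0, 0.5), k_q = runif(1, 0, 2),
                       k_n = runif(1, 0, 1), k_lys = runif(1, 0, 1),
                       L_p = runif(1, 50, 200), L_v = runif(1, 200, 500),
                       A_max = runif(1, 0, 1), d_ang = runif(1, 0.05, 0.5),
                       a_ang = runif(1, 0, 10), e_imm = runif(1, 0, 0.05),
                       k_apo = runif(1, 0, 1))
    mode <- if (i %% 2 == 0) "xenograft" else "in_vitro"
    dosing <- if (i %% 4 == 0) list(conc_nM = 20) else NULL
    sc <- growth_scenario(mode, mutation_profile(egfr_ex19del = TRUE),
                          dosing = dosing, n0 = 1e5, horizon = 20)
    tr <- simulate_growth(p, sc)
    expect_true(all(tr$nb_pc >= 0 & tr$nb_qc >= 0 & tr$nb_nc >= 0 &
                      tr$A >= 0))
    expect_true(all(is.finite(tr$volume_mm3)))
  }
})

test_that("without loss pathways the total count never decreases", {
  p <- growth_params(k_div = 0.1, k_q = 1, k_n = 0.4, k_lys = 0,
                     L_p = 100, L_v = 200, e_imm = 0)
  tr <- simulate_growth(p, growth_scenario("in_vitro",
                                           n0 = cells_from_radius(150),
                                           horizon = 30))
  total <- tr$nb_pc + tr$nb_qc + tr$nb_nc
  expect_true(all(diff(total) >= -1e-6 * total[-1]))
  # radius is a monotone function of total count
  expect_true(all(diff(tr$radius_um) >= -1e-6 * tr$radius_um[-1]))
})

test_that("in vitro mode forces vascular and immune terms to zero", {
  p <- growth_params(A_max = 1, a_ang = 10, e_imm = 0.5, k_q = 0.5,
                     k_div = 0.1)
  tr <- simulate_growth(p, growth_scenario("in_vitro", n0 = 1e5,
                                           horizon = 10))
  expect_true(all(tr$A == 0))
  # same parameters without immune kill give the identical trajectory
  p0 <- p; p0$e_imm <- 0
  tr0 <- simulate_growth(p0, growth_scenario("in_vitro", n0 = 1e5,
                                             horizon = 10))
  expect_equal(tr$nb_pc, tr0$nb_pc, tolerance = 1e-10)
})

test_that("allometric transfer commutes with simulation", {
  p_ref <- growth_params(k_div = 0.12, k_q = 0.8, k_n = 0.3, k_lys = 0.2,
                         L_p = 120, L_v = 300, ref_mass_g = 2.63)
  sc23 <- growth_scenario("xenograft", body_mass_g = 23, n0 = 1e6,
                          horizon = 15, init = "proliferating")
  tr1 <- simulate_growth(p_ref, sc23)
  # manually pre-scale every rate to 23 g and declare that mass as the
  # reference: identical trajectory
  f <- (23 / 2.63)^(-1 / 4)
  p_scaled <- growth_params(k_div = 0.12 * f, k_q = 0.8 * f,
                            k_n = 0.3 * f, k_lys = 0.2 * f, L_p = 120,
                            L_v = 300, A_max = p_ref$A_max,
                            d_ang = p_ref$d_ang * f,
                            a_ang = p_ref$a_ang,
                            e_imm = p_ref$e_imm * f,
                            k_apo = p_ref$k_apo * f, ref_mass_g = 23)
  tr2 <- simulate_growth(p_scaled, sc23)
  expect_equal(tr1$volume_mm3, tr2$volume_mm3, tolerance = 1e-8)
})

test_that("the adaptive integrator agrees with a fixed-step RK4 oracle", {
  p <- growth_params(k_div = 0.12, k_q = 0.6, k_n = 0.3, k_lys = 0.15,
                     L_p = 120, L_v = 250)
  n0 <- cells_from_radius(150)
  times <- seq(0, 30, by = 5)
  tr <- simulate_growth(p, growth_scenario("in_vitro", n0 = n0,
                                           horizon = 30, grid = times))
  oracle <- rk4_rim_model(p, n0, times, dt = 1e-3)
  for (v in c("nb_pc", "nb_qc", "nb_nc")) {
    scale <- pmax(abs(oracle[[v]]), 1e-3 * n0)
    expect_lt(max(abs(tr[[v]] - oracle[[v]]) / scale), 1e-3)
  }
})

test_that("equilibrated initialization yields a composed established tumor", {
  p <- surrogate_base_params()
  sc <- xenograft_scenario("egfr_placebo")
  y0 <- equilibrated_state(p, sc)
  expect_equal(sum(y0[1:3]), cells_from_volume(200), tolerance = 1e-6)
  expect_gt(y0[[1]], 0)       # proliferating cells present
  expect_gt(y0[[4]], 0)       # vascular support established
  tr <- simulate_growth(p, sc, y0 = y0)
  expect_equal(tr$volume_mm3[1], 200, tolerance = 1e-6)
  # explicit y0 reproduces the scenario's own equilibrated start
  tr2 <- simulate_growth(p, sc)
  expect_equal(tr$volume_mm3, tr2$volume_mm3, tolerance = 1e-8)
})

test_that("trajectory CSV export round-trips", {
  dir <- withr::local_tempdir()
  tr <- simulate_growth(growth_params(), growth_scenario("in_vitro",
                                                         n0 = 1e4,
                                                         horizon = 5))
  f <- file.path(dir, "traj.csv")
  write_trajectory_csv(tr, f)
  back <- utils::read.csv(f)
  expect_equal(names(back),
               c("t", "nb_pc", "nb_qc", "nb_nc", "A", "volume_mm3",
                 "radius_um", "prolif_fraction"))
  expect_equal(back$radius_um, tr$radius_um, tolerance = 1e-9)
})
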