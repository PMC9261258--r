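test_that("binary constraints apply strict comparators over windows", {
  traj <- make_traj(0:10, fn = function(t) rep(5, length(t)))
  expect_equal(score_constraint(
    binary_constraint("a", "y", "greater", 3), traj), 1)
  expect_equal(score_constraint(
    binary_constraint("a", "y", "greater", 5), traj), 0) # boundary fails
  expect_equal(score_constraint(
    binary_constraint("a", "y", "less", 5.0001), traj), 1)

  const05 <- make_traj(0:10, fn = function(t) rep(0.5, length(t)))
  expect_equal(score_constraint(
    binary_constraint("b", "y", "between", c(0.4, 0.6),
                      time_window = c(0, 10)), const05), 1)

  ramp <- make_traj(0:10, fn = identity)
  expect_equal(score_constraint(
    binary_constraint("c", "y", "greater", 4, time_window = c(5, 10)),
    ramp), 1)
  expect_equal(score_constraint(
    binary_constraint("c", "y", "greater", 4, time_window = c(0, 10)),
    ramp), 0)
  # "final" looks at the last sample only
  expect_equal(score_constraint(
    binary_constraint("d", "y", "greater", 9.5), ramp), 1)
})

test_that("binary constraint validation rejects bad configurations", {
  expect_error(binary_constraint("x", "y", "between", c(2, 1)),
               "lower < upper")
  expect_error(binary_constraint("x", "y", "greater", c(1, 2)),
               "single threshold")
  traj <- make_traj(0:10, fn = identity)
  expect_error(score_constraint(
    binary_constraint("x", "z", "greater", 1), traj),
    "no output variable")
  expect_error(score_constraint(
    binary_constraint("x", "y", "greater", 1, time_window = c(5, 20)),
    traj), "outside the simulated horizon")
})

test_that("continuous score is 1 inside the 2-SD band and decays as exp(1-r)", {
  series <- data.frame(time = c(1, 2, 3), mean = c(10, 20, 30),
                       sd = c(1, 2, 3))
  traj <- make_traj(0:4, fn = function(t) 10 * t)
  con <- data_constraint("fit", "y", series)
  expect_equal(score_constraint(con, traj), 1)

  # offset by exactly 2 sd at every point: boundary of the band
  off2 <- make_traj(0:4, fn = function(t) 10 * t + 2 * t)
  series2 <- data.frame(time = c(1, 2, 3), mean = c(10, 20, 30),
                        sd = c(1, 2, 3))
  expect_equal(score_constraint(data_constraint("f", "y", series2), off2),
               1, tolerance = 1e-12)

  # offset by 4 sd: r = 2 everywhere, phi = exp(-1)
  off4 <- make_traj(0:4, fn = function(t) 10 * t + 4 * t)
  expect_equal(score_constraint(data_constraint("f", "y", series2), off4),
               exp(-1), tolerance = 1e-12)
})

test_that("continuous score interpolates the model onto data times", {
  series <- data.frame(time = c(0.5, 1.5), mean = c(5, 15), sd = c(1, 1))
  traj <- make_traj(c(0, 1, 2), fn = function(t) 10 * t)
  expect_equal(score_constraint(data_constraint("f", "y", series), traj), 1)
})

test_that("zero/missing SDs fall back to a relative default", {
  series <- data.frame(time = 1, mean = 10, sd = 0)
  traj <- make_traj(0:2, fn = function(t) rep(12, length(t)))
  # fallback sd = 1, r = 2/2 = 1 -> still perfect
  expect_equal(score_constraint(data_constraint("f", "y", series), traj), 1)
  series0 <- data.frame(time = 1, mean = 0, sd = 0)
  traj0 <- make_traj(0:2, fn = function(t) rep(2, length(t)))
  # absolute fallback 1 when the mean is 0: r = 1
  expect_equal(score_constraint(data_constraint("f", "y", series0), traj0),
               1)
})

test_that("continuous score is invariant under affine rescaling", {
  set.seed(7)
  for (i in 1:10) {
    times <- sort(runif(5, 0, 10))
    series <- data.frame(time = times, mean = rnorm(5, 10),
                         sd = runif(5, 0.5, 2))
    traj <- make_traj(seq(0, 10, 0.5), fn = function(t) 10 + rnorm(21))
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    s1 <- score_constraint(data_constraint("f", "y", series), traj)
    series2 <- transform(series, mean = a * mean + b, sd = a * sd)
    traj2 <- traj; traj2$y <- a * traj2$y + b
    s2 <- score_constraint(data_constraint("f", "y", series2), traj2)
    expect_equal(s1, s2, tolerance = 1e-9)
  }
})

test_that("the weighted objective matches hand-computed values", {
  traj <- make_traj(0:1, fn = function(t) rep(1, length(t)))
  pass <- binary_constraint("pass", "y", "greater", 0, weight = 1)
  fail <- binary_constraint("fail", "y", "greater", 2, weight = 1)
  expect_equal(objective_value(objective_spec(list(pass, fail)), traj), 0.5)

  spec2 <- objective_spec(list(
    binary_constraint("a", "y", "greater", 0, weight = 2),
    binary_constraint("b", "y", "greater", 0.5, weight = 1),
    binary_constraint("c", "y", "greater", 2, weight = 1)))
  expect_equal(objective_value(spec2, traj), 0.75)
})

test_that("objective normalization and monotonicity invariants hold", {
  set.seed(11)
  for (i in 1:20) {
    traj <- make_traj(0:10, fn = function(t) cumsum(rnorm(length(t))))
    w <- runif(3, 0.1, 3)
    cons <- list(
      binary_constraint("b1", "y", "greater", rnorm(1), weight = w[1]),
      data_constraint("d1", "y",
                      data.frame(time = c(2, 5), mean = rnorm(2),
                                 sd = runif(2, 0.5, 1)), weight = w[2]),
      binary_constraint("b2", "y", "less", rnorm(1), weight = w[3]))
    f1 <- objective_value(objective_spec(cons), traj)
    expect_gte(f1, 0); expect_lte(f1, 1)
    # uniform weight rescaling leaves f unchanged
    cons_scaled <- lapply(cons, function(cc) { cc$weight <- cc$weight * 3.7; cc })
    expect_equal(objective_value(objective_spec(cons_scaled), traj), f1,
                 tolerance = 1e-12)
  }
  # f is monotone in each sub-score: replacing a failing binary with a
  # passing one cannot decrease f
  traj <- make_traj(0:1, fn = function(t) rep(1, length(t)))
  lo <- objective_value(objective_spec(list(
    binary_constraint("a", "y", "greater", 2, weight = 1),
    binary_constraint("b", "y", "greater", 0, weight = 2))), traj)
  hi <- objective_value(objective_spec(list(
    binary_constraint("a", "y", "greater", 0, weight = 1),
    binary_constraint("b", "y", "greater", 0, weight = 2))), traj)
  expect_gte(hi, lo)
})

test_that("zero total weight is a configuration error", {
  expect_error(objective_spec(list(
    binary_constraint("a", "y", "greater", 0, weight = 0))),
    "weight")
})

test_that("series CSV and YAML objective configs round-trip", {
  dir <- withr::local_tempdir()
  ds <- generate_spheroid_series(3)
  csv <- file.path(dir, "radius.csv")
  write_dataset_csv(ds, csv)
  back <- read_series_csv(csv)
  expect_equal(back$mean, ds$series$mean, tolerance = 1e-9)

  cfg <- file.path(dir, "objective.yaml")
  yaml::write_yaml(list(constraints = list(
    list(type = "binary", name = "cap", variable = "radius_um",
         comparator = "less", threshold = 1000, time_window = "final",
         weight = 0.5),
    list(type = "data", name = "fit", variable = "radius_um",
         series_file = "radius.csv", weight = 1))), cfg)
  spec <- read_objective_config(cfg)
  expect_s3_class(spec, "objective_spec")
  expect_named(spec$constraints, c("cap", "fit"))
  expect_equal(spec$constraints$fit$series$sd, ds$series$sd,
               tolerance = 1e-9)
})
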