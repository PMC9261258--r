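#' Synthetic calibration datasets
#'
#' Generators emulating the two calibration data sources of the worked
#' example: in vitro spheroid radius time courses and four mouse-xenograft
#' tumor-volume arms. Only the published growth behaviors (slopes, the
#' day-20 radius, plateau onsets) are treated as ground truth; sampling
#' grids, initial sizes, SD schedules and plateau shapes are declared
#' design constants echoed into each dataset. Noise is additive Gaussian
#' on the means (sd/4), so different seeds share the same design and
#' differ only in noise.
#'
#' @name synthetic_data
NULL

# design constants (echoed into every dataset)
.spheroid_design <- list(
  r0_um = 150, slope_um_day = 12.5, ramp_days = 20, radius_day20 = 400,
  plateau_um = 480, tail_rate = 0.1, days = seq(0, 30, by = 2),
  sd_frac = 0.08, noise_frac = 0.25
)

.xenograft_design <- list(
  v0_mm3 = 200, days = seq(0, 28, by = 3.5), sd_frac = 0.10,
  noise_frac = 0.25,
  arms = list(
    egfr_placebo = list(slope = 20, ramp_days = 20),
    egfr_gefitinib = list(slope = -16, ramp_days = 10, plateau = 40),
    egfr_pik3ca_placebo = list(slope = 7.5, ramp_days = 20),
    egfr_pik3ca_gefitinib = list(slope = 7.5, ramp_days = 20)
  )
)

# noise-free spheroid radius design mean (um)
spheroid_mean <- function(t) {
  d <- .spheroid_design
  ramp <- d$r0_um + d$slope_um_day * pmin(t, d$ramp_days)
  tail <- (d$plateau_um - d$radius_day20) *
    (1 - exp(-d$tail_rate * pmax(t - d$ramp_days, 0)))
  ramp + tail
}

# noise-free xenograft volume design mean (mm^3) for one arm
xenograft_mean <- function(t, arm) {
  d <- .xenograft_design
  a <- d$arms[[arm]]
  if (is.null(a)) stop("unknown xenograft arm '", arm, "'; arms: ",
                       paste(names(d$arms), collapse = ", "), call. = FALSE)
  m <- d$v0_mm3 + a$slope * pmin(t, a$ramp_days)
  if (!is.null(a$plateau)) m[t > a$ramp_days] <- a$plateau
  if (a$slope > 0) { # growth arms: the ramp slope halves past the window,
    # saturating exponentially (mild plateau onset)
    past <- t > a$ramp_days
    m[past] <- d$v0_mm3 + a$slope * a$ramp_days +
      (a$slope / 2) * 10 * (1 - exp(-(t[past] - a$ramp_days) / 10))
  }
  m
}

new_synthetic_dataset <- function(label, series, truth, seed) {
  structure(list(label = label, series = series, truth = truth, seed = seed),
            class = "synthetic_dataset")
}

#' Generate a synthetic spheroid radius dataset
#'
#' Radius (um) sampled every 2 days over 30 days: linear growth of
#' 12.5 um/day from 150 um, reaching 400 um at day 20, then a saturating
#' approach to a 480 um plateau. SDs are 8% of the design mean; observed
#' means carry seeded additive Gaussian noise of sd/4.
#'
#' @param seed Integer seed for the noise.
#' @return A `synthetic_dataset`: `$series` data frame
#'   (`time`, `mean`, `sd`), `$truth` design descriptor, `$seed`.
#' @export
generate_spheroid_series <- function(seed = 1L) {
  d <- .spheroid_design
  mu <- spheroid_mean(d$days)
  sd <- d$sd_frac * mu
  set.seed(seed)
  obs <- mu + stats::rnorm(length(mu), 0, sd * d$noise_frac)
  new_synthetic_dataset(
    "spheroid_radius",
    data.frame(time = d$days, mean = obs, sd = sd),
    c(d, list(design_mean = mu)), seed
  )
}

#' Generate a synthetic xenograft volume arm
#'
#' Tumor volume (mm^3) sampled twice weekly over 4 weeks from 200 mm^3.
#' Arms: `egfr_placebo` grows +20 mm^3/day over days 0-20;
#' `egfr_gefitinib` shrinks -16 mm^3/day over days 0-10 then plateaus;
#' `egfr_pik3ca_placebo` and `egfr_pik3ca_gefitinib` share an identical
#' +7.5 mm^3/day design (gefitinib has no effect on the resistant line).
#' SDs are 10% of the design mean; seeded noise as in
#' [generate_spheroid_series()].
#'
#' @param arm Arm name (see above).
#' @param seed Integer seed for the noise.
#' @return A `synthetic_dataset`.
#' @export
generate_xenograft_series <- function(arm, seed = 1L) {
  d <- .xenograft_design
  mu <- xenograft_mean(d$days, arm)
  sd <- d$sd_frac * mu
  # the two PIK3CA arms share one noise stream: identical designs stay
  # identical datasets (treatment truly has no effect)
  noise_seed <- if (grepl("pik3ca", arm)) seed + 211L else seed
  set.seed(noise_seed)
  obs <- mu + stats::rnorm(length(mu), 0, sd * d$noise_frac)
  new_synthetic_dataset(
    arm,
    data.frame(time = d$days, mean = obs, sd = sd),
    c(d["v0_mm3"], d$arms[[arm]], list(design_mean = mu)), seed
  )
}

#' Generate all four xenograft arms
#'
#' @param seed Integer seed.
#' @return Named list of `synthetic_dataset` objects.
#' @export
generate_xenograft_arms <- function(seed = 1L) {
  arms <- names(.xenograft_design$arms)
  out <- lapply(arms, generate_xenograft_series, seed = seed)
  names(out) <- arms
  out
}

#' Write a synthetic dataset to CSV
#'
#' Writes `time,mean,sd` rows preceded by `#`-comment header lines that
#' record the label, seed and design constants, so the file round-trips
#' through [read_series_csv()].
#'
#' @param dataset A `synthetic_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(dataset, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# synthetic dataset: %s (seed %d)",
                     dataset$label, dataset$seed), con)
  flat <- unlist(dataset$truth[!vapply(dataset$truth, is.list, logical(1L))])
  writeLines(sprintf("# design: %s",
                     paste(sprintf("%s=%g", names(flat), flat),
                           collapse = " ")), con)
  utils::write.table(dataset$series, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Least-squares slope of a series over a time window
#'
#' Utility used throughout the examples and checks: ordinary
#' least-squares slope of `value ~ time` restricted to
#' `from <= time <= to`.
#'
#' @param time,value Numeric vectors.
#' @param from,to Window bounds (days).
#' @return The fitted slope.
#' @export
fit_slope <- function(time, value, from = min(time), to = max(time)) {
  keep <- time >= from - 1e-9 & time <= to + 1e-9
  stats::coef(stats::lm(value[keep] ~ time[keep]))[[2L]]
}
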