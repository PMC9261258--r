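#' Constraint scoring
#'
#' Biological constraints are translated into sub-scores in `[0, 1]` and
#' combined into one weighted objective
#' \deqn{f(\theta) = \frac{\sum_k \omega_k s_k(y(\theta))}{\sum_k \omega_k}}
#' where \eqn{y(\theta)} is the simulated trajectory, \eqn{s_k} the k-th
#' sub-score and \eqn{\omega_k \ge 0} its weight. Two constraint kinds are
#' supported: binary knowledge rules (score 0 or 1) and continuous
#' data-fit rules (score varying continuously in `[0, 1]`).
#'
#' A *trajectory* throughout this package is a data frame with a time
#' column `t` (days) and one column per model output variable.
#'
#' @name scoring
NULL

#' Binary knowledge constraint
#'
#' Scores 1 when a model output satisfies a comparator against a threshold
#' at every sampled time inside a window (or at the final sample only),
#' 0 otherwise. Comparators are strict, so boundary equality scores 0.
#'
#' @param name Constraint label.
#' @param variable Trajectory column the rule applies to.
#' @param comparator One of `"greater"`, `"less"`, `"between"`.
#' @param threshold One value for `"greater"`/`"less"`; `c(lower, upper)`
#'   with `lower < upper` for `"between"`.
#' @param time_window `"final"` (last sample only) or `c(t_start, t_end)`
#'   in days.
#' @param weight Nonnegative weight of the constraint in the objective.
#' @param scenario Optional scenario label; used by multi-scenario
#'   calibration steps to route the constraint to the right simulation.
#' @return An object of classes `binary_constraint`, `constraint`.
#' @export
binary_constraint <- function(name, variable, comparator, threshold,
                              time_window = "final", weight = 1,
                              scenario = NULL) {
  comparator <- match.arg(comparator, c("greater", "less", "between"))
  stopifnot(is.numeric(threshold), all(is.finite(threshold)))
  if (comparator == "between") {
    if (length(threshold) != 2L || threshold[1L] >= threshold[2L]) {
      stop("'between' needs threshold = c(lower, upper) with lower < upper",
           call. = FALSE)
    }
  } else if (length(threshold) != 1L) {
    stop("comparator '", comparator, "' takes a single threshold",
         call. = FALSE)
  }
  if (!identical(time_window, "final")) {
    stopifnot(is.numeric(time_window), length(time_window) == 2L,
              time_window[1L] <= time_window[2L])
  }
  stopifnot(is.numeric(weight), length(weight) == 1L, weight >= 0)
  structure(
    list(name = name, variable = variable, comparator = comparator,
         threshold = threshold, time_window = time_window, weight = weight,
         scenario = scenario),
    class = c("binary_constraint", "constraint")
  )
}

#' Continuous data-fit constraint
#'
#' Scores how close a model output stays to a measured time series.
#' For each data point the model output (linearly interpolated onto the
#' data time) is compared to the measured mean in units of two standard
#' deviations: \eqn{r_t = |y(t) - m_t| / (2 s_t)}. The point score is 1
#' when the model lies within the 2-SD band (\eqn{r_t \le 1}) and decays
#' as \eqn{\exp(1 - r_t)} outside; the constraint score is the mean over
#' data points.
#'
#' Zero or missing SDs fall back to `sd_fallback_frac * |mean|`
#' (1 in absolute terms when the mean is also 0).
#'
#' @param name Constraint label.
#' @param variable Trajectory column the series refers to.
#' @param series Data frame with columns `time`, `mean`, `sd` (times in
#'   days, strictly increasing, `sd >= 0`).
#' @param weight Nonnegative weight.
#' @param sd_fallback_frac Relative SD substituted where `sd` is 0 or `NA`.
#' @param scenario Optional scenario label (see [binary_constraint()]).
#' @return An object of classes `data_constraint`, `constraint`.
#' @export
data_constraint <- function(name, variable, series, weight = 1,
                            sd_fallback_frac = 0.1, scenario = NULL) {
  series <- as.data.frame(series)
  need <- c("time", "mean", "sd")
  if (!all(need %in% names(series))) {
    stop("series must have columns time, mean, sd", call. = FALSE)
  }
  series <- series[need]
  if (nrow(series) < 1L) stop("series needs at least one point", call. = FALSE)
  if (is.unsorted(series$time, strictly = TRUE)) {
    stop("series times must be strictly increasing", call. = FALSE)
  }
  if (any(series$sd < 0, na.rm = TRUE)) stop("sd must be >= 0", call. = FALSE)
  stopifnot(is.numeric(weight), length(weight) == 1L, weight >= 0)
  structure(
    list(name = name, variable = variable, series = series, weight = weight,
         sd_fallback_frac = sd_fallback_frac, scenario = scenario),
    class = c("data_constraint", "constraint")
  )
}

#' Knowledge anchor constraint
#'
#' Encodes a printed quantitative statement ("reaches about 400 um at
#' day 20") as a continuous data constraint on a few anchor points, with
#' the 2-SD half-width set to a stated relative uncertainty. Scores 1
#' when the model passes within `rel_2sd * value` of every anchor and
#' decays smoothly outside, so it pulls an optimizer toward the stated
#' behavior where a hard binary rule would give no signal.
#'
#' @param name Constraint label.
#' @param variable Trajectory column.
#' @param times,values Anchor times (days) and target values.
#' @param rel_2sd Relative half-width of the perfect-score band.
#' @param weight Nonnegative weight.
#' @param scenario Optional scenario label.
#' @return A [data_constraint()].
#' @export
anchor_constraint <- function(name, variable, times, values,
                              rel_2sd = 0.05, weight = 1, scenario = NULL) {
  stopifnot(length(times) == length(values), rel_2sd > 0)
  data_constraint(name, variable,
                  data.frame(time = times, mean = values,
                             sd = rel_2sd * abs(values) / 2),
                  weight = weight, scenario = scenario)
}

#' Bundle constraints into an objective
#'
#' @param constraints List of [binary_constraint()] / [data_constraint()]
#'   objects. Total weight must be positive.
#' @return An object of class `objective_spec`.
#' @export
objective_spec <- function(constraints) {
  if (inherits(constraints, "constraint")) constraints <- list(constraints)
  stopifnot(length(constraints) >= 1L)
  ok <- vapply(constraints, inherits, logical(1L), "constraint")
  if (!all(ok)) stop("all elements must be constraint objects", call. = FALSE)
  w <- vapply(constraints, `[[`, numeric(1L), "weight")
  if (sum(w) <= 0) stop("total constraint weight must be positive",
                        call. = FALSE)
  nms <- vapply(constraints, `[[`, character(1L), "name")
  names(constraints) <- nms
  structure(list(constraints = constraints), class = "objective_spec")
}

# Extract a variable from a trajectory, with a clear configuration error.
traj_column <- function(trajectory, variable) {
  trajectory <- as.data.frame(trajectory)
  if (!"t" %in% names(trajectory)) {
    stop("trajectory must have a time column 't'", call. = FALSE)
  }
  if (!variable %in% names(trajectory)) {
    stop("trajectory has no output variable '", variable, "' (available: ",
         paste(setdiff(names(trajectory), "t"), collapse = ", "), ")",
         call. = FALSE)
  }
  trajectory[c("t", variable)]
}

#' Score a single constraint against a trajectory
#'
#' @param constraint A constraint object.
#' @param trajectory Trajectory data frame (`t` + output columns).
#' @return A score in `[0, 1]`; exactly 0 or 1 for binary constraints.
#' @export
score_constraint <- function(constraint, trajectory) {
  UseMethod("score_constraint")
}

#' @export
score_constraint.binary_constraint <- function(constraint, trajectory) {
  tv <- traj_column(trajectory, constraint$variable)
  if (identical(constraint$time_window, "final")) {
    y <- tv[[2L]][nrow(tv)]
  } else {
    w <- constraint$time_window
    if (w[1L] < min(tv$t) - 1e-9 || w[2L] > max(tv$t) + 1e-9) {
      stop("constraint '", constraint$name, "': time window [", w[1L], ", ",
           w[2L], "] outside the simulated horizon [", min(tv$t), ", ",
           max(tv$t), "]", call. = FALSE)
    }
    y <- tv[[2L]][tv$t >= w[1L] & tv$t <= w[2L]]
    if (length(y) == 0L) { # window between samples: interpolate its edges
      y <- stats::approx(tv$t, tv[[2L]], xout = w)$y
    }
  }
  ok <- switch(constraint$comparator,
    greater = all(y > constraint$threshold),
    less    = all(y < constraint$threshold),
    between = all(y > constraint$threshold[1L] & y < constraint$threshold[2L])
  )
  as.numeric(ok)
}

#' @export
score_constraint.data_constraint <- function(constraint, trajectory) {
  tv <- traj_column(trajectory, constraint$variable)
  s <- constraint$series
  if (max(s$time) > max(tv$t) + 1e-9 || min(s$time) < min(tv$t) - 1e-9) {
    stop("constraint '", constraint$name,
         "': data times outside the simulated horizon", call. = FALSE)
  }
  y <- stats::approx(tv$t, tv[[2L]], xout = s$time, rule = 1L)$y
  sd <- s$sd
  bad <- is.na(sd) | sd == 0
  if (any(bad)) {
    fb <- constraint$sd_fallback_frac * abs(s$mean[bad])
    fb[fb == 0] <- 1
    sd[bad] <- fb
  }
  r <- abs(y - s$mean) / (2 * sd)
  phi <- ifelse(r <= 1, 1, exp(1 - r))
  mean(phi)
}

#' Evaluate the weighted objective
#'
#' Computes \eqn{f = \sum_k \omega_k s_k / \sum_k \omega_k} over all
#' constraints in the objective. `f` lies in `[0, 1]` and equals 1 exactly
#' when every positively weighted constraint scores 1.
#'
#' @param spec An [objective_spec()].
#' @param trajectory Trajectory data frame, or a named list of trajectories
#'   when constraints carry scenario labels.
#' @param details Return per-constraint scores alongside `f`?
#' @return The objective value, or (with `details = TRUE`) a list with
#'   elements `f` and `scores`.
#' @export
objective_value <- function(spec, trajectory, details = FALSE) {
  stopifnot(inherits(spec, "objective_spec"))
  pick <- function(con) {
    if (is.data.frame(trajectory) || !is.list(trajectory)) return(trajectory)
    if (is.null(con$scenario)) return(trajectory[[1L]])
    tr <- trajectory[[con$scenario]]
    if (is.null(tr)) {
      stop("no trajectory for scenario '", con$scenario, "'", call. = FALSE)
    }
    tr
  }
  s <- vapply(spec$constraints,
              function(con) score_constraint(con, pick(con)), numeric(1L))
  w <- vapply(spec$constraints, `[[`, numeric(1L), "weight")
  f <- sum(w * s) / sum(w)
  if (details) list(f = f, scores = s, weights = w) else f
}

#' Read a measurement series from CSV
#'
#' Expects the header `time,mean,sd` with times in days.
#'
#' @param path CSV file path.
#' @return Data frame with columns `time`, `mean`, `sd`.
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time", "mean", "sd")
  if (!all(need %in% names(df))) {
    stop("'", path, "' must have header time,mean,sd", call. = FALSE)
  }
  df[need]
}

#' Load an objective from a YAML configuration
#'
#' The file holds a top-level `constraints:` list; each entry has a
#' `type` (`binary` or `data`), `name`, `variable`, `weight`, and either
#' comparator/threshold/time_window fields (binary) or a `series` file
#' path or inline table (data). Relative series paths are resolved
#' against the config file's directory.
#'
#' @param path YAML file path.
#' @return An [objective_spec()].
#' @export
read_objective_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$constraints)) {
    stop("config '", path, "' has no 'constraints' key", call. = FALSE)
  }
  base <- dirname(path)
  cons <- lapply(cfg$constraints, function(cc) {
    type <- cc$type
    if (is.null(type)) stop("constraint without 'type' in ", path,
                            call. = FALSE)
    weight <- if (is.null(cc$weight)) 1 else cc$weight
    if (type == "binary") {
      tw <- cc$time_window
      if (is.null(tw)) tw <- "final"
      if (is.list(tw)) tw <- unlist(tw)
      binary_constraint(cc$name, cc$variable, cc$comparator,
                        unlist(cc$threshold), tw, weight,
                        scenario = cc$scenario)
    } else if (type == "data") {
      series <- if (!is.null(cc$series_file)) {
        p <- cc$series_file
        if (!file.exists(p)) p <- file.path(base, cc$series_file)
        read_series_csv(p)
      } else {
        as.data.frame(lapply(cc$series, unlist))
      }
      fb <- if (is.null(cc$sd_fallback_frac)) 0.1 else cc$sd_fallback_frac
      data_constraint(cc$name, cc$variable, series, weight,
                      sd_fallback_frac = fb, scenario = cc$scenario)
    } else {
      stop("unknown constraint type '", type, "' in ", path, call. = FALSE)
    }
  })
  objective_spec(cons)
}
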