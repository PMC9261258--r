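#' Stepwise calibration engine
#'
#' A calibration plan is an ordered list of steps. Each step maximizes a
#' weighted-constraint objective over its *free* parameters with CMA-ES
#' while all previously solved parameters stay frozen, then freezes (or
#' interval-narrows) its solutions for the steps downstream. After every
#' step, the constraints of all earlier steps are re-evaluated with the
#' merged parameter set; the plan aborts if any earlier constraint score
#' falls below a configurable floor. Steps may re-free an earlier
#' parameter; the carry-over check then guards the earlier behavior.
#'
#' Steps can carry advisory ordering metadata (`priority_notes`) — e.g.
#' "well-documented first, lowest granularity first, least connected
#' first" — which is reported but not enforced.
#'
#' @name stepwise
NULL

#' Define one calibration step
#'
#' @param name Step label.
#' @param scenarios Named list of [growth_scenario()] objects simulated at
#'   every objective evaluation. Constraints reference them through their
#'   `scenario` field (constraints with `scenario = NULL` use the first).
#' @param free Character vector of parameter names searched in this step.
#' @param constraints An [objective_spec()] for this step's objective.
#' @param carryover Optional [objective_spec()] re-verified after later
#'   steps (defaults to `constraints`). Plans typically carry over the
#'   measured-data and knowledge rules but not tight optimizer-guidance
#'   anchors.
#' @param stop_threshold,max_generations,stagnation_window,stagnation_tol
#'   Optimizer settings for this step (see [search_spec()]).
#' @param n_restarts Independent CMA-ES runs (distinct derived seeds); the
#'   best result is kept. Restarts after the first start from the
#'   incumbent best with a tightened spread (polish runs).
#' @param init_sd_frac Optional initial search standard deviation for the
#'   first run, as a fraction of each parameter's interval width;
#'   `NULL` keeps the default rule (half the interval width). Steps
#'   whose initial guesses are informative typically set a small
#'   fraction so the search refines rather than re-explores.
#' @param prescreen Optional named integer vector of factorial levels
#'   for a subset of the free parameters. Before the CMA-ES runs, the
#'   step objective is evaluated on the full factorial grid over those
#'   parameters (others held at their initial guesses) and the best row
#'   replaces the initial guesses — a deterministic coarse screen that
#'   places the optimizer in the right basin of a multimodal landscape.
#' @param narrow One of `"freeze"` (pin solved parameters) or
#'   `"interval"` (shrink their bounds around the solution) applied to
#'   this step's free parameters for downstream steps.
#' @param priority_notes Optional advisory text on why the step is
#'   ordered where it is.
#' @return An object of class `calibration_step`.
#' @export
calibration_step <- function(name, scenarios, free, constraints,
                             carryover = NULL,
                             stop_threshold = 0.999,
                             max_generations = 150L,
                             stagnation_window = 30L,
                             stagnation_tol = 1e-6,
                             n_restarts = 1L,
                             init_sd_frac = NULL,
                             prescreen = NULL,
                             narrow = c("freeze", "interval"),
                             priority_notes = NULL) {
  if (inherits(scenarios, "growth_scenario")) scenarios <- list(scenarios)
  if (is.null(names(scenarios)) || any(!nzchar(names(scenarios)))) {
    names(scenarios) <- paste0("scenario", seq_along(scenarios))
  }
  stopifnot(all(vapply(scenarios, inherits, logical(1L), "growth_scenario")),
            inherits(constraints, "objective_spec"),
            is.character(free), length(free) >= 1L)
  if (is.null(carryover)) carryover <- constraints
  stopifnot(inherits(carryover, "objective_spec"))
  structure(
    list(name = name, scenarios = scenarios, free = free,
         constraints = constraints, carryover = carryover,
         stop_threshold = stop_threshold,
         max_generations = as.integer(max_generations),
         stagnation_window = as.integer(stagnation_window),
         stagnation_tol = stagnation_tol,
         n_restarts = as.integer(n_restarts),
         init_sd_frac = init_sd_frac, prescreen = prescreen,
         narrow = match.arg(narrow), priority_notes = priority_notes),
    class = "calibration_step"
  )
}

# Simulate all scenarios of a step for a full parameter vector theta.
# "gef_conc_nM" is routed into each dosed scenario's exposure; everything
# else overrides growth parameters. Invalid parameter regions (e.g.
# L_p > L_v) yield NULL, which the objective scores 0.
simulate_step_scenarios <- function(step, base_params, theta) {
  conc <- if ("gef_conc_nM" %in% names(theta)) theta[["gef_conc_nM"]] else NULL
  theta <- theta[setdiff(names(theta), "gef_conc_nM")]
  params <- tryCatch(set_growth_params(base_params, theta),
                     error = function(e) NULL)
  if (is.null(params)) return(NULL)
  out <- vector("list", length(step$scenarios))
  names(out) <- names(step$scenarios)
  y0_cache <- list() # arms sharing genotype/size share the burn-in state
  for (nm in names(step$scenarios)) {
    sc <- step$scenarios[[nm]]
    if (!is.null(sc$dosing) && !is.null(conc)) sc$dosing$conc_nM <- conc
    y0 <- NULL
    if (sc$init == "equilibrated") {
      key <- paste(sc$mode, sc$n0, sc$body_mass_g,
                   sc$mutations$kras, sc$mutations$egfr_ex19del,
                   sc$mutations$pik3ca, sep = "|")
      if (is.null(y0_cache[[key]])) {
        y0_cache[[key]] <- tryCatch(equilibrated_state(params, sc),
                                    error = function(e) NULL)
        if (is.null(y0_cache[[key]])) return(NULL)
      }
      y0 <- y0_cache[[key]]
    }
    tr <- tryCatch(simulate_growth(params, sc, y0 = y0),
                   error = function(e) NULL)
    if (is.null(tr)) return(NULL)
    out[[nm]] <- tr
  }
  out
}

step_objective_fn <- function(step, base_params) {
  function(theta) {
    trajs <- simulate_step_scenarios(step, base_params, theta)
    if (is.null(trajs)) return(0)
    objective_value(step$constraints, trajs)
  }
}

#' Re-verify earlier constraints under a merged parameter set
#'
#' Re-simulates the scenarios of already-completed steps with the merged
#' parameters and scores every constraint again.
#'
#' @param merged Named vector of the full merged parameter set.
#' @param earlier_steps List of completed [calibration_step()]s.
#' @param base_params Baseline [growth_params()].
#' @param floor Pass/fail score floor.
#' @return Data frame: step, constraint, score, pass.
#' @export
verify_carryover <- function(merged, earlier_steps, base_params,
                             floor = 0.8) {
  rows <- list()
  for (st in earlier_steps) {
    trajs <- simulate_step_scenarios(st, base_params, merged)
    if (is.null(trajs)) {
      stop("carry-over re-simulation failed for step '", st$name, "'",
           call. = FALSE)
    }
    cons <- if (is.null(st$carryover)) st$constraints else st$carryover
    for (con in cons$constraints) {
      tr <- if (is.null(con$scenario)) trajs[[1L]] else trajs[[con$scenario]]
      s <- score_constraint(con, tr)
      rows[[length(rows) + 1L]] <- data.frame(
        step = st$name, constraint = con$name, score = s, pass = s >= floor
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(step = character(), constraint = character(),
                      score = numeric(), pass = logical()))
  }
  do.call(rbind, rows)
}

#' Narrow parameter ranges after a completed step
#'
#' `"freeze"` pins each solved parameter at its best value (a degenerate
#' interval, auto-frozen downstream). `"interval"` shrinks the bounds to
#' `best +- k * final_search_sd`, intersected with the original bounds;
#' a zero final spread degenerates to a freeze.
#'
#' @param result The step's `cma_result`.
#' @param specs Named list of [parameter_spec()]s (the step's search
#'   space).
#' @param strategy `"freeze"` or `"interval"`.
#' @param k Half-width multiplier for `"interval"`.
#' @return The updated named list of `parameter_spec`s.
#' @export
narrow_ranges <- function(result, specs, strategy = c("freeze", "interval"),
                          k = 3) {
  strategy <- match.arg(strategy)
  for (nm in names(specs)) {
    if (!nm %in% names(result$best_par)) next
    p <- specs[[nm]]
    best <- unname(result$best_par[[nm]])
    if (strategy == "freeze") {
      lo <- hi <- best
    } else {
      sd_nat <- result$final_sd[[nm]]
      if (is.null(sd_nat) || is.na(sd_nat)) { # log-scale: widen in log space
        sd_int <- result$final_sd_internal[[nm]]
        span <- log(p$upper) - log(p$lower)
        lo <- max(p$lower, exp(log(best) - k * sd_int * span))
        hi <- min(p$upper, exp(log(best) + k * sd_int * span))
      } else {
        lo <- max(p$lower, best - k * sd_nat)
        hi <- min(p$upper, best + k * sd_nat)
      }
      if (hi <= lo) lo <- hi <- best
    }
    specs[[nm]] <- parameter_spec(nm, lo, hi,
                                  init = if (hi > lo) best else NULL,
                                  unit = p$unit, log_scale = p$log_scale,
                                  allometric = p$allometric)
  }
  specs
}

#' Run a calibration plan
#'
#' Executes the steps in order. For each step a [search_spec()] is built
#' from the step's free parameters (errors if a name is unknown), the
#' objective is maximized (best of `n_restarts` CMA-ES runs on derived
#' seeds), solutions are frozen for downstream steps, and all earlier
#' constraints are re-verified with the merged parameter set. The plan
#' aborts with a diagnostic if a carry-over score drops below
#' `carryover_floor`; a step that exhausts its generation budget below
#' its threshold is flagged unconverged with a warning and the plan
#' continues.
#'
#' @param steps List of [calibration_step()]s, in order.
#' @param parameter_specs Named list of [parameter_spec()]s covering every
#'   parameter any step frees.
#' @param base_params Baseline [growth_params()]; frozen parameters not
#'   yet solved keep their baseline values.
#' @param seed Master integer seed; per-step, per-restart seeds are
#'   derived deterministically from it.
#' @param carryover_floor Abort floor for re-verified earlier constraints.
#' @return A `plan_result`: per-step results, merged parameter vector,
#'   carry-over report, per-step convergence flags, seed.
#' @export
run_plan <- function(steps, parameter_specs, base_params, seed = 1L,
                     carryover_floor = 0.8) {
  stopifnot(length(steps) >= 1L,
            all(vapply(steps, inherits, logical(1L), "calibration_step")))
  known <- c(names(base_params), "gef_conc_nM")
  solved <- numeric(0L)
  specs <- parameter_specs
  step_reports <- vector("list", length(steps))
  names(step_reports) <- vapply(steps, `[[`, character(1L), "name")
  carry <- NULL
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    missing_specs <- setdiff(st$free, names(specs))
    if (length(missing_specs)) {
      stop("step '", st$name, "' frees unknown parameters: ",
           paste(missing_specs, collapse = ", "), call. = FALSE)
    }
    if (length(setdiff(st$free, known))) {
      stop("step '", st$name, "' references parameters the model ",
           "does not have: ",
           paste(setdiff(st$free, known), collapse = ", "), call. = FALSE)
    }
    # freeze previously solved parameters not re-freed here
    base_i <- base_params
    frozen_now <- solved[setdiff(names(solved), st$free)]
    if (length(frozen_now)) {
      base_i <- set_growth_params(
        base_i, frozen_now[setdiff(names(frozen_now), "gef_conc_nM")])
    }
    obj_fn <- step_objective_fn(st, base_i)
    if ("gef_conc_nM" %in% names(frozen_now)) {
      conc_frozen <- frozen_now[["gef_conc_nM"]]
      inner <- obj_fn
      obj_fn <- function(theta) inner(c(theta, gef_conc_nM = conc_frozen))
    }
    # a step that re-frees an already-solved parameter searches it over
    # its ORIGINAL bounds again (starting from the solved value); only
    # parameters never freed by the step stay frozen
    specs_step <- specs[st$free]
    for (nm in st$free) {
      p <- specs_step[[nm]]
      if (p$upper <= p$lower && nm %in% names(solved)) {
        p0 <- parameter_specs[[nm]]
        b <- min(max(unname(solved[[nm]]), p0$lower), p0$upper)
        specs_step[[nm]] <- parameter_spec(nm, p0$lower, p0$upper,
                                           init = b, unit = p0$unit,
                                           log_scale = p0$log_scale,
                                           allometric = p0$allometric)
      }
    }
    # deterministic factorial prescreen: seed the search in the best
    # coarse-grid basin
    if (!is.null(st$prescreen)) {
      sn <- intersect(names(st$prescreen), st$free)
      sn <- sn[vapply(specs_step[sn], function(p) p$upper > p$lower,
                      logical(1L))]
      if (length(sn)) {
        des <- factorial_design(specs_step[sn], levels = st$prescreen[sn])
        others <- setdiff(st$free, sn)
        base_theta <- vapply(specs_step[others], `[[`, numeric(1L), "init")
        names(base_theta) <- others
        best_v <- -Inf
        best_row <- NULL
        for (ri in seq_len(nrow(des$design))) {
          row <- unlist(des$design[ri, , drop = FALSE])
          v <- obj_fn(c(row, base_theta))
          if (v > best_v) { best_v <- v; best_row <- row }
        }
        for (nm in names(best_row)) {
          p <- specs_step[[nm]]
          b <- min(max(unname(best_row[[nm]]), p$lower), p$upper)
          specs_step[[nm]] <- parameter_spec(nm, p$lower, p$upper,
                                             init = b,
                                             unit = p$unit,
                                             log_scale = p$log_scale,
                                             allometric = p$allometric)
        }
      }
    }
    best <- NULL
    for (r in seq_len(st$n_restarts)) {
      specs_r <- specs_step
      polish <- r > 1L && r == st$n_restarts && !is.null(best)
      if (r == 1L && !is.null(st$init_sd_frac)) {
        for (nm in names(specs_r)) {
          p <- specs_r[[nm]]
          if (p$upper <= p$lower) next
          sd_nat <- if (p$log_scale) {
            p$init * st$init_sd_frac * (log(p$upper) - log(p$lower))
          } else {
            st$init_sd_frac * (p$upper - p$lower)
          }
          specs_r[[nm]] <- parameter_spec(nm, p$lower, p$upper,
                                          init = p$init, unit = p$unit,
                                          log_scale = p$log_scale,
                                          allometric = p$allometric,
                                          init_sd = sd_nat)
        }
      }
      if (polish) {
        # the final restart polishes the incumbent: start from its best
        # point with a tight initial spread
        for (nm in names(specs_r)) {
          p <- specs_r[[nm]]
          if (p$upper <= p$lower) next
          b <- min(max(unname(best$best_par[[nm]]), p$lower), p$upper)
          sd_nat <- if (p$log_scale) {
            b * 0.1 * (log(p$upper) - log(p$lower))
          } else {
            0.1 * (p$upper - p$lower)
          }
          specs_r[[nm]] <- parameter_spec(nm, p$lower, p$upper, init = b,
                                          unit = p$unit,
                                          log_scale = p$log_scale,
                                          allometric = p$allometric,
                                          init_sd = sd_nat)
        }
      }
      sspec <- search_spec(
        specs_r,
        stop_threshold = st$stop_threshold,
        stagnation_window = st$stagnation_window,
        stagnation_tol = st$stagnation_tol,
        max_generations = st$max_generations,
        seed = (seed * 97L + i * 1009L + r * 7919L) %% 2147483647L
      )
      res <- cma_maximize(obj_fn, sspec)
      if (is.null(best) || res$best_value > best$best_value) best <- res
      if (best$best_value >= st$stop_threshold) break
    }
    converged <- best$best_value >= st$stop_threshold ||
      best$stop_reason != "budget"
    if (!converged) {
      warning("step '", st$name, "' unconverged: best objective ",
              signif(best$best_value, 4), " after budget; plan continues",
              call. = FALSE)
    }
    solved_step <- best$best_par[st$free]
    solved[names(solved_step)] <- solved_step
    specs[st$free] <- specs_step
    specs <- narrow_ranges(best, specs, st$narrow)
    step_reports[[i]] <- list(name = st$name, result = best,
                              objective = best$best_value,
                              converged = converged,
                              solved = solved_step)
    # carry-over verification against all earlier steps
    if (i > 1L) {
      carry <- verify_carryover(solved, steps[seq_len(i - 1L)],
                                base_params, floor = carryover_floor)
      if (nrow(carry) && any(!carry$pass)) {
        bad <- carry[!carry$pass, , drop = FALSE]
        stop("carry-over violation after step '", st$name, "': ",
             paste(sprintf("%s/%s=%.3f", bad$step, bad$constraint,
                           bad$score), collapse = ", "),
             " below floor ", carryover_floor, call. = FALSE)
      }
    }
  }
  structure(
    list(steps = step_reports, merged = solved,
         params = set_growth_params(
           base_params, solved[setdiff(names(solved), "gef_conc_nM")]),
         carryover = carry, seed = seed,
         carryover_floor = carryover_floor),
    class = "plan_result"
  )
}

#' @export
print.plan_result <- function(x, ...) {
  cat("<plan_result>\n")
  for (st in x$steps) {
    cat(sprintf("  step '%s': objective %.4f (%s)\n", st$name,
                st$objective,
                if (st$converged) "converged" else "unconverged"))
  }
  if (!is.null(x$carryover) && nrow(x$carryover)) {
    cat(sprintf("  carry-over: %d/%d constraints >= floor %.2f\n",
                sum(x$carryover$pass), nrow(x$carryover),
                x$carryover_floor))
  }
  invisible(x)
}
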