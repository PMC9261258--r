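#' CMA-ES maximizer
#'
#' A self-contained (mu/mu_w, lambda) Covariance Matrix Adaptation
#' Evolution Strategy in the standard Hansen formulation: logarithmic
#' recombination weights over the best mu = floor(p/2) candidates,
#' cumulative step-size adaptation (CSA), and a rank-one plus rank-mu
#' covariance update, with all learning rates the usual functions of the
#' dimension d and the variance-effective selection mass mu_eff.
#'
#' The optimizer *maximizes* an objective mapping a named parameter vector
#' to `[0, 1]`. Internally it works in normalized coordinates: every
#' parameter is mapped onto `[0, 1]` (logarithmically when its spec sets
#' `log_scale`), which keeps the covariance well conditioned when
#' parameters span different units and orders of magnitude.
#'
#' @name cmaes
NULL

#' Default population size
#'
#' The rule `p = 4 + floor(3 * log(d))` (natural logarithm) for the number
#' of candidates sampled per generation in dimension `d`.
#'
#' @param d Number of free parameters, `d >= 1`.
#' @return Integer population size.
#' @examples
#' default_population_size(1)  # 4
#' default_population_size(14) # 11
#' @export
default_population_size <- function(d) {
  if (!is.numeric(d) || length(d) != 1L || d < 1) {
    stop("d must be a positive integer", call. = FALSE)
  }
  as.integer(4L + floor(3 * log(d)))
}

# --- coordinate transforms (natural <-> internal [0,1]) ---------------------

par_to_internal <- function(p, x) {
  if (p$log_scale) {
    (log(x) - log(p$lower)) / (log(p$upper) - log(p$lower))
  } else {
    (x - p$lower) / (p$upper - p$lower)
  }
}

par_to_natural <- function(p, z) {
  if (p$log_scale) {
    exp(log(p$lower) + z * (log(p$upper) - log(p$lower)))
  } else {
    p$lower + z * (p$upper - p$lower)
  }
}

internal_init_sd <- function(p) {
  if (is.null(p$init_sd)) return(0.5) # half the unit-interval width
  if (p$log_scale) {
    # delta-method conversion of a natural-units sd at the initial guess
    p$init_sd / (p$init * (log(p$upper) - log(p$lower)))
  } else {
    p$init_sd / (p$upper - p$lower)
  }
}

# Strategy constants for dimension d and population size lambda.
cma_weights <- function(d, lambda) {
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mu_eff <- 1 / sum(w^2)
  c_sigma <- (mu_eff + 2) / (d + mu_eff + 5)
  d_sigma <- 1 + 2 * max(0, sqrt((mu_eff - 1) / (d + 1)) - 1) + c_sigma
  c_c <- (4 + mu_eff / d) / (d + 4 + 2 * mu_eff / d)
  c_1 <- 2 / ((d + 1.3)^2 + mu_eff)
  c_mu <- min(1 - c_1, 2 * (mu_eff - 2 + 1 / mu_eff) / ((d + 2)^2 + mu_eff))
  chi_n <- sqrt(d) * (1 - 1 / (4 * d) + 1 / (21 * d^2))
  list(mu = mu, w = w, mu_eff = mu_eff, c_sigma = c_sigma, d_sigma = d_sigma,
       c_c = c_c, c_1 = c_1, c_mu = c_mu, chi_n = chi_n)
}

#' Initialize CMA-ES state
#'
#' The distribution mean starts at the initial guesses; the covariance is
#' diagonal with each standard deviation equal to half of the parameter's
#' search-interval width (or the spec's `init_sd` override), expressed in
#' internal normalized coordinates; the global step size starts at 1 and
#' both evolution paths at zero. Parameters with degenerate intervals are
#' auto-frozen and excluded from the search dimension.
#'
#' @param spec A [search_spec()].
#' @return A `cma_state` list (mean, C, sigma, paths, generation,
#'   best-so-far).
#' @export
cma_init <- function(spec) {
  stopifnot(inherits(spec, "search_spec"))
  free <- free_parameter_names(spec)
  if (length(free) == 0L) {
    stop("all parameters are frozen; nothing to optimize", call. = FALSE)
  }
  pars <- spec$parameters[free]
  d <- length(pars)
  mean_z <- vapply(pars, function(p) par_to_internal(p, p$init), numeric(1L))
  sds <- vapply(pars, internal_init_sd, numeric(1L))
  structure(
    list(mean = mean_z, C = diag(sds^2, d), sigma = 1,
         p_sigma = numeric(d), p_c = numeric(d),
         generation = 0L, best_par = NULL, best_value = -Inf,
         free = free, d = d),
    class = "cma_state"
  )
}

# Eigendecompose C, flooring eigenvalues for numerical safety.
cma_eigen <- function(C) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  if (any(e$values < 1e-12)) {
    warning("covariance repaired: eigenvalues floored at 1e-12",
            call. = FALSE)
    e$values <- pmax(e$values, 1e-12)
  }
  e
}

#' Sample one generation of candidates
#'
#' Draws `n` candidates from `Normal(mean, sigma^2 C)` in internal
#' coordinates. Out-of-bounds draws are resampled up to 100 times, then
#' clipped to the boundary. Uses (and advances) R's global RNG stream, so
#' runs are reproducible under a fixed seed.
#'
#' @param state A `cma_state`.
#' @param n Number of candidates.
#' @return A `d x n` matrix of internal coordinates in `[0, 1]`.
#' @export
cma_sample <- function(state, n) {
  d <- state$d
  e <- cma_eigen(state$C)
  A <- e$vectors %*% (sqrt(e$values) * t(e$vectors)) # C^{1/2}
  Z <- matrix(NA_real_, d, n)
  for (i in seq_len(n)) {
    for (k in seq_len(100L)) {
      zi <- state$mean + state$sigma * as.numeric(A %*% stats::rnorm(d))
      if (all(zi >= 0 & zi <= 1)) break
    }
    Z[, i] <- pmin(pmax(zi, 0), 1)
  }
  rownames(Z) <- state$free
  Z
}

#' One CMA-ES update from an evaluated generation
#'
#' Selects the best `mu = floor(p/2)` candidates (descending objective,
#' ties broken by candidate index), recombines them with logarithmic
#' weights into the new mean, updates the evolution paths, applies the
#' rank-one plus rank-mu covariance update and the CSA step-size rule,
#' and tracks the best candidate seen so far. Non-finite objective values
#' are treated as 0 (the worst possible score) with a warning.
#'
#' @param state A `cma_state`.
#' @param Z `d x p` matrix of internal candidates from [cma_sample()].
#' @param values Objective value per candidate (maximized).
#' @param natural Optional named list/matrix of natural-coordinate
#'   candidates used to record `best_par`.
#' @return The updated `cma_state`.
#' @export
cma_update <- function(state, Z, values, natural = NULL) {
  d <- state$d
  p <- ncol(Z)
  stopifnot(length(values) == p)
  if (any(!is.finite(values))) {
    warning("non-finite objective values treated as 0", call. = FALSE)
    values[!is.finite(values)] <- 0
  }
  k <- cma_weights(d, p)
  ord <- order(values, seq_len(p), decreasing = c(TRUE, FALSE),
               method = "radix")
  sel <- ord[seq_len(k$mu)]

  mean_old <- state$mean
  Y <- (Z[, sel, drop = FALSE] - mean_old) / state$sigma # selected steps
  y_w <- as.numeric(Y %*% k$w)
  mean_new <- mean_old + state$sigma * y_w

  e <- cma_eigen(state$C)
  C_inv_sqrt <- e$vectors %*% ((1 / sqrt(e$values)) * t(e$vectors))
  p_sigma <- (1 - k$c_sigma) * state$p_sigma +
    sqrt(k$c_sigma * (2 - k$c_sigma) * k$mu_eff) *
    as.numeric(C_inv_sqrt %*% y_w)
  gen <- state$generation + 1L
  h_sigma <- as.numeric(
    sqrt(sum(p_sigma^2)) / sqrt(1 - (1 - k$c_sigma)^(2 * gen)) <
      (1.4 + 2 / (d + 1)) * k$chi_n
  )
  p_c <- (1 - k$c_c) * state$p_c +
    h_sigma * sqrt(k$c_c * (2 - k$c_c) * k$mu_eff) * y_w

  rank_mu <- Y %*% (k$w * t(Y))
  delta_h <- (1 - h_sigma) * k$c_c * (2 - k$c_c)
  C_new <- (1 - k$c_1 - k$c_mu) * state$C +
    k$c_1 * (tcrossprod(p_c) + delta_h * state$C) +
    k$c_mu * rank_mu
  sigma_new <- state$sigma *
    exp((k$c_sigma / k$d_sigma) * (sqrt(sum(p_sigma^2)) / k$chi_n - 1))

  best_i <- ord[1L]
  if (values[best_i] > state$best_value) {
    state$best_value <- values[best_i]
    state$best_par <- if (!is.null(natural)) natural[, best_i] else Z[, best_i]
  }
  state$mean <- mean_new
  state$C <- C_new
  state$sigma <- sigma_new
  state$p_sigma <- p_sigma
  state$p_c <- p_c
  state$generation <- gen
  state
}

#' Stopping decision
#'
#' Stops with reason `"threshold"` once the best objective reaches the
#' spec's `stop_threshold`, with `"stagnation"` when the per-generation
#' best has improved by less than `stagnation_tol` over the last
#' `stagnation_window` generations, and with `"budget"` at
#' `max_generations`; otherwise `NULL` (continue).
#'
#' @param state A `cma_state`.
#' @param history Numeric vector of per-generation best objective values.
#' @param spec The [search_spec()].
#' @return A reason string, or `NULL` to continue.
#' @export
cma_should_stop <- function(state, history, spec) {
  if (state$best_value >= spec$stop_threshold) return("threshold")
  w <- spec$stagnation_window
  if (length(history) >= w + 1L) {
    recent <- utils::tail(history, w + 1L)
    if (max(recent) - recent[1L] < spec$stagnation_tol) return("stagnation")
  }
  if (state$generation >= spec$max_generations) return("budget")
  NULL
}

#' Maximize an objective with CMA-ES
#'
#' Runs the full sample / evaluate / update / stop loop. The objective
#' receives a *named* vector in natural units (auto-frozen parameters
#' included at their pinned values); an error or non-finite value on a
#' candidate scores it 0 and the run continues. The whole run is
#' reproducible under the spec's seed.
#'
#' @param objective_fn `function(named numeric vector) -> value in [0, 1]`.
#' @param spec A [search_spec()].
#' @return A `cma_result` list: `best_par` (named, natural units),
#'   `best_value`, `history` data frame (generation, best, worst, mean,
#'   best_so_far), `stop_reason`, `seed`, final `state`.
#' @export
cma_maximize <- function(objective_fn, spec) {
  stopifnot(is.function(objective_fn), inherits(spec, "search_spec"))
  set.seed(spec$seed)
  state <- cma_init(spec)
  pars <- spec$parameters[state$free]
  frozen <- frozen_parameter_values(spec)
  lambda <- if (identical(spec$population_size, "auto")) {
    default_population_size(state$d)
  } else {
    spec$population_size
  }
  hist_rows <- vector("list", spec$max_generations)
  gen_best <- numeric(0L)
  stop_reason <- "budget"
  repeat {
    Z <- cma_sample(state, lambda)
    natural <- vapply(seq_len(lambda), function(i) {
      vapply(state$free, function(nm) par_to_natural(pars[[nm]], Z[nm, i]),
             numeric(1L))
    }, numeric(state$d))
    natural <- matrix(natural, nrow = state$d, ncol = lambda,
                      dimnames = list(state$free, NULL))
    values <- vapply(seq_len(lambda), function(i) {
      theta <- c(natural[, i], frozen)
      v <- tryCatch(objective_fn(theta), error = function(e) {
        warning("objective failed on a candidate (scored 0): ",
                conditionMessage(e), call. = FALSE)
        0
      })
      if (!is.finite(v)) 0 else v
    }, numeric(1L))
    state <- cma_update(state, Z, values, natural)
    gen_best <- c(gen_best, max(values))
    hist_rows[[state$generation]] <- data.frame(
      generation = state$generation, best = max(values), worst = min(values),
      mean = mean(values), best_so_far = state$best_value
    )
    reason <- cma_should_stop(state, gen_best, spec)
    if (!is.null(reason)) { stop_reason <- reason; break }
  }
  history <- do.call(rbind, hist_rows[!vapply(hist_rows, is.null, logical(1L))])
  # report the search's final spread in natural units (for interval
  # narrowing downstream)
  sd_internal <- state$sigma * sqrt(pmax(diag(state$C), 0))
  widths <- vapply(pars, function(p) {
    if (p$log_scale) NA_real_ else p$upper - p$lower
  }, numeric(1L))
  final_sd <- sd_internal * widths
  names(final_sd) <- state$free
  structure(
    list(best_par = c(state$best_par, frozen),
         best_value = state$best_value, history = history,
         stop_reason = stop_reason, seed = spec$seed,
         final_sd = final_sd, final_sd_internal = sd_internal,
         state = state),
    class = "cma_result"
  )
}

#' @export
print.cma_result <- function(x, ...) {
  cat(sprintf("<cma_result> best %.6f after %d generations (stop: %s)\n",
              x$best_value, x$state$generation, x$stop_reason))
  cat("  best parameters:\n")
  print(round(x$best_par, 6))
  invisible(x)
}

#' Write a run history CSV
#'
#' Columns: generation, best, worst, mean objective per generation and the
#' running best-so-far.
#'
#' @param result A `cma_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(result, path) {
  utils::write.csv(result$history, path, row.names = FALSE)
  invisible(path)
}
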