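#' Define a calibratable parameter
#'
#' A `parameter_spec` describes one unknown of a calibration problem: its
#' search interval, initial guess, physical unit (used to derive the
#' allometric exponent when `allometric = TRUE`), and whether the search
#' should run on a log scale.
#'
#' @param name Parameter name (unique within a search).
#' @param lower,upper Search bounds in natural units; `lower < upper`.
#'   Equal bounds declare a frozen parameter, which is excluded from the
#'   search dimension.
#' @param init Initial guess; must lie in `[lower, upper]`. Defaults to the
#'   interval midpoint (geometric midpoint when `log_scale = TRUE`).
#' @param unit Physical-dimension descriptor, e.g. `"1/day"`,
#'   `"dimensionless"`, `"um"`. See [allometric_exponent()] for the units
#'   recognised by the allometric machinery.
#' @param log_scale Search on a logarithmic scale? Requires `lower > 0`.
#' @param allometric Should the parameter be rescaled with body mass by the
#'   allometric power law before simulation?
#' @param init_sd Optional initial search standard deviation in natural
#'   units. When `NULL`, the standard deviation defaults to half of the
#'   search interval width.
#' @return An object of class `parameter_spec`.
#' @export
parameter_spec <- function(name, lower, upper, init = NULL,
                           unit = "dimensionless", log_scale = FALSE,
                           allometric = FALSE, init_sd = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.numeric(lower), is.numeric(upper), length(lower) == 1L,
            length(upper) == 1L, is.finite(lower), is.finite(upper))
  if (lower > upper) {
    stop("parameter '", name, "': lower bound exceeds upper bound",
         call. = FALSE)
  }
  if (log_scale && lower <= 0) {
    stop("parameter '", name, "': log_scale requires strictly positive bounds",
         call. = FALSE)
  }
  if (is.null(init)) {
    init <- if (log_scale) sqrt(lower * upper) else (lower + upper) / 2
  }
  if (init < lower || init > upper) {
    stop("parameter '", name, "': initial guess ", init,
         " outside [", lower, ", ", upper, "]", call. = FALSE)
  }
  if (!is.null(init_sd) && (!is.numeric(init_sd) || init_sd <= 0)) {
    stop("parameter '", name, "': init_sd must be a positive number",
         call. = FALSE)
  }
  structure(
    list(name = name, lower = lower, upper = upper, init = init,
         unit = unit, log_scale = isTRUE(log_scale),
         allometric = isTRUE(allometric), init_sd = init_sd),
    class = "parameter_spec"
  )
}

#' @export
print.parameter_spec <- function(x, ...) {
  cat(sprintf("<parameter_spec> %s [%g, %g] init %g (%s)%s%s\n",
              x$name, x$lower, x$upper, x$init, x$unit,
              if (x$log_scale) " log" else "",
              if (x$allometric) " allometric" else ""))
  invisible(x)
}

#' Define a CMA-ES search
#'
#' Bundles the parameter list with the optimizer's hyper-parameters.
#' Parameters with degenerate intervals (`lower == upper`) are automatically
#' frozen at their bound and excluded from the search dimension `d`.
#'
#' @param parameters List of [parameter_spec()] objects.
#' @param population_size Number of candidates per generation, or `"auto"`
#'   for the default rule `4 + floor(3 * log(d))` (see
#'   [default_population_size()]).
#' @param stop_threshold Stop as soon as the best objective reaches this
#'   value (in `(0, 1]`).
#' @param stagnation_window,stagnation_tol Stop when the per-generation best
#'   objective improves by less than `stagnation_tol` over the last
#'   `stagnation_window` generations.
#' @param max_generations Hard budget on generations.
#' @param seed Integer seed controlling all sampling; a fixed seed makes the
#'   whole run reproducible.
#' @return An object of class `search_spec`.
#' @export
search_spec <- function(parameters, population_size = "auto",
                        stop_threshold = 0.999, stagnation_window = 30L,
                        stagnation_tol = 1e-6, max_generations = 500L,
                        seed = 1L) {
  if (inherits(parameters, "parameter_spec")) parameters <- list(parameters)
  stopifnot(length(parameters) >= 1L)
  ok <- vapply(parameters, inherits, logical(1L), "parameter_spec")
  if (!all(ok)) stop("all parameters must be parameter_spec objects",
                     call. = FALSE)
  nms <- vapply(parameters, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) stop("duplicate parameter names: ",
                               paste(nms[duplicated(nms)], collapse = ", "),
                               call. = FALSE)
  names(parameters) <- nms
  if (!identical(population_size, "auto")) {
    stopifnot(is.numeric(population_size), population_size >= 2)
    population_size <- as.integer(population_size)
  }
  stopifnot(stop_threshold > 0, stop_threshold <= 1,
            stagnation_window >= 1, stagnation_tol > 0, max_generations >= 1)
  structure(
    list(parameters = parameters, population_size = population_size,
         stop_threshold = stop_threshold,
         stagnation_window = as.integer(stagnation_window),
         stagnation_tol = stagnation_tol,
         max_generations = as.integer(max_generations),
         seed = as.integer(seed)),
    class = "search_spec"
  )
}

# Names of the searchable (non-degenerate) parameters.
free_parameter_names <- function(spec) {
  free <- vapply(spec$parameters, function(p) p$upper > p$lower, logical(1L))
  names(spec$parameters)[free]
}

# Values of the auto-frozen (degenerate-interval) parameters.
frozen_parameter_values <- function(spec) {
  frozen <- vapply(spec$parameters, function(p) p$upper <= p$lower, logical(1L))
  vapply(spec$parameters[frozen], `[[`, numeric(1L), "lower")
}
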