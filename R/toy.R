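#' Toy calibration problem
#'
#' A two-dimensional illustration of heterogeneous-constraint scoring: a
#' continuous score built from the (negated) six-hump-camel benchmark,
#' rescaled into `[0, 1]`, combined with equal weight with a binary
#' half-plane rule. The combined objective has a single global maximum of
#' 1 at `(0.0898, -0.7126)` — the camel optimum that satisfies the binary
#' rule — while the mirrored camel optimum `(-0.0898, 0.7126)` violates
#' the rule and only reaches 0.5.
#'
#' @name toy
NULL

# magnitude of the six-hump-camel global optimum, used for rescaling
CAMEL_MAX <- 1.0316

#' Negated six-hump-camel function
#'
#' `-[(4 - 2.1 x1^2 + x1^4/3) x1^2 + x1 x2 + (-4 + 4 x2^2) x2^2]`, whose
#' two global maxima of about 1.0316 sit at `(+-0.0898, -+0.7126)`, with
#' four further local maxima.
#'
#' @param x1,x2 Coordinates (vectorized).
#' @return The raw (unscaled) camel score.
#' @export
camel_raw <- function(x1, x2) {
  -((4 - 2.1 * x1^2 + x1^4 / 3) * x1^2 + x1 * x2 + (-4 + 4 * x2^2) * x2^2)
}

#' Rescale a raw camel value into \[0, 1\]
#'
#' Divides by the known optimum magnitude (1.0316) and clips to `[0, 1]`,
#' so the global maxima map to exactly 1 and the argmax is preserved.
#'
#' @param v Raw value(s).
#' @return Value(s) in `[0, 1]`.
#' @export
rescale_u <- function(v) {
  pmin(pmax(v / CAMEL_MAX, 0), 1)
}

#' Binary half-plane score
#'
#' 1 when `x2 <= x1` (boundary included), 0 otherwise.
#'
#' @param x1,x2 Coordinates (vectorized).
#' @return 0/1 score(s).
#' @export
halfplane_h <- function(x1, x2) {
  as.numeric(x2 <= x1)
}

#' Combined toy objective
#'
#' Equal-weight combination `f = (g + h) / 2` of the rescaled continuous
#' camel score `g` and the binary half-plane score `h`; values in `[0, 1]`.
#'
#' @param x1,x2 Coordinates (vectorized).
#' @return Objective value(s).
#' @export
toy_objective <- function(x1, x2) {
  (rescale_u(camel_raw(x1, x2)) + halfplane_h(x1, x2)) / 2
}

#' Search spec for the toy problem
#'
#' Box `[-2, 2] x [-1, 1]`, initial guess `(-2, 1)`, initial standard
#' deviations 0.5 on both coordinates, population size 20.
#'
#' @param seed Integer seed.
#' @param stop_threshold,max_generations Optimizer settings; defaults stop
#'   on stagnation very close to the optimum.
#' @return A [search_spec()].
#' @export
toy_search_spec <- function(seed = 1L, stop_threshold = 0.9999,
                            max_generations = 300L) {
  search_spec(
    list(
      parameter_spec("x1", -2, 2, init = -2, init_sd = 0.5),
      parameter_spec("x2", -1, 1, init = 1, init_sd = 0.5)
    ),
    population_size = 20L,
    stop_threshold = stop_threshold,
    stagnation_window = 20L,
    stagnation_tol = 1e-8,
    max_generations = max_generations,
    seed = seed
  )
}

#' Run the toy calibration demo
#'
#' Maximizes the toy objective with CMA-ES under the reference settings
#' (start `(-2, 1)`, sigma 0.5, population 20).
#'
#' @param seed Integer seed.
#' @param ... Passed to [toy_search_spec()].
#' @return A `cma_result`.
#' @export
toy_demo <- function(seed = 1L, ...) {
  cma_maximize(function(theta) toy_objective(theta[["x1"]], theta[["x2"]]),
               toy_search_spec(seed = seed, ...))
}

#' Brute-force grid search over the toy box
#'
#' Evaluates the toy objective on a regular `n x n` grid over
#' `[-2, 2] x [-1, 1]` and returns the grid maximum — an independent check
#' that the global maximum is 1 near `(0.0898, -0.7126)`.
#'
#' @param n Grid points per axis.
#' @return List with `value`, `x1`, `x2` of the grid maximum.
#' @export
toy_grid_search <- function(n = 1001L) {
  x1 <- seq(-2, 2, length.out = n)
  x2 <- seq(-1, 1, length.out = n)
  best <- list(value = -Inf, x1 = NA_real_, x2 = NA_real_)
  for (v2 in x2) { # row-wise to keep memory flat
    f <- toy_objective(x1, v2)
    i <- which.max(f)
    if (f[i] > best$value) best <- list(value = f[i], x1 = x1[i], x2 = v2)
  }
  best
}
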