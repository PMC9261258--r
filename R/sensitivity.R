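#' Factorial parameter-space screening
#'
#' Before calibration, large parameter ranges are screened with regular
#' factorial designs: every combination of a few equally spaced levels
#' per parameter is simulated, combinations leading to numerical error
#' or aberrant model behavior (literature-derived binary rules) are
#' discarded, and the surviving rows define the reduced parameter space
#' handed to the optimizer.
#'
#' @name sensitivity
NULL

#' Build a regular factorial design
#'
#' Full Cartesian grid of `levels` equally spaced values per parameter
#' (log-spaced for `log_scale` parameters), endpoints included, in
#' deterministic lexicographic row order (last parameter varies
#' fastest).
#'
#' @param specs List of [parameter_spec()]s.
#' @param levels Levels per parameter (single value or one per
#'   parameter), each `>= 2`.
#' @return Object of class `factorial_design`: `$design` (data frame,
#'   one column per parameter), `$specs`, `$levels`.
#' @export
factorial_design <- function(specs, levels = 3L) {
  if (inherits(specs, "parameter_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1L,
            all(vapply(specs, inherits, logical(1L), "parameter_spec")))
  nms <- vapply(specs, `[[`, character(1L), "name")
  names(specs) <- nms
  levels <- rep_len(as.integer(levels), length(specs))
  if (any(levels < 2L)) stop("levels must be >= 2", call. = FALSE)
  n_rows <- prod(as.numeric(levels))
  if (n_rows > 1e6) {
    stop("design would have ", format(n_rows, big.mark = ","),
         " rows; use fewer levels or parameters (fractional screening)",
         call. = FALSE)
  }
  grids <- mapply(function(p, l) {
    if (p$log_scale) exp(seq(log(p$lower), log(p$upper), length.out = l))
    else seq(p$lower, p$upper, length.out = l)
  }, specs, levels, SIMPLIFY = FALSE)
  # lexicographic: first parameter slowest
  design <- rev(expand.grid(rev(grids), KEEP.OUT.ATTRS = FALSE))
  names(design) <- nms
  structure(list(design = design, specs = specs, levels = levels),
            class = "factorial_design")
}

#' Screen a factorial design through the growth model
#'
#' Simulates every design row (overriding the baseline parameters) and
#' classifies it as `"ok"`, `"numerical_error"` (integration failure) or
#' `"aberrant"` (violates an aberrance rule, expressed as
#' [binary_constraint()]s). The reduced range of each parameter is the
#' min–max over `"ok"` rows; parameters with no surviving rows are
#' reported as blocking.
#'
#' @param design A [factorial_design()].
#' @param base_params Baseline [growth_params()].
#' @param scenario A [growth_scenario()] to simulate.
#' @param aberrance_rules List of [binary_constraint()]s; a row is
#'   aberrant when any rule scores 0.
#' @return List of class `screen_result`: `$classification` data frame
#'   (design columns + `status`), `$reduced` (per-parameter
#'   `lower`/`upper` over ok rows), `$blocking` (parameter names with no
#'   ok rows — empty unless the whole design fails).
#' @export
screen_design <- function(design, base_params, scenario,
                          aberrance_rules = list()) {
  stopifnot(inherits(design, "factorial_design"),
            inherits(base_params, "growth_params"),
            inherits(scenario, "growth_scenario"))
  if (length(aberrance_rules) &&
      !all(vapply(aberrance_rules, inherits, logical(1L),
                  "binary_constraint"))) {
    stop("aberrance rules must be binary constraints", call. = FALSE)
  }
  df <- design$design
  if (nrow(df) == 0L) stop("empty design", call. = FALSE)
  status <- character(nrow(df))
  for (i in seq_len(nrow(df))) {
    theta <- unlist(df[i, , drop = FALSE])
    tr <- tryCatch({
      simulate_growth(set_growth_params(base_params, theta), scenario)
    }, error = function(e) NULL)
    if (is.null(tr)) {
      status[i] <- "numerical_error"
      next
    }
    ok <- all(vapply(aberrance_rules, score_constraint, numeric(1L),
                     trajectory = tr) == 1)
    status[i] <- if (ok) "ok" else "aberrant"
  }
  keep <- df[status == "ok", , drop = FALSE]
  reduced <- lapply(names(df), function(nm) {
    if (nrow(keep) == 0L) return(c(lower = NA_real_, upper = NA_real_))
    c(lower = min(keep[[nm]]), upper = max(keep[[nm]]))
  })
  names(reduced) <- names(df)
  blocking <- if (nrow(keep) == 0L) names(df) else character(0L)
  structure(
    list(classification = cbind(df, status = status), reduced = reduced,
         blocking = blocking),
    class = "screen_result"
  )
}

#' Turn screened ranges into narrowed parameter specs
#'
#' @param result A `screen_result`.
#' @param specs The original [parameter_spec()] list used for the design.
#' @return The spec list with bounds intersected with the reduced
#'   ranges (initial guesses clipped inside).
#' @export
apply_screen <- function(result, specs) {
  for (nm in names(result$reduced)) {
    r <- result$reduced[[nm]]
    if (anyNA(r) || !nm %in% names(specs)) next
    p <- specs[[nm]]
    lo <- max(p$lower, r[["lower"]])
    hi <- min(p$upper, r[["upper"]])
    init <- min(max(p$init, lo), hi)
    specs[[nm]] <- parameter_spec(nm, lo, hi, init = init, unit = p$unit,
                                  log_scale = p$log_scale && lo > 0,
                                  allometric = p$allometric)
  }
  specs
}
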