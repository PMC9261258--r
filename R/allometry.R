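#' Allometric scaling of model parameters
#'
#' Physiological quantities scale with body mass as power laws
#' \eqn{Z = a M^b} (Kleiber's law: metabolic rate scales with exponent
#' 3/4). The exponent is determined by the parameter's physical
#' dimension, so a rate calibrated at one body mass can be transferred to
#' another scale (e.g. from an in vitro reference mass of 2.63 g to a
#' 23 g mouse) without recalibration.
#'
#' @name allometry
NULL

# quarter-power exponent table keyed by dimension class
.allometry_table <- list(
  dimensionless = 0,
  rate          = -1 / 4, # first-order rate constants, unit 1/time
  flux          = 3 / 4,  # metabolic/transport fluxes, quantity per time
  time          = 1 / 4   # characteristic times
)

# unit strings mapped onto dimension classes
.unit_dimension <- list(
  dimensionless = "dimensionless",
  "1/day" = "rate", "1/h" = "rate", "per-time" = "rate", rate = "rate",
  "quantity/day" = "flux", "quantity/time" = "flux", flux = "flux",
  day = "time", h = "time", time = "time"
)

#' Allometric exponent from a physical unit
#'
#' Maps a unit string to its quarter-power allometric exponent:
#' dimensionless quantities scale with `b = 0`, first-order rates
#' (`1/time`) with `b = -1/4`, fluxes (`quantity/time`) with `b = 3/4`
#' (Kleiber's law), and characteristic times with `b = 1/4`.
#'
#' @param unit Unit string (e.g. `"1/day"`) or dimension class name.
#' @param extra Optional named numeric vector extending/overriding the
#'   unit table (configuration hook).
#' @return The exponent `b`.
#' @export
allometric_exponent <- function(unit, extra = NULL) {
  if (!is.null(extra) && unit %in% names(extra)) {
    return(unname(extra[[unit]]))
  }
  dim_class <- .unit_dimension[[unit]]
  if (is.null(dim_class)) {
    stop("unknown unit '", unit, "'; supported units: ",
         paste(names(.unit_dimension), collapse = ", "),
         " (extend via the 'extra' table)", call. = FALSE)
  }
  .allometry_table[[dim_class]]
}

#' Transfer a parameter value between body masses
#'
#' `value_at_target = value_at_ref * (m_target / m_ref)^b`.
#'
#' @param value Parameter value at the reference mass.
#' @param m_ref,m_target Body masses in grams (both `> 0`).
#' @param b Allometric exponent (see [allometric_exponent()]).
#' @return The value rescaled to `m_target`.
#' @examples
#' scale_allometric(1, m_ref = 1, m_target = 16, b = 3/4) # 8
#' @export
scale_allometric <- function(value, m_ref, m_target, b) {
  if (any(m_ref <= 0) || any(m_target <= 0)) {
    stop("body masses must be positive", call. = FALSE)
  }
  value * (m_target / m_ref)^b
}

#' Allometric coefficient from a calibrated value
#'
#' Inverts the power law: `a = value / m_ref^b`, so that `a * m^b`
#' reproduces the calibrated value at `m = m_ref` and extrapolates it to
#' any other mass.
#'
#' @param value Calibrated parameter value at `m_ref`.
#' @param m_ref Reference body mass in grams (`> 0`).
#' @param b Allometric exponent.
#' @return The coefficient `a`.
#' @export
allometric_coefficient <- function(value, m_ref, b) {
  if (any(m_ref <= 0)) stop("body masses must be positive", call. = FALSE)
  value / m_ref^b
}
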