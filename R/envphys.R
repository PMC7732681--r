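#' Air state
#'
#' Bundle of the chamber/laboratory air variables used throughout the
#' package: air temperature, relative humidity and atmospheric pressure.
#' Leaf temperature is taken equal to air (block) temperature; no
#' leaf-to-air offset is modelled.
#'
#' @param T_air Air temperature (degrees C). Must lie in (-20, 60).
#' @param RH Relative humidity as a fraction in \[0, 1\]. Instrument files
#'   reporting percent must be divided by 100 at ingest (see
#'   [read_gas_exchange_table()]).
#' @param P_atm Atmospheric pressure (kPa), default 101.325 (sea-level
#'   standard, used when a file carries no pressure).
#' @return An object of class `air_state`.
#' @examples
#' air_state(25, 0.30)
#' @export
air_state <- function(T_air, RH, P_atm = 101.325) {
  stopifnot(is.numeric(T_air), is.numeric(RH), is.numeric(P_atm))
  if (any(T_air <= -20 | T_air >= 60)) {
    stop("air_state: T_air must lie in (-20, 60) degrees C", call. = FALSE)
  }
  if (any(RH < 0 | RH > 1)) {
    stop("air_state: RH must be a fraction in [0, 1]", call. = FALSE)
  }
  if (any(P_atm <= 0)) {
    stop("air_state: P_atm must be positive (kPa)", call. = FALSE)
  }
  structure(list(T_air = T_air, RH = RH, P_atm = P_atm),
            class = "air_state")
}

#' Saturation vapor pressure (Tetens)
#'
#' Tetens formulation over liquid water,
#' \eqn{e_s(T) = 0.6108 \exp(17.27 T / (T + 237.3))} kPa.
#' The Buck formulation differs by less than 0.1% over the supported
#' temperature range.
#'
#' @param T_air Air temperature (degrees C), in (-20, 60).
#' @return Saturation vapor pressure (kPa).
#' @examples
#' saturation_vapor_pressure(25) # ~3.17 kPa
#' @export
saturation_vapor_pressure <- function(T_air) {
  if (!is.numeric(T_air) || any(T_air <= -20 | T_air >= 60)) {
    stop("saturation_vapor_pressure: T_air must lie in (-20, 60) degrees C",
         call. = FALSE)
  }
  0.6108 * exp(17.27 * T_air / (T_air + 237.3))
}

#' Vapor pressure deficit
#'
#' \eqn{D = (1 - RH) \, e_s(T)}. At 25 degrees C and 30% relative humidity
#' this gives ~2.2 kPa, the nighttime chamber deficit used to force
#' stomatal closure.
#'
#' @param air An [air_state()].
#' @return Vapor pressure deficit (kPa).
#' @export
vapor_pressure_deficit <- function(air) {
  stopifnot(inherits(air, "air_state"))
  (1 - air$RH) * saturation_vapor_pressure(air$T_air)
}

#' Leaf transpiration from conductance and vapor pressure deficit
#'
#' \eqn{E_l = g_s D / P}, returned in mmol m-2 s-1 for `gs` in
#' mol m-2 s-1. Linear in both `gs` and `D`.
#'
#' @param gs Conductance to water vapor (mol m-2 s-1), >= 0.
#' @param D Vapor pressure deficit (kPa), >= 0.
#' @param P Atmospheric pressure (kPa), > 0.
#' @return Transpiration rate (mmol m-2 s-1).
#' @examples
#' transpiration_rate(0.1, 2.22, 101.3)
#' @export
transpiration_rate <- function(gs, D, P) {
  stopifnot(is.numeric(gs), is.numeric(D), is.numeric(P))
  if (any(P <= 0)) stop("transpiration_rate: P must be > 0 kPa", call. = FALSE)
  if (any(gs < 0)) stop("transpiration_rate: gs must be >= 0", call. = FALSE)
  if (any(D < 0)) stop("transpiration_rate: D must be >= 0", call. = FALSE)
  mol_to_mmol(gs * D / P)
}

#' @rdname unit_conversions
#' @export
mol_to_mmol <- function(x) x * 1000

#' Conductance unit conversions
#'
#' Exact scaling between mol m-2 s-1 and mmol m-2 s-1.
#'
#' @param x Numeric vector.
#' @return Rescaled numeric vector.
#' @name unit_conversions
#' @export
mmol_to_mol <- function(x) x / 1000
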