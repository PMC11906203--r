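#' Gas mixture of carbon dioxide, oxygen and balance gas
#'
#' A well-mixed gas volume is described by the volume fractions of CO2 and
#' O2; everything else (nitrogen plus trace gases) is lumped into a balance
#' fraction so the three always sum to one. Fractions are dimensionless
#' (0.21, not 21); formatting to vol% happens only at reporting time.
#'
#' @param f_co2 CO2 volume fraction in `[0, 1]`.
#' @param f_o2 O2 volume fraction in `[0, 1]`.
#' @param f_bal Balance (N2 + trace) fraction; defaults to `1 - f_co2 - f_o2`.
#' @return An object of class `gas_mixture`: a named numeric vector with
#'   components `f_co2`, `f_o2`, `f_bal`.
#' @examples
#' fresh_air()
#' gas_mixture(f_co2 = 0.044, f_o2 = 0.164)
#' @export
gas_mixture <- function(f_co2, f_o2, f_bal = NULL) {
  if (is.null(f_bal)) f_bal <- 1 - f_co2 - f_o2
  x <- c(f_co2 = f_co2, f_o2 = f_o2, f_bal = f_bal)
  if (any(!is.finite(x))) {
    stop("gas fractions must be finite numbers", call. = FALSE)
  }
  if (any(x < -1e-12) || any(x > 1 + 1e-12)) {
    stop("gas fractions must lie in [0, 1]; got (",
         paste(signif(x, 6), collapse = ", "), ")", call. = FALSE)
  }
  if (abs(sum(x) - 1) > 1e-9) {
    stop("gas fractions must sum to 1 (got ", signif(sum(x), 12), ")",
         call. = FALSE)
  }
  x <- pmin(pmax(x, 0), 1)
  structure(x, class = "gas_mixture")
}

#' @rdname gas_mixture
#' @export
fresh_air <- function() gas_mixture(f_co2 = 0.0004, f_o2 = 0.21)

#' @export
print.gas_mixture <- function(x, ...) {
  cat(sprintf("<gas_mixture> CO2 %.4g vol%%, O2 %.4g vol%%, balance %.4g vol%%\n",
              100 * x[["f_co2"]], 100 * x[["f_o2"]], 100 * x[["f_bal"]]))
  invisible(x)
}

#' Pressure convention for fraction / partial-pressure conversion
#'
#' Partial pressures are computed against an effective total pressure:
#' the barometric total minus an optional water-vapor correction. The dry
#' convention (no correction) reproduces the textbook fresh-air values
#' (21 vol% O2 -> 159.6 ~ 160 mm Hg at 760 mm Hg); the BTPS convention
#' subtracts 47 mm Hg of saturated water vapor at body temperature.
#'
#' @param total_pressure Total (barometric) pressure, mm Hg. Default 760.
#' @param water_vapor_correction mm Hg subtracted from the total; 0 for the
#'   dry convention, 47 for BTPS.
#' @return An object of class `pressure_convention`.
#' @examples
#' convention_dry()
#' convention_btps()
#' @export
pressure_convention <- function(total_pressure = 760,
                                water_vapor_correction = 0) {
  if (!is.finite(total_pressure) || !is.finite(water_vapor_correction) ||
      water_vapor_correction < 0 ||
      total_pressure <= water_vapor_correction) {
    stop("need total_pressure > water_vapor_correction >= 0", call. = FALSE)
  }
  structure(
    list(total_pressure = total_pressure,
         water_vapor_correction = water_vapor_correction),
    class = "pressure_convention"
  )
}

#' @rdname pressure_convention
#' @export
convention_dry <- function(total_pressure = 760) {
  pressure_convention(total_pressure, 0)
}

#' @rdname pressure_convention
#' @export
convention_btps <- function(total_pressure = 760) {
  pressure_convention(total_pressure, 47)
}

effective_pressure <- function(conv) {
  conv$total_pressure - conv$water_vapor_correction
}

#' Convert a volume fraction to a partial pressure
#'
#' @param f Volume fraction in `[0, 1]`.
#' @param conv A [pressure_convention()]; dry 760 mm Hg by default.
#' @return Partial pressure in mm Hg: `f * (total - water_vapor_correction)`.
#' @examples
#' fraction_to_partial_pressure(0.21)    # 159.6, ~160 mm Hg
#' fraction_to_partial_pressure(0.0004)  # 0.304, ~0.3 mm Hg
#' @export
fraction_to_partial_pressure <- function(f, conv = convention_dry()) {
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1)) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  f * effective_pressure(conv)
}

#' Convert a partial pressure to a volume fraction
#'
#' Inverse of [fraction_to_partial_pressure()] under the same convention.
#'
#' @param p Partial pressure, mm Hg; must not exceed the effective total.
#' @inheritParams fraction_to_partial_pressure
#' @return Volume fraction.
#' @examples
#' partial_pressure_to_fraction(35)  # 0.04605
#' @export
partial_pressure_to_fraction <- function(p, conv = convention_dry()) {
  pe <- effective_pressure(conv)
  if (any(!is.finite(p)) || any(p < 0) || any(p > pe)) {
    stop("partial pressure must lie in [0, ", pe, "] mm Hg", call. = FALSE)
  }
  p / pe
}

#' Conservatively mix two gas volumes
#'
#' Volume-weighted mixing of two well-mixed gas parcels: each species
#' fraction of the result is the volume-weighted mean, so species volumes
#' are conserved exactly.
#'
#' @param a,b [gas_mixture()] objects.
#' @param vol_a,vol_b Non-negative parcel volumes (mL); their sum must be
#'   positive.
#' @return A [gas_mixture()].
#' @examples
#' mix_gas(gas_mixture(0.044, 0.164), 35, fresh_air(), 35)
#' @export
mix_gas <- function(a, vol_a, b, vol_b) {
  stopifnot(inherits(a, "gas_mixture"), inherits(b, "gas_mixture"))
  if (vol_a < 0 || vol_b < 0) {
    stop("parcel volumes must be non-negative", call. = FALSE)
  }
  if (vol_a + vol_b <= 0) {
    stop("cannot mix two zero-volume parcels", call. = FALSE)
  }
  w <- vol_a / (vol_a + vol_b)
  out <- w * unclass(a) + (1 - w) * unclass(b)
  gas_mixture(out[["f_co2"]], out[["f_o2"]], out[["f_bal"]])
}
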