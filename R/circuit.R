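#' Laminar tube airway element
#'
#' A straight tube in fully developed laminar flow obeys the Poiseuille law
#' `dP = R_lin * Q` with `R_lin = 8 mu L / (pi r^4)`. The default geometry is
#' the open-ended breathing tube: 300 mm long, 5 mm internal diameter.
#'
#' @param length_mm Tube length, mm.
#' @param diameter_mm Internal diameter, mm.
#' @param viscosity Dynamic viscosity of air, Pa s. Default 1.81e-5
#'   (room temperature).
#' @return An airway element of class `c("tube_element", "airway_element")`.
#' @examples
#' tube_element()
#' element_dp(tube_element(), q = 80.6)
#' @export
tube_element <- function(length_mm = 300, diameter_mm = 5,
                         viscosity = 1.81e-5) {
  r <- tube_resistance(length_mm, diameter_mm, viscosity)
  structure(
    list(length_mm = length_mm, diameter_mm = diameter_mm,
         viscosity = viscosity, r_lin = r),
    class = c("tube_element", "airway_element")
  )
}

#' Poiseuille resistance of a cylindrical tube
#'
#' `R_lin = 8 mu L / (pi r^4)`, converted from SI (Pa s / m^3) to the
#' circuit units mbar s / mL (1 Pa s / m^3 = 1e-8 mbar s / mL).
#'
#' @inheritParams tube_element
#' @return Linear resistance in mbar s / mL.
#' @examples
#' tube_resistance(300, 5)  # ~3.54e-3 mbar s/mL
#' @export
tube_resistance <- function(length_mm, diameter_mm, viscosity = 1.81e-5) {
  if (length_mm <= 0 || diameter_mm <= 0 || viscosity <= 0) {
    stop("tube geometry and viscosity must be positive", call. = FALSE)
  }
  r_m <- diameter_mm / 2 / 1000
  r_si <- 8 * viscosity * (length_mm / 1000) / (pi * r_m^4) # Pa s / m^3
  r_si * 1e-8
}

#' Sharp-edged orifice airway element
#'
#' Incompressible quadratic orifice law
#' `dP = rho Q |Q| / (2 Cd^2 A^2)`, sign-preserving. The paper's test
#' series uses diameters 4.03, 3.25, 2.64, 1.93 and 1.07 mm.
#'
#' @param diameter_mm Orifice internal diameter, mm.
#' @param discharge_coefficient Dimensionless discharge coefficient in
#'   `(0, 1]`; 0.6 is the sharp-edged convention.
#' @param air_density Air density, kg/m^3.
#' @return An airway element of class `c("orifice_element", "airway_element")`.
#' @examples
#' element_dp(orifice_element(1.07), q = 80.6)  # ~134 mbar
#' @export
orifice_element <- function(diameter_mm, discharge_coefficient = 0.6,
                            air_density = 1.2) {
  if (diameter_mm <= 0) stop("orifice diameter must be positive", call. = FALSE)
  if (discharge_coefficient <= 0 || discharge_coefficient > 1) {
    stop("discharge coefficient must lie in (0, 1]", call. = FALSE)
  }
  if (air_density <= 0) stop("air density must be positive", call. = FALSE)
  area_m2 <- pi * (diameter_mm / 2000)^2
  # dP[Pa] = rho Q[m3/s]^2 / (2 Cd^2 A^2); to mbar per (mL/s)^2:
  # Q[m3/s] = 1e-6 Q[mL/s], Pa -> mbar is /100  =>  factor 1e-14
  k_quad <- air_density / (2 * discharge_coefficient^2 * area_m2^2) * 1e-14
  structure(
    list(diameter_mm = diameter_mm,
         discharge_coefficient = discharge_coefficient,
         air_density = air_density, k_quad = k_quad),
    class = c("orifice_element", "airway_element")
  )
}

#' Lumped linear resistor element
#'
#' A plain linear pressure-drop element `dP = R Q`, used for the small
#' intrinsic resistance of porous bedding material.
#'
#' @param r_lin Resistance in mbar s / mL, non-negative.
#' @return An airway element.
#' @export
resistor_element <- function(r_lin) {
  if (!is.finite(r_lin) || r_lin < 0) {
    stop("resistance must be a non-negative number", call. = FALSE)
  }
  structure(list(r_lin = r_lin),
            class = c("resistor_element", "airway_element"))
}

#' Pressure drop across a single airway element
#'
#' @param element An airway element (tube, orifice or resistor).
#' @param q Flow, mL/s (vectorised); positive into the lung.
#' @return Pressure drop in mbar, an odd function of `q`.
#' @export
element_dp <- function(element, q) UseMethod("element_dp")

#' @export
element_dp.tube_element <- function(element, q) element$r_lin * q

#' @export
element_dp.resistor_element <- function(element, q) element$r_lin * q

#' @export
element_dp.orifice_element <- function(element, q) element$k_quad * q * abs(q)

#' Series airway: ordered chain of elements
#'
#' Pressure drops of elements in series add at equal flow, so the chain's
#' `dP(Q)` is the element sum: strictly increasing and odd in `Q`.
#'
#' @param ... Airway elements, in order.
#' @return An object of class `airway` (a list of elements).
#' @examples
#' aw <- airway(tube_element(), orifice_element(1.07))
#' airway_dp(aw, 80.6)
#' @export
airway <- function(...) {
  elements <- list(...)
  if (length(elements) == 0) {
    stop("an airway needs at least one element", call. = FALSE)
  }
  ok <- vapply(elements, inherits, logical(1), what = "airway_element")
  if (!all(ok)) stop("all airway components must be airway elements",
                     call. = FALSE)
  structure(elements, class = "airway")
}

#' Total pressure drop across a series airway
#'
#' @param aw An [airway()].
#' @param q Flow, mL/s (vectorised).
#' @return Total pressure drop, mbar.
#' @export
airway_dp <- function(aw, q) {
  stopifnot(inherits(aw, "airway"))
  Reduce(`+`, lapply(unclass(aw), element_dp, q = q))
}

#' Compliant lung element
#'
#' Twin-bellows lung with compliance 0.7 mL/mbar reciprocating between
#' 30 and 65 mL (tidal volume 35 mL) by default. In the simulator the
#' volume excursion is prescribed by the breathing pattern; compliance is
#' carried for the pressure-driven mode and reporting.
#'
#' @param compliance mL per mbar, > 0.
#' @param v_min,v_max End-expiratory and end-inspiratory volumes, mL.
#' @param gas Initial lung gas, a [gas_mixture()]; fresh air by default.
#' @return An object of class `compliant_lung`.
#' @export
compliant_lung <- function(compliance = 0.7, v_min = 30, v_max = 65,
                           gas = fresh_air()) {
  if (compliance <= 0) stop("compliance must be positive", call. = FALSE)
  if (!(v_min > 0 && v_min < v_max)) {
    stop("need 0 < v_min < v_max", call. = FALSE)
  }
  stopifnot(inherits(gas, "gas_mixture"))
  structure(list(compliance = compliance, v_min = v_min, v_max = v_max,
                 gas = gas),
            class = "compliant_lung")
}

#' Bedding gas-storage compartment
#'
#' A single well-mixed compartment of effective volume `storage_volume`
#' sitting at the airway opening. On each inhalation a fraction
#' `entrainment` of the tidal volume is drawn from the stored gas (capped
#' by what the compartment holds); exhaled gas mixes back into the
#' compartment with overflow vented to ambient; between breaths the
#' compartment's composition excess over ambient decays by the washout
#' retention factor.
#'
#' @param storage_volume Effective gas storage volume, mL (>= 0).
#' @param entrainment Fraction beta in `[0, 1]` of inhaled volume drawn
#'   from stored gas (before the availability cap).
#' @param retention Per-breath washout retention a in `[0, 1]`: the
#'   fraction of the compartment's composition excess over ambient that
#'   survives to the next breath.
#' @param resistance Intrinsic linear airflow resistance of the material,
#'   mbar s / mL (near zero for open polyfill).
#' @param gas Initial stored gas; ambient fresh air by default.
#' @return An object of class `storage_compartment`.
#' @export
storage_compartment <- function(storage_volume, entrainment = 1,
                                retention = 0.5, resistance = 0,
                                gas = fresh_air()) {
  if (!is.finite(storage_volume) || storage_volume < 0) {
    stop("storage_volume must be non-negative", call. = FALSE)
  }
  if (entrainment < 0 || entrainment > 1) {
    stop("entrainment must lie in [0, 1]", call. = FALSE)
  }
  if (retention < 0 || retention > 1) {
    stop("retention must lie in [0, 1]", call. = FALSE)
  }
  if (!is.finite(resistance) || resistance < 0) {
    stop("resistance must be non-negative", call. = FALSE)
  }
  stopifnot(inherits(gas, "gas_mixture"))
  structure(list(storage_volume = storage_volume, entrainment = entrainment,
                 retention = retention, resistance = resistance, gas = gas),
            class = "storage_compartment")
}

#' Polyfill layer preset for the storage compartment
#'
#' Maps a layer count of low-density polyfill to storage parameters
#' linearly: `storage_volume = kappa * layers` and intrinsic resistance
#' `r_per_layer * layers`. With the default `kappa` of 5 mL/layer the
#' "wrapped" 8-layer condition stores more than one tidal volume, so the
#' entrainment cap makes inhalation draw entirely from stored gas
#' (full rebreathing). These are calibration constants: the bench work
#' quantifies layers, not storage volume.
#'
#' @param layers Number of polyfill layers (>= 0); 0 means no storage.
#' @param kappa_ml_per_layer Effective storage volume per layer, mL.
#' @param r_per_layer Intrinsic linear resistance per layer, mbar s / mL.
#' @param retention Per-breath washout retention, see
#'   [storage_compartment()].
#' @return A [storage_compartment()], or `NULL` for `layers = 0`.
#' @examples
#' polyfill_storage(4)
#' @export
polyfill_storage <- function(layers, kappa_ml_per_layer = 5,
                             r_per_layer = 2e-4, retention = 0.5) {
  if (!is.finite(layers) || layers < 0) {
    stop("layers must be non-negative", call. = FALSE)
  }
  if (layers == 0) return(NULL)
  storage_compartment(
    storage_volume = kappa_ml_per_layer * layers,
    entrainment = 1,
    retention = retention,
    resistance = r_per_layer * layers
  )
}

#' The paper's three storage presets for the combination grid
#'
#' "2 layers", "4 layers" and "wrapped" (treated as an 8-layer
#' equivalent) polyfill conditions.
#'
#' @param condition One of "2 layers", "4 layers", "wrapped".
#' @inheritParams polyfill_storage
#' @return A [storage_compartment()].
#' @export
storage_preset <- function(condition = c("2 layers", "4 layers", "wrapped"),
                           kappa_ml_per_layer = 5, r_per_layer = 2e-4,
                           retention = 0.5) {
  condition <- match.arg(condition)
  layers <- switch(condition, "2 layers" = 2, "4 layers" = 4, "wrapped" = 8)
  polyfill_storage(layers, kappa_ml_per_layer, r_per_layer, retention)
}
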