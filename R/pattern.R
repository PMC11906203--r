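#' Prescribed breathing pattern
#'
#' The lung-volume driver: a periodic volume trajectory spanning
#' `[v_min, v_min + tidal_volume]` at a fixed rate. The default is the
#' sleeping-infant setting of the bench model: 44 breaths/min, 35 mL tidal
#' volume, sinusoidal excursion. A trapezoidal-flow waveform with a
#' configurable rise fraction is available as an alternative to the
#' sinusoid.
#'
#' @param rate Breathing rate, breaths per minute (> 0).
#' @param tidal_volume Tidal volume, mL (> 0).
#' @param waveform `"sinusoid"` (default) or `"trapezoid"` (trapezoidal
#'   flow: linear rise, plateau, linear fall within each half-cycle).
#' @param rise_fraction For the trapezoid, the fraction of each half-cycle
#'   spent ramping flow up (and, symmetrically, down); in `(0, 0.5]`.
#' @return An object of class `breathing_pattern`.
#' @examples
#' breathing_pattern()
#' @export
breathing_pattern <- function(rate = 44, tidal_volume = 35,
                              waveform = c("sinusoid", "trapezoid"),
                              rise_fraction = 0.25) {
  waveform <- match.arg(waveform)
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  if (tidal_volume <= 0) stop("tidal_volume must be positive", call. = FALSE)
  if (waveform == "trapezoid" &&
      (rise_fraction <= 0 || rise_fraction > 0.5)) {
    stop("rise_fraction must lie in (0, 0.5]", call. = FALSE)
  }
  structure(list(rate = rate, tidal_volume = tidal_volume,
                 waveform = waveform, rise_fraction = rise_fraction,
                 period = 60 / rate),
            class = "breathing_pattern")
}

# normalized trapezoid flow shape on s in [0,1]: integral 1
trapezoid_shape <- function(s, rho) {
  q <- ifelse(s < rho, s / rho,
              ifelse(s > 1 - rho, (1 - s) / rho, 1)) / (1 - rho)
  v <- ifelse(s < rho, s^2 / (2 * rho),
              ifelse(s > 1 - rho, 1 - rho - (1 - s)^2 / (2 * rho),
                     s - rho / 2)) / (1 - rho)
  list(q = q, v = v)
}

#' Lung volume and flow of a breathing pattern
#'
#' Evaluate the prescribed volume `V(t)` (mL) and its derivative, the
#' prescribed flow `dV/dt` (mL/s, positive during inhalation), at
#' arbitrary times. Inhalation occupies the first half of each period.
#'
#' @param pattern A [breathing_pattern()].
#' @param t Time(s), s (vectorised).
#' @param v_min End-expiratory volume, mL.
#' @return `pattern_volume()` returns volumes in mL; `pattern_flow()`
#'   returns flows in mL/s.
#' @export
pattern_volume <- function(pattern, t, v_min = 30) {
  vt <- pattern$tidal_volume
  per <- pattern$period
  phi <- (t %% per) / per
  if (pattern$waveform == "sinusoid") {
    v_min + vt / 2 * (1 - cos(2 * pi * phi))
  } else {
    inhale <- phi < 0.5
    s <- ifelse(inhale, phi * 2, (phi - 0.5) * 2)
    sh <- trapezoid_shape(s, pattern$rise_fraction)
    ifelse(inhale, v_min + vt * sh$v, v_min + vt * (1 - sh$v))
  }
}

#' @rdname pattern_volume
#' @export
pattern_flow <- function(pattern, t) {
  vt <- pattern$tidal_volume
  per <- pattern$period
  phi <- (t %% per) / per
  if (pattern$waveform == "sinusoid") {
    vt / 2 * (2 * pi / per) * sin(2 * pi * phi)
  } else {
    inhale <- phi < 0.5
    s <- ifelse(inhale, phi * 2, (phi - 0.5) * 2)
    sh <- trapezoid_shape(s, pattern$rise_fraction)
    ifelse(inhale, 1, -1) * vt * sh$q / (per / 2)
  }
}

#' Metabolic gas source
#'
#' A constant source metering CO2 into the lung gas and removing O2, as in
#' the bench model where CO2 is metered into the externally actuated lung.
#' The default CO2 rate is calibrated so that, with no storage medium, the
#' equilibrium exhaled CO2 fraction is 4.4 vol% above ambient divided
#' into the tidal volume: `0.044 * 35 mL * 44/min = 67.76 mL/min`. O2
#' uptake defaults to the CO2 rate divided by a respiratory quotient of
#' 0.8.
#'
#' In the default `"neutral"` volume mode the source is volume-neutral in
#' the lung (the O2/CO2 volume imbalance is carried by the balance gas),
#' so airway flow equals the prescribed `dV/dt` exactly and each breath
#' moves exactly one tidal volume through the airway. The `"net"` mode
#' instead lets the metabolic imbalance appear as a small extra airway
#' flow.
#'
#' @param co2_mL_min CO2 injection rate, mL/min (>= 0).
#' @param rq Respiratory quotient used for the default O2 uptake.
#' @param o2_mL_min O2 uptake rate, mL/min (>= 0); default `co2_mL_min/rq`.
#' @param volume_mode `"neutral"` (default) or `"net"`; see Details.
#' @return An object of class `metabolic_source`.
#' @export
metabolic_source <- function(co2_mL_min = 0.044 * 35 * 44, rq = 0.8,
                             o2_mL_min = co2_mL_min / rq,
                             volume_mode = c("neutral", "net")) {
  volume_mode <- match.arg(volume_mode)
  if (co2_mL_min < 0 || o2_mL_min < 0) {
    stop("metabolic rates must be non-negative", call. = FALSE)
  }
  structure(list(co2_mL_min = co2_mL_min, o2_mL_min = o2_mL_min,
                 rq = rq, volume_mode = volume_mode),
            class = "metabolic_source")
}
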