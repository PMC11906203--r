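#' Generate a synthetic pressure-volume fixture with known work
#'
#' Deterministic, seedless p-v records emulating the bench waveforms
#' (sinusoidal volume through an open tube or an orifice), plus two
#' geometric loops with closed-form areas. Every fixture carries its
#' analytically expected work of breathing, so the trapezoidal integrator
#' can be checked against an independent oracle.
#'
#' Kinds:
#' \describe{
#'   \item{`"flat"`}{sinusoidal volume, pressure identically zero;
#'     expected work 0.}
#'   \item{`"ellipse"`}{an elliptical loop with pressure semi-axis
#'     `a_mbar` (centred on 0) and volume semi-axis `b_mL`, traversed so
#'     the inspiratory limb sees negative pressure; expected work is the
#'     half-ellipse area `pi a b / 2` mbar mL.}
#'   \item{`"linear_sinusoid"`}{sinusoidal volume through a linear
#'     resistance `r_lin`; expected work from
#'     [wob_linear_closed_form()].}
#'   \item{`"orifice_sinusoid"`}{sinusoidal volume through a quadratic
#'     orifice of diameter `diameter_mm`; expected work from
#'     [wob_orifice_closed_form()].}
#' }
#'
#' @param kind Fixture kind, see Details.
#' @param cycles Number of full cycles in the record.
#' @param samples_per_cycle Samples per cycle (>= 50).
#' @param rate Breaths per minute.
#' @param tidal_volume Tidal volume, mL (volume spans `v_min` to
#'   `v_min + tidal_volume` for the sinusoid kinds).
#' @param v_min End-expiratory volume, mL.
#' @param r_lin Linear resistance for `"linear_sinusoid"`, mbar s / mL.
#' @param diameter_mm Orifice diameter for `"orifice_sinusoid"`, mm.
#' @param a_mbar,b_mL Ellipse semi-axes.
#' @return A list with `data` (tibble: `t_s`, `p_mbar`, `V_mL`),
#'   `expected_wob_J` (per cycle) and `kind`.
#' @examples
#' fx <- generate_pv_fixture("ellipse", a_mbar = 10, b_mL = 17.5)
#' fx$expected_wob_J  # pi * 10 * 17.5 / 2 * 1e-4
#' @export
generate_pv_fixture <- function(kind = c("linear_sinusoid", "ellipse",
                                         "orifice_sinusoid", "flat"),
                                cycles = 10, samples_per_cycle = 500,
                                rate = 44, tidal_volume = 35, v_min = 30,
                                r_lin = 0.01, diameter_mm = 2.64,
                                a_mbar = 10, b_mL = 17.5) {
  kind <- match.arg(kind)
  if (samples_per_cycle < 50) {
    stop("need at least 50 samples per cycle", call. = FALSE)
  }
  if (cycles < 1) stop("need at least one cycle", call. = FALSE)
  per <- 60 / rate
  omega <- 2 * pi / per
  n <- as.integer(cycles * samples_per_cycle) + 1L
  t <- seq(0, cycles * per, length.out = n)
  # records start at end-inspiration (full lung), so all volume minima are
  # interior and segmentation drops exactly the leading/trailing half-cycles
  th <- omega * t
  if (kind == "ellipse") {
    v <- v_min + b_mL + b_mL * cos(th)
    p <- a_mbar * sin(th)
    expected <- pi * a_mbar * b_mL / 2 * 1e-4
  } else {
    v <- v_min + tidal_volume / 2 * (1 + cos(th))
    q <- -tidal_volume / 2 * omega * sin(th)
    if (kind == "flat") {
      p <- rep(0, n)
      expected <- 0
    } else if (kind == "linear_sinusoid") {
      p <- -r_lin * q
      expected <- wob_linear_closed_form(r_lin, tidal_volume, rate)
    } else {
      orf <- orifice_element(diameter_mm)
      p <- -element_dp(orf, q)
      expected <- wob_orifice_closed_form(orf$k_quad, tidal_volume, rate)
    }
  }
  list(data = tibble::tibble(t_s = t, p_mbar = p, V_mL = v),
       expected_wob_J = expected, kind = kind)
}
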