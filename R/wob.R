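#' Segment a pressure-volume record into breath cycles
#'
#' Cycles are delimited by successive local minima of the volume channel
#' (end-expiration convention) after light moving-average smoothing;
#' partial leading and trailing cycles are discarded.
#'
#' @param data A data frame with at least a time column and a volume
#'   column (`t_s` and `V_mL` by default, as written by the simulator).
#' @param time,volume Column names (strings) of the time and volume
#'   channels.
#' @param smooth_window Moving-average window (samples, odd); default
#'   chosen from the record length.
#' @return A tibble with one row per complete cycle: `cycle`,
#'   `start_idx`, `end_idx` (row indices into `data`, inclusive, minimum
#'   to next minimum), `t_start`, `t_end`.
#' @examples
#' rec <- generate_pv_fixture("linear_sinusoid", cycles = 5)$data
#' segment_breaths(rec)
#' @export
segment_breaths <- function(data, time = "t_s", volume = "V_mL",
                            smooth_window = NULL) {
  check_columns(data, c(time, volume))
  t <- data[[time]]
  v <- data[[volume]]
  if (is.unsorted(t, strictly = TRUE)) {
    stop("time channel must be strictly increasing", call. = FALSE)
  }
  n <- length(v)
  if (is.null(smooth_window)) {
    smooth_window <- max(3L, as.integer(n / 200) * 2L + 1L)
  }
  if (smooth_window %% 2 == 0) smooth_window <- smooth_window + 1L
  vs <- if (smooth_window >= 3 && n > smooth_window) {
    stats::filter(v, rep(1 / smooth_window, smooth_window), sides = 2)
  } else v
  vs <- as.numeric(vs)
  # interior local minima (first index of any flat run)
  interior <- 2:(n - 1)
  cond <- vs[interior] <= vs[interior - 1] & vs[interior] < vs[interior + 1]
  cond[is.na(cond)] <- FALSE
  cand <- interior[cond]
  # collapse runs of adjacent candidates (flat minima) to their first index
  if (length(cand) > 1) {
    keep <- c(TRUE, diff(cand) > 1)
    cand <- cand[keep]
  }
  if (length(cand) < 2) {
    stop("record does not span two volume minima; cannot segment breaths",
         call. = FALSE)
  }
  tibble::tibble(
    cycle = seq_len(length(cand) - 1),
    start_idx = cand[-length(cand)],
    end_idx = cand[-1],
    t_start = t[cand[-length(cand)]],
    t_end = t[cand[-1]]
  )
}

# trapezoidal p-v work of one cycle (rows of a single cycle, in order):
# inspiratory work against sub-ambient pressure, expiratory work against
# positive pressure, and peak negative pressure magnitude.
# 1 mbar mL = 1e-4 J exactly.
pv_cycle_work <- function(cycle_data, pressure = "p_mbar",
                          volume = "V_mL") {
  p <- cycle_data[[pressure]]
  v <- cycle_data[[volume]]
  dv <- diff(v)
  pm <- (p[-1] + p[-length(p)]) / 2
  insp <- dv > 0 & pm < 0
  exh <- dv < 0 & pm > 0
  list(
    work_J = sum(-pm[insp] * dv[insp]) * 1e-4,
    work_exhale_J = sum(pm[exh] * (-dv[exh])) * 1e-4,
    peak_neg_p_mbar = max(0, -min(p))
  )
}

#' Work of breathing from a pressure-volume record
#'
#' For each complete breath cycle, computes the area on the negative side
#' of the p-v diagram: the trapezoidal integral of `-p dV` over the
#' inspiratory limb (`dV > 0`) restricted to sub-ambient pressure
#' (`p < 0`), converted with 1 mbar mL = 1e-4 J. This is the headline
#' work of breathing; work done against positive pressure during
#' exhalation is reported separately.
#'
#' @inheritParams segment_breaths
#' @param pressure Name of the pressure column (mbar, relative to
#'   ambient).
#' @param cycles Optional cycle table from [segment_breaths()]; computed
#'   from the record if omitted.
#' @return A tibble with one row per cycle: `cycle`, `work_J`,
#'   `work_mJ`, `work_exhale_J`, `peak_neg_p_mbar`, `t_start`, `t_end`.
#' @examples
#' rec <- generate_pv_fixture("linear_sinusoid", cycles = 5)$data
#' wob_cycles(rec)
#' @export
wob_cycles <- function(data, time = "t_s", pressure = "p_mbar",
                       volume = "V_mL", cycles = NULL) {
  check_columns(data, c(time, pressure, volume))
  if (is.null(cycles)) {
    cycles <- segment_breaths(data, time = time, volume = volume)
  }
  res <- purrr::map(seq_len(nrow(cycles)), function(k) {
    rows <- cycles$start_idx[k]:cycles$end_idx[k]
    pv_cycle_work(data[rows, , drop = FALSE], pressure, volume)
  })
  tibble::tibble(
    cycle = cycles$cycle,
    work_J = purrr::map_dbl(res, "work_J"),
    work_mJ = 1000 * purrr::map_dbl(res, "work_J"),
    work_exhale_J = purrr::map_dbl(res, "work_exhale_J"),
    peak_neg_p_mbar = purrr::map_dbl(res, "peak_neg_p_mbar"),
    t_start = cycles$t_start,
    t_end = cycles$t_end
  )
}

#' Scale per-cycle work to work per minute
#'
#' @param work_per_cycle_J Work per breath, J (non-negative).
#' @param rate Breathing rate, breaths per minute (non-negative).
#' @return Work per minute, J/min (the product).
#' @examples
#' wob_per_minute(2.22e-3, 44)
#' @export
wob_per_minute <- function(work_per_cycle_J, rate) {
  if (any(work_per_cycle_J < 0) || any(rate < 0)) {
    stop("work and rate must be non-negative", call. = FALSE)
  }
  work_per_cycle_J * rate
}

#' Summarise work of breathing over a whole record
#'
#' Mean per-cycle work, its per-minute scaling at the rate implied by the
#' mean cycle duration (or a supplied rate), and the worst peak negative
#' pressure.
#'
#' @inheritParams wob_cycles
#' @param rate Breathing rate, breaths/min; if `NULL`, inferred from the
#'   mean cycle duration.
#' @return A one-row tibble: `n_cycles`, `mean_work_J`, `rate_bpm`,
#'   `wob_J_min`, `peak_neg_p_mbar`.
#' @export
wob_summary <- function(data, time = "t_s", pressure = "p_mbar",
                        volume = "V_mL", rate = NULL) {
  cyc <- wob_cycles(data, time = time, pressure = pressure, volume = volume)
  if (is.null(rate)) rate <- 60 / mean(cyc$t_end - cyc$t_start)
  tibble::tibble(
    n_cycles = nrow(cyc),
    mean_work_J = mean(cyc$work_J),
    rate_bpm = rate,
    wob_J_min = wob_per_minute(mean(cyc$work_J), rate),
    peak_neg_p_mbar = max(cyc$peak_neg_p_mbar)
  )
}

#' Closed-form work for a linear resistance and sinusoidal tidal driver
#'
#' For volume `V(t)` sinusoidal with tidal volume `V_T` at angular
#' frequency `omega` through a linear resistance `R`, the inspiratory
#' work against sub-ambient pressure is `pi R omega V_T^2 / 8` in
#' mbar mL, i.e. times 1e-4 in J. Used as an independent oracle for the
#' trapezoidal integrator.
#'
#' @param r_lin Linear resistance, mbar s / mL.
#' @param tidal_volume Tidal volume, mL.
#' @param rate Breaths per minute.
#' @return Work per breath, J.
#' @examples
#' wob_linear_closed_form(0.01, 35, 44)  # 2.22e-3 J
#' @export
wob_linear_closed_form <- function(r_lin, tidal_volume = 35, rate = 44) {
  omega <- 2 * pi * rate / 60
  pi * r_lin * omega * tidal_volume^2 / 8 * 1e-4
}

#' Closed-form work for a quadratic orifice and sinusoidal tidal driver
#'
#' With `dP = K Q |Q|` and peak flow `Q0 = V_T omega / 2`, the
#' inspiratory work is `K Q0^3 (4/3) / omega` in mbar mL.
#'
#' @param k_quad Quadratic coefficient, mbar / (mL/s)^2 (the orifice
#'   element's `k_quad`).
#' @inheritParams wob_linear_closed_form
#' @return Work per breath, J.
#' @export
wob_orifice_closed_form <- function(k_quad, tidal_volume = 35, rate = 44) {
  omega <- 2 * pi * rate / 60
  q0 <- tidal_volume * omega / 2
  k_quad * q0^3 * (4 / 3) / omega * 1e-4
}
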