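#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a breathing simulation
#'
#' @param x A `breath_sim` from [run_simulation()].
#' @param what `"trace"` (default) for the time-series grid, `"breaths"`
#'   for the per-breath table.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.breath_sim <- function(x, what = c("trace", "breaths"), ...) {
  what <- match.arg(what)
  if (what == "trace") x$trace else x$breaths
}

#' One-row equilibrium summary of a breathing simulation
#'
#' @param x A `breath_sim`.
#' @param ... Unused.
#' @return A one-row tibble: equilibrium lung CO2 and O2 (vol%), etCO2
#'   (mm Hg, dry convention at 760 mm Hg), WOB (J/min, inspiratory
#'   negative-side; exhalation-side reported separately), work per cycle
#'   (J), peak negative circuit pressure (mbar), breaths to equilibrium,
#'   breaths run, converged flag.
#' @export
glance.breath_sim <- function(x, ...) {
  tibble::as_tibble(x$summary)
}

#' Plot a breathing simulation
#'
#' @param object A `breath_sim`.
#' @param type `"timeseries"` for pressure/volume/CO2 against time,
#'   `"pv"` for the pressure-volume loop of the final breath.
#' @param breaths For `"timeseries"`, how many trailing breaths to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.breath_sim <- function(object, type = c("timeseries", "pv"),
                                breaths = 5, ...) {
  type <- match.arg(type)
  per <- object$config$pattern$period
  tr <- object$trace
  if (type == "pv") {
    t_max <- max(tr$t_s)
    last <- tr[tr$t_s >= t_max - per + 1e-9, ]
    ggplot2::ggplot(last, ggplot2::aes(x = .data$p_mbar, y = .data$V_mL)) +
      ggplot2::geom_path() +
      ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
      ggplot2::labs(x = "circuit pressure (mbar)", y = "lung volume (mL)",
                    title = "Pressure-volume loop (final breath)")
  } else {
    t_max <- max(tr$t_s)
    win <- tr[tr$t_s >= t_max - breaths * per, ]
    long <- tidyr::pivot_longer(
      win[, c("t_s", "V_mL", "p_mbar", "lung_fCO2")],
      cols = -"t_s", names_to = "channel", values_to = "value")
    ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s, y = .data$value)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
      ggplot2::labs(x = "time (s)", y = NULL)
  }
}

#' Plot a series result
#'
#' Work of breathing and equilibrium lung CO2 side by side across the
#' conditions of a test series, mirroring the bench summary figures.
#'
#' @param object A `series_result` from [run_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.series_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$condition <- factor(paste(df$resistance, df$storage, sep = " / "),
                         levels = unique(paste(df$resistance, df$storage,
                                               sep = " / ")))
  long <- tidyr::pivot_longer(df[, c("condition", "wob_J_min", "co2_pct")],
                              cols = -"condition",
                              names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric, levels = c("wob_J_min", "co2_pct"),
                        labels = c("WOB (J/min)", "lung CO2 (vol%)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition,
                                     y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL)
}
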