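#' Run one resistance x storage condition
#'
#' Builds the bench-default configuration for a named condition (open
#' tube or tube + orifice; a polyfill layer count) and runs it to
#' equilibrium.
#'
#' @param diameter_mm Orifice diameter, mm, or `NA` for the open tube
#'   alone.
#' @param layers Polyfill layers (0 for no storage medium).
#' @param ... Passed to [sim_config()] (e.g. `max_breaths`, `timestep`).
#' @return A one-row tibble of condition labels and equilibrium metrics
#'   (the columns of a series result, see [run_series()]).
#' @export
run_condition <- function(diameter_mm = NA, layers = 0, ...) {
  elements <- list(tube_element())
  if (!is.na(diameter_mm)) {
    elements <- c(elements, list(orifice_element(diameter_mm)))
  }
  cfg <- sim_config(
    airway = do.call(airway, elements),
    storage = polyfill_storage(layers),
    ...
  )
  sim <- run_simulation(cfg)
  s <- sim$summary
  tibble::tibble(
    resistance = if (is.na(diameter_mm)) "open tube"
                 else sprintf("%.2f mm orifice", diameter_mm),
    diameter_mm = diameter_mm,
    storage = if (layers == 0) "none"
              else if (layers >= 8) "wrapped"
              else sprintf("%d layers", as.integer(layers)),
    layers = layers,
    co2_pct = s$co2_pct,
    o2_pct = s$o2_pct,
    etco2_mmHg = s$etco2_mmHg,
    wob_J_min = s$wob_J_min,
    peak_neg_p_mbar = s$peak_neg_p_mbar,
    breaths_to_equilibrium = s$breaths_to_equilibrium,
    converged = s$converged
  )
}

run_condition_grid <- function(grid, ...) {
  rows <- purrr::pmap(grid[, c("diameter_mm", "layers")],
                      run_condition, ...)
  dplyr::bind_rows(rows)
}

#' The bench test series: resistance, storage, and their combination
#'
#' Reproduces the three test series of the bench study with the
#' paper-default driver and source:
#' \describe{
#'   \item{Series 1 (airflow resistance)}{open tube plus the five
#'     orifices (4.03, 3.25, 2.64, 1.93, 1.07 mm), no storage medium.
#'     Expected: work of breathing rises steeply as the diameter shrinks
#'     while equilibrium lung CO2 stays put.}
#'   \item{Series 2 (gas storage)}{open tube with a polyfill layer
#'     ladder (0, 1, 2, 4, 8 layers). Expected: equilibrium CO2 climbs
#'     with each layer while WOB barely moves.}
#'   \item{Series 3 (combination)}{the 3 x 3 grid of \{open tube,
#'     3.25 mm, 1.93 mm\} x \{2 layers, 4 layers, wrapped\}. Expected:
#'     the two effects are summative.}
#' }
#' Series 1 and 2 are one-dimensional slices of the same
#' condition-grid code path used for series 3.
#'
#' @param series Which series to run: 1, 2 or 3.
#' @param check If `TRUE` (default), evaluate the series' trend
#'   assertions and raise an error naming any violated trend.
#' @param series1_wob_range For series 2's "slight WOB increase" check:
#'   the series-1 WOB range (J/min) to compare against; computed by
#'   running series 1 when `NULL` and `check = TRUE`.
#' @param layers Layer ladder for series 2.
#' @param ... Passed on to [sim_config()].
#' @return A tibble with one row per condition (`resistance`,
#'   `diameter_mm`, `storage`, `layers`, `co2_pct`, `o2_pct`,
#'   `etco2_mmHg`, `wob_J_min`, `peak_neg_p_mbar`,
#'   `breaths_to_equilibrium`, `converged`), of class `series_result`,
#'   with the assertion table in `attr(, "assertions")` when checked.
#' @examples
#' \donttest{
#' s1 <- run_series(1)
#' attr(s1, "assertions")
#' }
#' @export
run_series <- function(series, check = TRUE, series1_wob_range = NULL,
                       layers = c(0, 1, 2, 4, 8), ...) {
  stopifnot(series %in% 1:3)
  orifices <- c(4.03, 3.25, 2.64, 1.93, 1.07)
  grid <- switch(as.character(series),
    "1" = tibble::tibble(diameter_mm = c(NA, orifices), layers = 0),
    "2" = tibble::tibble(diameter_mm = NA, layers = layers),
    "3" = tidyr::expand_grid(diameter_mm = c(NA, 3.25, 1.93),
                             layers = c(2, 4, 8))
  )
  res <- run_condition_grid(grid, ...)
  res <- structure(res, series = series,
                   class = c("series_result", class(res)))
  if (check) {
    checks <- check_series(res, series1_wob_range = series1_wob_range, ...)
    attr(res, "assertions") <- checks
    if (any(!checks$pass)) {
      stop("series ", series, " trend assertion(s) violated: ",
           paste(checks$assertion[!checks$pass], collapse = "; "),
           call. = FALSE)
    }
  }
  res
}

#' @rdname run_series
#' @export
run_series_1 <- function(...) run_series(1, ...)

#' @rdname run_series
#' @export
run_series_2 <- function(...) run_series(2, ...)

#' @rdname run_series
#' @export
run_series_3 <- function(...) run_series(3, ...)

#' Evaluate the trend assertions of a series result
#'
#' Operationalizes the qualitative bench findings as numeric checks:
#' series 1 — WOB strictly increasing with decreasing orifice diameter
#' and equilibrium CO2 spread at most `co2_spread_max` vol%; series 2 —
#' CO2 strictly increasing along the layer ladder with the WOB spread at
#' most `wob_frac_max` of the series-1 WOB range; series 3 — CO2
#' non-decreasing along the storage axis at fixed resistance, WOB
#' non-decreasing along the resistance axis at fixed storage, and
#' resistance/storage additivity of WOB within `additivity_tol`.
#'
#' @param res A `series_result` from [run_series()].
#' @param co2_spread_max Series-1 CO2 spread bound, vol% absolute.
#' @param wob_frac_max Series-2 WOB spread bound, as a fraction of the
#'   series-1 WOB range.
#' @param additivity_tol Series-3 relative additivity band.
#' @inheritParams run_series
#' @return A tibble: `assertion`, `pass`, `value`.
#' @export
check_series <- function(res, series1_wob_range = NULL,
                         co2_spread_max = 0.1, wob_frac_max = 0.2,
                         additivity_tol = 0.1, ...) {
  series <- attr(res, "series")
  out <- list()
  add <- function(name, pass, value) {
    out[[length(out) + 1]] <<- tibble::tibble(
      assertion = name, pass = pass, value = value)
  }
  if (series == 1) {
    add("row count is 6 (open tube + 5 orifices)", nrow(res) == 6,
        nrow(res))
    add("WOB strictly increasing as diameter decreases",
        !is.unsorted(res$wob_J_min, strictly = TRUE),
        min(diff(res$wob_J_min)))
    spread <- max(res$co2_pct) - min(res$co2_pct)
    add(sprintf("equilibrium CO2 spread <= %.2g vol%%", co2_spread_max),
        spread <= co2_spread_max, spread)
    add("all conditions converged", all(res$converged),
        sum(res$converged))
  } else if (series == 2) {
    add("CO2 strictly increasing with layers",
        !is.unsorted(res$co2_pct, strictly = TRUE), min(diff(res$co2_pct)))
    add("O2 non-increasing with layers",
        all(diff(res$o2_pct) <= 1e-9), max(diff(res$o2_pct)))
    if (is.null(series1_wob_range)) {
      s1 <- run_series(1, check = FALSE, ...)
      series1_wob_range <- max(s1$wob_J_min) - min(s1$wob_J_min)
    }
    frac <- (max(res$wob_J_min) - min(res$wob_J_min)) / series1_wob_range
    add(sprintf("WOB spread <= %.2g of series-1 WOB range", wob_frac_max),
        frac <= wob_frac_max, frac)
    add("all conditions converged", all(res$converged),
        sum(res$converged))
  } else {
    add("row count is 9 (3 x 3 grid)", nrow(res) == 9, nrow(res))
    co2_mono <- res |>
      dplyr::group_by(.data$resistance) |>
      dplyr::summarise(ok = all(diff(.data$co2_pct[order(.data$layers)])
                                >= -1e-9)) |>
      dplyr::pull("ok")
    add("CO2 non-decreasing along storage axis", all(co2_mono),
        sum(co2_mono))
    wob_mono <- res |>
      dplyr::group_by(.data$layers) |>
      dplyr::summarise(ok = all(diff(.data$wob_J_min[order(
        -dplyr::coalesce(.data$diameter_mm, Inf))]) >= -1e-9)) |>
      dplyr::pull("ok")
    add("WOB non-decreasing along resistance axis", all(wob_mono),
        sum(wob_mono))
    # additivity: WOB(r, s) vs WOB(r, s_min) + [WOB(open, s) - WOB(open, s_min)]
    s_min <- min(res$layers)
    res2 <- dplyr::mutate(res,
                          rkey = dplyr::coalesce(.data$diameter_mm, Inf))
    base_r <- res2 |>
      dplyr::filter(.data$layers == s_min) |>
      dplyr::select("rkey", base_wob = "wob_J_min")
    open_s <- res2 |>
      dplyr::filter(is.infinite(.data$rkey)) |>
      dplyr::select("layers", open_wob = "wob_J_min")
    base_open <- open_s$open_wob[open_s$layers == s_min]
    joined <- res2 |>
      dplyr::left_join(base_r, by = "rkey") |>
      dplyr::left_join(open_s, by = "layers") |>
      dplyr::mutate(pred = .data$base_wob + .data$open_wob - base_open,
                    rel = abs(.data$wob_J_min - .data$pred) /
                      .data$wob_J_min)
    rel_err <- joined$rel
    add(sprintf("WOB additivity within %.0f%%", 100 * additivity_tol),
        all(rel_err <= additivity_tol), max(rel_err))
    add("all conditions converged", all(res$converged),
        sum(res$converged))
  }
  dplyr::bind_rows(out)
}

#' Write a series result as CSV plus an assertion log
#'
#' Writes the condition table to `path` (numeric columns at 10
#' significant digits) and, when the result carries an assertion table,
#' a human-readable pass/fail log to `paste0(path, ".log")`.
#'
#' @param res A `series_result` (or any data frame of conditions).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_report <- function(res, path) {
  write_pv_csv(as.data.frame(res), path)
  checks <- attr(res, "assertions")
  if (!is.null(checks)) {
    lines <- c(
      sprintf("series %s assertion report", attr(res, "series")),
      sprintf("[%s] %s (value = %.6g)",
              ifelse(checks$pass, "PASS", "FAIL"),
              checks$assertion, checks$value)
    )
    writeLines(lines, paste0(path, ".log"))
  }
  invisible(path)
}
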