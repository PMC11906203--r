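# column check shared by readers and the WOB entry points
check_columns <- function(data, needed,
                          accepted = c("t_s", "p_mbar", "V_mL", "Q_mL_s",
                                       "lung_fCO2", "lung_fO2",
                                       "storage_fCO2")) {
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    stop("missing column(s): ", paste(missing, collapse = ", "),
         "; accepted column names are: ", paste(accepted, collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a pressure-volume record from CSV
#'
#' Header-keyed (column order does not matter); requires columns `t_s`,
#' `p_mbar`, `V_mL`; extra columns such as the simulator's `Q_mL_s` and
#' fraction channels are kept. Time must be strictly increasing.
#'
#' @param path Path to a comma-separated file with a header row.
#' @return A tibble.
#' @export
read_pv_csv <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(data, c("t_s", "p_mbar", "V_mL"))
  if (is.unsorted(data$t_s, strictly = TRUE)) {
    stop("time column t_s must be strictly increasing", call. = FALSE)
  }
  data
}

#' Write a pressure-volume record (or any numeric table) to CSV
#'
#' Numeric columns are serialized with 10 significant digits, enough for a
#' lossless round-trip at 1e-9 relative precision.
#'
#' @param data A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pv_csv <- function(data, path) {
  out <- dplyr::mutate(data, dplyr::across(dplyr::where(is.numeric),
                                           ~ signif(.x, 10)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a simulation trace in the canonical column layout
#'
#' Columns exactly `t_s, V_mL, p_mbar, Q_mL_s, lung_fCO2, lung_fO2,
#' storage_fCO2`.
#'
#' @param sim A `breath_sim` from [run_simulation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_csv <- function(sim, path) {
  stopifnot(inherits(sim, "breath_sim"))
  cols <- c("t_s", "V_mL", "p_mbar", "Q_mL_s",
            "lung_fCO2", "lung_fO2", "storage_fCO2")
  write_pv_csv(sim$trace[, cols], path)
}
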