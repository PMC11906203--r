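#' Load a simulation configuration from a YAML file
#'
#' Plain-text structured configuration with nested sections `lung`,
#' `airway`, `storage`, `pattern`, `source`, `ambient` and `numerics`;
#' any omitted field falls back to the bench-model default (44 breaths
#' per minute, 35 mL tidal volume between 30 and 65 mL, 0.7 mL/mbar
#' compliance, open 300 x 5 mm tube, calibrated metabolic source, no
#' storage). Unknown keys and out-of-range values raise errors naming the
#' offending field. An empty (or missing-section) file yields the full
#' default configuration.
#'
#' Recognised keys:
#' \preformatted{
#' lung:     compliance, v_min, v_max
#' airway:   tube: {length_mm, diameter_mm, viscosity}  (or tube: none)
#'           orifice: {diameter_mm, discharge_coefficient, air_density}
#' storage:  layers                       # polyfill preset, or:
#'           storage_volume, entrainment, retention, resistance
#' pattern:  rate, tidal_volume, waveform, rise_fraction
#' source:   co2_mL_min, rq, o2_mL_min, volume_mode
#' ambient:  f_co2, f_o2
#' numerics: timestep, max_breaths, eq_tol
#' }
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A validated [sim_config()].
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known_sections <- c("lung", "airway", "storage", "pattern", "source",
                      "ambient", "numerics")
  check_keys(raw, known_sections, "top level")

  lg <- section(raw, "lung", c("compliance", "v_min", "v_max"))
  lung <- compliant_lung(
    compliance = lg$compliance %||% 0.7,
    v_min = lg$v_min %||% 30,
    v_max = lg$v_max %||% 65
  )

  aw_raw <- section(raw, "airway", c("tube", "orifice"))
  elements <- list()
  tube_spec <- if ("tube" %in% names(aw_raw)) aw_raw$tube else list()
  if (!identical(tube_spec, "none")) {
    check_keys(tube_spec, c("length_mm", "diameter_mm", "viscosity"),
               "airway$tube")
    elements <- c(elements, list(tube_element(
      length_mm = tube_spec$length_mm %||% 300,
      diameter_mm = tube_spec$diameter_mm %||% 5,
      viscosity = tube_spec$viscosity %||% 1.81e-5
    )))
  }
  if (!is.null(aw_raw$orifice)) {
    check_keys(aw_raw$orifice,
               c("diameter_mm", "discharge_coefficient", "air_density"),
               "airway$orifice")
    if (is.null(aw_raw$orifice$diameter_mm)) {
      stop("config field airway$orifice$diameter_mm is required",
           call. = FALSE)
    }
    elements <- c(elements, list(orifice_element(
      diameter_mm = aw_raw$orifice$diameter_mm,
      discharge_coefficient = aw_raw$orifice$discharge_coefficient %||% 0.6,
      air_density = aw_raw$orifice$air_density %||% 1.2
    )))
  }
  if (length(elements) == 0) {
    stop("config airway must contain at least one element", call. = FALSE)
  }
  aw <- do.call(airway, elements)

  st_raw <- section(raw, "storage",
                    c("layers", "storage_volume", "entrainment",
                      "retention", "resistance"))
  storage <- if (length(st_raw) == 0) {
    NULL
  } else if (!is.null(st_raw$layers)) {
    extra <- setdiff(names(st_raw), c("layers", "retention"))
    if (length(extra) > 0) {
      stop("config storage: 'layers' preset cannot be combined with: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    polyfill_storage(st_raw$layers,
                     retention = st_raw$retention %||% 0.5)
  } else {
    storage_compartment(
      storage_volume = st_raw$storage_volume %||%
        stop("config storage needs 'layers' or 'storage_volume'",
             call. = FALSE),
      entrainment = st_raw$entrainment %||% 1,
      retention = st_raw$retention %||% 0.5,
      resistance = st_raw$resistance %||% 0
    )
  }

  pt <- section(raw, "pattern",
                c("rate", "tidal_volume", "waveform", "rise_fraction"))
  pattern <- breathing_pattern(
    rate = pt$rate %||% 44,
    tidal_volume = pt$tidal_volume %||% (lung$v_max - lung$v_min),
    waveform = pt$waveform %||% "sinusoid",
    rise_fraction = pt$rise_fraction %||% 0.25
  )

  sr <- section(raw, "source",
                c("co2_mL_min", "rq", "o2_mL_min", "volume_mode"))
  rq <- sr$rq %||% 0.8
  co2 <- sr$co2_mL_min %||% (0.044 * pattern$tidal_volume * pattern$rate)
  source <- metabolic_source(
    co2_mL_min = co2, rq = rq,
    o2_mL_min = sr$o2_mL_min %||% (co2 / rq),
    volume_mode = sr$volume_mode %||% "neutral"
  )

  am <- section(raw, "ambient", c("f_co2", "f_o2"))
  ambient <- gas_mixture(f_co2 = am$f_co2 %||% 0.0004,
                         f_o2 = am$f_o2 %||% 0.21)

  nm <- section(raw, "numerics", c("timestep", "max_breaths", "eq_tol"))
  sim_config(lung = lung, airway = aw, storage = storage,
             pattern = pattern, source = source, ambient = ambient,
             timestep = nm$timestep %||% NULL,
             max_breaths = nm$max_breaths %||% 1000,
             eq_tol = nm$eq_tol %||% 1e-4)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

check_keys <- function(x, allowed, where) {
  if (!is.list(x)) {
    if (is.null(x) || identical(x, "none")) return(invisible(TRUE))
    stop("config section '", where, "' must be a mapping", call. = FALSE)
  }
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    stop("unknown config key(s) in ", where, ": ",
         paste(unknown, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

section <- function(raw, name, allowed) {
  x <- raw[[name]]
  if (is.null(x)) return(list())
  check_keys(x, allowed, name)
  x
}
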