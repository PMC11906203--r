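# shared fixtures: small, fast configurations built in code

quick_config <- function(layers = 0, diameter_mm = NA, max_breaths = 200,
                         ...) {
  elements <- list(tube_element())
  if (!is.na(diameter_mm)) {
    elements <- c(elements, list(orifice_element(diameter_mm)))
  }
  sim_config(airway = do.call(airway, elements),
             storage = polyfill_storage(layers),
             max_breaths = max_breaths, ...)
}

# injection per breath at the default calibrated source, mL
default_injection_per_breath <- function() (0.044 * 35 * 44) / 44
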