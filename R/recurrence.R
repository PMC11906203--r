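#' Analytic per-breath steady state of the rebreathing model
#'
#' Closed-form reduction of the simulator's mass balance to a linear
#' two-state per-breath map on (lung composition, storage composition),
#' per gas species. One breath does, in order: inhale one tidal volume as
#' the entrainment-weighted blend of stored and ambient gas into the
#' well-mixed lung (plus the per-breath metabolic source), exhale one
#' tidal volume at the mixed lung fraction into the storage compartment
#' (volume-weighted, overflow vented), then apply the inter-breath
#' washout. The fixed point is obtained by a direct 2x2 linear solve; it
#' exists iff the map's spectral radius is below one (it reaches one when
#' entrainment and retention are both 1 with storage at least one tidal
#' volume: zero net CO2 export, unbounded accumulation).
#'
#' With the volume-neutral metabolic source this fixed point coincides
#' with [run_simulation()]'s equilibrium exactly (up to time
#' discretization), which makes it the engine's independent oracle. In
#' the fresh-air limit (no storage) the exhaled CO2 fraction is exactly
#' `ambient + injection_per_breath / tidal_volume`.
#'
#' @param storage_volume Storage volume, mL (0 for none).
#' @param entrainment,retention Storage parameters beta and a, see
#'   [storage_compartment()].
#' @param tidal_volume Tidal volume, mL.
#' @param frc End-expiratory (residual) lung volume, mL.
#' @param rate Breaths per minute.
#' @param source A [metabolic_source()].
#' @param ambient Ambient gas.
#' @return A one-row tibble: `lung_fCO2` and `lung_fO2` (exhaled mean
#'   fractions at steady state), `storage_fCO2`, `storage_fO2`, and a
#'   `bounded` flag (`FALSE` when no fixed point exists; fractions are
#'   then `NA`).
#' @examples
#' breath_steady_state()                       # fresh-air limit
#' breath_steady_state(storage_volume = 40)    # wrapped-equivalent
#' @export
breath_steady_state <- function(storage_volume = 0, entrainment = 1,
                                retention = 0.5, tidal_volume = 35,
                                frc = 30, rate = 44,
                                source = metabolic_source(),
                                ambient = fresh_air()) {
  amb <- unclass(ambient)
  per_breath <- c(source$co2_mL_min, -source$o2_mL_min) / rate
  fp <- lapply(1:2, function(sp) {
    species_fixed_point(storage_volume, entrainment, retention,
                        tidal_volume, frc, amb[sp], per_breath[sp])
  })
  bounded <- fp[[1]]$bounded && fp[[2]]$bounded
  tibble::tibble(
    lung_fCO2 = if (bounded) fp[[1]]$lung else NA_real_,
    lung_fO2 = if (bounded) max(0, fp[[2]]$lung) else NA_real_,
    storage_fCO2 = if (bounded) fp[[1]]$storage else NA_real_,
    storage_fO2 = if (bounded) max(0, fp[[2]]$storage) else NA_real_,
    bounded = bounded
  )
}

# per-species linear map and fixed point; state x = (lung end-expiratory
# fraction, storage fraction), source s in mL/breath
species_map <- function(storage_volume, entrainment, retention,
                        tidal_volume, frc, amb_f, s) {
  vt <- tidal_volume
  v_s <- storage_volume
  beta <- if (v_s > 0) min(entrainment, v_s / vt) else 0
  a <- if (v_s > 0) retention else 0
  # i = beta g + (1-beta) amb ; f = (frc l + vt i + s)/(frc + vt)
  cf_l <- frc / (frc + vt)
  cf_g <- vt * beta / (frc + vt)
  cf_0 <- (vt * (1 - beta) * amb_f + s) / (frc + vt)
  if (v_s > 0) {
    drawn <- beta * vt
    keep <- v_s - drawn
    vol_new <- keep + vt
    # gm = (keep g + vt f)/vol_new ; g' = amb + a (gm - amb)
    m21 <- a * (vt / vol_new) * cf_l
    m22 <- a * (keep / vol_new + (vt / vol_new) * cf_g)
    c2 <- a * ((vt / vol_new) * cf_0) + (1 - a) * amb_f
  } else {
    m21 <- 0; m22 <- 0; c2 <- amb_f
  }
  list(M = matrix(c(cf_l, cf_g, m21, m22), 2, 2, byrow = TRUE),
       offset = c(cf_0, c2))
}

species_fixed_point <- function(storage_volume, entrainment, retention,
                                tidal_volume, frc, amb_f, s) {
  mp <- species_map(storage_volume, entrainment, retention,
                    tidal_volume, frc, amb_f, s)
  rho <- max(Mod(eigen(mp$M, only.values = TRUE)$values))
  if (rho >= 1 - 1e-9) {
    return(list(bounded = FALSE, lung = NA_real_, storage = NA_real_))
  }
  x <- solve(diag(2) - mp$M, mp$offset)
  list(bounded = TRUE, lung = x[1], storage = x[2])
}

#' Iterate the per-breath map explicitly
#'
#' Brute-force iteration of the same per-breath linear map that
#' [breath_steady_state()] solves in closed form, starting from ambient
#' composition. Used as the cross-check that the direct solve and the
#' iterated dynamics agree, and to inspect transients.
#'
#' @inheritParams breath_steady_state
#' @param n_breaths Number of breaths to iterate.
#' @return A tibble with one row per breath: `breath`, `lung_fCO2`,
#'   `storage_fCO2` (the map state after that breath).
#' @export
breath_map_iterate <- function(n_breaths, storage_volume = 0,
                               entrainment = 1, retention = 0.5,
                               tidal_volume = 35, frc = 30, rate = 44,
                               source = metabolic_source(),
                               ambient = fresh_air()) {
  amb <- unclass(ambient)
  s <- source$co2_mL_min / rate
  mp <- species_map(storage_volume, entrainment, retention,
                    tidal_volume, frc, amb[1], s)
  x <- c(amb[1], amb[1])
  out <- matrix(0, n_breaths, 2)
  for (k in seq_len(n_breaths)) {
    x <- as.numeric(mp$M %*% x + mp$offset)
    out[k, ] <- x
  }
  tibble::tibble(breath = seq_len(n_breaths),
                 lung_fCO2 = out[, 1], storage_fCO2 = out[, 2])
}
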