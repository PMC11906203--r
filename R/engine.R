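#' Assemble a simulation configuration
#'
#' Bundles the circuit, driver and source into a validated configuration.
#' The defaults reproduce the bench model's baseline: 0.7 mL/mbar lungs
#' reciprocating 30-65 mL at 44 breaths/min through the open-ended
#' 300 x 5 mm tube, breathing ambient fresh air, with the calibrated
#' metabolic source and no storage medium.
#'
#' @param lung A [compliant_lung()].
#' @param airway An [airway()] chain.
#' @param storage A [storage_compartment()] or `NULL` for none.
#' @param pattern A [breathing_pattern()]; its tidal volume must equal
#'   `lung$v_max - lung$v_min`.
#' @param source A [metabolic_source()].
#' @param ambient Ambient gas, a [gas_mixture()].
#' @param timestep Integration step, s; at most 1/200 of the breath period
#'   (the default gives exactly 200 samples per breath).
#' @param max_breaths Maximum number of breaths to simulate.
#' @param eq_tol Equilibrium tolerance: per-breath change in exhaled CO2
#'   fraction below which (for 5 consecutive breaths) the run is declared
#'   converged.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config()
#' @export
sim_config <- function(lung = compliant_lung(),
                       airway = breathsim::airway(tube_element()),
                       storage = NULL,
                       pattern = breathing_pattern(),
                       source = metabolic_source(),
                       ambient = fresh_air(),
                       timestep = NULL,
                       max_breaths = 1000,
                       eq_tol = 1e-4) {
  stopifnot(inherits(lung, "compliant_lung"),
            inherits(airway, "airway"),
            inherits(pattern, "breathing_pattern"),
            inherits(source, "metabolic_source"),
            inherits(ambient, "gas_mixture"))
  if (!is.null(storage)) stopifnot(inherits(storage, "storage_compartment"))
  vt <- lung$v_max - lung$v_min
  if (abs(pattern$tidal_volume - vt) > 1e-9) {
    stop("pattern tidal_volume (", pattern$tidal_volume,
         " mL) must equal lung v_max - v_min (", vt, " mL)", call. = FALSE)
  }
  period <- pattern$period
  if (is.null(timestep)) timestep <- period / 200
  if (timestep <= 0 || timestep > period / 200 + 1e-12) {
    stop("timestep must be positive and at most period/200 (",
         signif(period / 200, 6), " s) for >= 200 samples per breath",
         call. = FALSE)
  }
  if (max_breaths < 2) stop("max_breaths must be at least 2", call. = FALSE)
  if (eq_tol <= 0) stop("eq_tol must be positive", call. = FALSE)
  structure(list(lung = lung, airway = airway, storage = storage,
                 pattern = pattern, source = source, ambient = ambient,
                 timestep = timestep, max_breaths = max_breaths,
                 eq_tol = eq_tol),
            class = "sim_config")
}

# full airway chain including storage intrinsic resistance
effective_airway <- function(config) {
  if (!is.null(config$storage) && config$storage$resistance > 0) {
    do.call(airway, c(unclass(config$airway),
                      list(resistor_element(config$storage$resistance))))
  } else {
    config$airway
  }
}

#' Run the breathing simulation
#'
#' Time-stepping simulation of prescribed-tidal-volume breathing with
#' species transport, storage exchange, a metabolic gas source and
#' equilibrium detection. Each step advances the prescribed volume,
#' advects species with the airway flow (inhaled gas is the
#' entrainment-weighted blend of stored and ambient gas; exhaled gas
#' accumulates into the storage compartment, overflow vented to ambient),
#' and meters CO2 in / O2 out continuously. At each breath boundary the
#' storage compartment mixes in the exhaled gas, vents its overflow and
#' relaxes toward ambient by the washout retention factor. Circuit
#' pressure is `-dP_airway(Q)`: negative during inhalation, positive
#' during exhalation.
#'
#' The run stops once the per-breath change in exhaled CO2 fraction stays
#' below `eq_tol` for 5 consecutive breaths (see [detect_equilibrium()]),
#' plus `extra_breaths` further breaths, or at `max_breaths`.
#'
#' @param config A [sim_config()].
#' @param extra_breaths Breaths to simulate beyond detected equilibrium
#'   (useful for steady-state conservation audits).
#' @return An object of class `breath_sim` with components
#'   \describe{
#'     \item{trace}{tibble of the uniform time grid: `t_s`, `V_mL`,
#'       `p_mbar`, `Q_mL_s`, `lung_fCO2`, `lung_fO2`, `storage_fCO2`.}
#'     \item{breaths}{per-breath tibble: exhaled mean fractions,
#'       end-exhalation lung fractions, storage composition, injected and
#'       net-vented CO2 volumes.}
#'     \item{summary}{equilibrium summary, see [glance.breath_sim()].}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- run_simulation(sim_config(max_breaths = 60))
#' glance(sim)
#' @export
run_simulation <- function(config, extra_breaths = 0) {
  stopifnot(inherits(config, "sim_config"))
  pat <- config$pattern
  per <- pat$period
  vt <- pat$tidal_volume
  v_min <- config$lung$v_min
  amb <- unclass(config$ambient)
  aw <- effective_airway(config)

  n_half <- ceiling(per / 2 / config$timestep)
  n <- 2L * as.integer(n_half)
  dt <- per / n
  # grid within one breath; volumes/flows are breath-periodic
  tt <- (0:n) * dt
  vv <- pattern_volume(pat, tt, v_min)
  vv[1] <- v_min; vv[n + 1] <- v_min        # exact period endpoints
  qq <- pattern_flow(pat, tt)
  dv <- diff(vv)

  src <- config$source
  r_co2 <- src$co2_mL_min / 60              # mL/s
  r_o2 <- src$o2_mL_min / 60
  neutral <- src$volume_mode == "neutral"
  # airway flow: in neutral mode the source is volume-neutral in the lung,
  # so airway flow is exactly dV/dt; in net mode the metabolic volume
  # imbalance appears as extra airway flow
  net_rate <- if (neutral) 0 else r_co2 - r_o2
  q_air_grid <- qq - net_rate
  p_grid <- -airway_dp(aw, q_air_grid)
  dvol_air <- dv - net_rate * dt

  st <- config$storage
  has_storage <- !is.null(st) && st$storage_volume > 0
  v_s <- if (has_storage) st$storage_volume else 0
  beta_eff <- if (has_storage) min(st$entrainment, v_s / vt) else 0
  retention <- if (has_storage) st$retention else 0
  g <- if (has_storage) unclass(st$gas) else amb

  # lung species volumes (mL): c(co2, o2, bal), sum == lung volume
  lung0 <- unclass(config$lung$gas)
  cl <- lung0 * v_min

  max_b <- config$max_breaths
  trace_list <- vector("list", max_b)
  br_exh_co2 <- br_exh_o2 <- br_end_co2 <- br_end_o2 <-
    br_storage_co2 <- br_inj <- br_vent <- numeric(max_b)
  converged_at <- NA_integer_
  b <- 0L
  remaining_extra <- -1L

  while (b < max_b) {
    b <- b + 1L
    t0 <- (b - 1L) * per
    f_in <- beta_eff * g + (1 - beta_eff) * amb
    ex_species <- c(0, 0, 0)
    vol_ex <- 0
    vol_in <- 0
    inj_b <- 0
    vent_co2 <- 0
    frac_mat <- matrix(0, nrow = n, ncol = 2)

    for (i in seq_len(n)) {
      frac_mat[i, 1] <- cl[1] / sum(cl)
      frac_mat[i, 2] <- cl[2] / sum(cl)
      dva <- dvol_air[i]
      if (dva > 0) {
        cl <- cl + f_in * dva
        vol_in <- vol_in + dva
      } else if (dva < 0) {
        f <- cl / sum(cl)
        out <- f * (-dva)
        cl <- cl - out
        ex_species <- ex_species + out
        vol_ex <- vol_ex - dva
      }
      # metabolic exchange
      d_in <- r_co2 * dt
      d_out <- min(r_o2 * dt, cl[2])
      cl[1] <- cl[1] + d_in
      cl[2] <- cl[2] - d_out
      # balance-gas compensation keeps the source volume-neutral; clamp
      # at zero balance gas (only reachable in unbounded-rebreathing runs
      # where lung CO2 approaches 100%)
      if (neutral) cl[3] <- cl[3] + max(d_out - d_in, -cl[3])
      inj_b <- inj_b + d_in
      if (any(cl < -1e-9)) {
        stop("simulation produced a negative species volume at breath ", b,
             ", step ", i, call. = FALSE)
      }
      cl[cl < 0] <- 0
    }

    # breath-boundary storage exchange and washout
    drawn <- beta_eff * vol_in
    if (has_storage) {
      keep_vol <- v_s - drawn
      sp <- g * keep_vol + ex_species
      vol_new <- keep_vol + vol_ex
      gm <- sp / vol_new
      overflow <- max(0, vol_new - v_s)
      vent_co2 <- vent_co2 + gm[1] * overflow
      # inter-breath washout: excess over ambient decays by retention
      vent_co2 <- vent_co2 + (1 - retention) * (gm[1] - amb[1]) * v_s
      g <- amb + retention * (gm - amb)
    } else {
      vent_co2 <- vent_co2 + ex_species[1]
    }
    ambient_in_co2 <- amb[1] * (1 - beta_eff) * vol_in

    br_exh_co2[b] <- ex_species[1] / vol_ex
    br_exh_o2[b] <- ex_species[2] / vol_ex
    br_end_co2[b] <- cl[1] / sum(cl)
    br_end_o2[b] <- cl[2] / sum(cl)
    br_storage_co2[b] <- if (has_storage) g[1] else NA_real_
    br_inj[b] <- inj_b
    br_vent[b] <- vent_co2 - ambient_in_co2

    trace_list[[b]] <- cbind(t0 + tt[seq_len(n)], frac_mat,
                             if (has_storage) br_storage_co2[b] else NA_real_)

    if (is.na(converged_at)) {
      eq <- detect_equilibrium(br_exh_co2[seq_len(b)], config$eq_tol)
      if (eq$converged) {
        converged_at <- eq$breaths
        remaining_extra <- as.integer(extra_breaths)
      }
    } else {
      remaining_extra <- remaining_extra - 1L
    }
    if (!is.na(converged_at) && remaining_extra <= 0L) break
  }

  n_b <- b
  idx <- seq_len(n_b)
  tr <- do.call(rbind, trace_list[idx])
  n_rows <- nrow(tr)
  per_breath_t <- tr[, 1]
  grid_i <- rep(seq_len(n), n_b)
  trace <- tibble::tibble(
    t_s = per_breath_t,
    V_mL = vv[grid_i],
    p_mbar = p_grid[grid_i],
    Q_mL_s = q_air_grid[grid_i],
    lung_fCO2 = tr[, 2],
    lung_fO2 = tr[, 3],
    storage_fCO2 = tr[, 4]
  )
  breaths <- tibble::tibble(
    breath = idx,
    exhaled_fCO2 = br_exh_co2[idx],
    exhaled_fO2 = br_exh_o2[idx],
    end_fCO2 = br_end_co2[idx],
    end_fO2 = br_end_o2[idx],
    storage_fCO2 = br_storage_co2[idx],
    injected_co2_mL = br_inj[idx],
    net_vented_co2_mL = br_vent[idx]
  )

  converged <- !is.na(converged_at)
  # WOB and pressure metrics from the (breath-invariant) p-v cycle
  cyc <- tibble::tibble(t_s = tt, p_mbar = p_grid, V_mL = vv)
  w <- pv_cycle_work(cyc)
  summary <- list(
    co2_pct = 100 * br_exh_co2[n_b],
    o2_pct = 100 * br_exh_o2[n_b],
    etco2_mmHg = fraction_to_partial_pressure(br_end_co2[n_b]),
    wob_J_min = wob_per_minute(w$work_J, pat$rate),
    wob_exhale_J_min = wob_per_minute(w$work_exhale_J, pat$rate),
    work_per_cycle_J = w$work_J,
    peak_neg_p_mbar = w$peak_neg_p_mbar,
    breaths_to_equilibrium = if (converged) converged_at else NA_integer_,
    breaths_run = n_b,
    converged = converged
  )
  structure(list(trace = trace, breaths = breaths, summary = summary,
                 config = config),
            class = "breath_sim")
}

#' @export
print.breath_sim <- function(x, ...) {
  s <- x$summary
  cat("<breath_sim> ", s$breaths_run, " breaths simulated",
      if (s$converged) paste0(" (equilibrium at breath ",
                              s$breaths_to_equilibrium, ")")
      else " (NOT converged)", "\n", sep = "")
  cat(sprintf("  lung CO2 %.3f vol%% | O2 %.2f vol%% | etCO2 %.1f mm Hg\n",
              s$co2_pct, s$o2_pct, s$etco2_mmHg))
  cat(sprintf("  WOB %.4g J/min | peak negative pressure %.4g mbar\n",
              s$wob_J_min, s$peak_neg_p_mbar))
  invisible(x)
}

#' Detect equilibrium in a per-breath composition trace
#'
#' A trace is declared converged at the first breath `k >= 2` for which
#' the per-breath changes over the trailing window (up to `consecutive`
#' breaths, truncated at the start of the trace) are all below `tol` in
#' absolute value.
#'
#' @param x Numeric vector of per-breath lung (exhaled) CO2 fractions.
#' @param tol Absolute per-breath change tolerance (fraction units).
#' @param consecutive Window length, default 5 breaths.
#' @return A list with `converged` (flag) and `breaths` (first converged
#'   breath index, or `NA`).
#' @export
detect_equilibrium <- function(x, tol = 1e-4, consecutive = 5) {
  if (length(x) < 2) return(list(converged = FALSE, breaths = NA_integer_))
  d <- abs(diff(x))
  ok <- d < tol
  for (k in seq_along(d)) {
    win <- seq(max(1, k - consecutive + 1), k)
    if (all(ok[win])) {
      return(list(converged = TRUE, breaths = k + 1L))
    }
  }
  list(converged = FALSE, breaths = NA_integer_)
}
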