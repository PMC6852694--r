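#' Two-compartment lake simulator for total copper
#'
#' Dynamic mass balance for a completely mixed oxic water column over a
#' single active sediment layer, with instantaneous equilibrium
#' partitioning re-computed every step (operator splitting: a Heun
#' predictor-corrector transport step, with the algebraic equilibrium
#' re-solved at each stage). Transport processes:
#' settling of particulate copper, resuspension of sediment solids,
#' sediment-water diffusive exchange of dissolved copper, burial out of
#' the active layer (at the net solids accumulation rate, keeping the
#' layer thickness constant), washout, and spike / re-dose / continuous
#' loading.
#'
#' All state is tracked per m2 of lake bed, so results are independent of
#' lake area. Negative-mass steps trigger automatic step halving; if the
#' step must fall below 1e-6 d the integration aborts.
#'
#' @param scenario A validated [lake_scenario()], or a `lake_setup` (from
#'   [builtin_scenarios()] / [load_scenario()]) in which case `dose` and
#'   `model` default to the setup's components.
#' @param dose A [metal_dose()].
#' @param model A [partitioning_model()].
#' @param duration_d Simulation length (d), > 0.
#' @param dt_d Integration step (d), > 0. The default 0.01 d changes
#'   reported concentrations by < 0.5 % on halving.
#' @param record_dt_d Output grid spacing (d); defaults to
#'   `max(dt_d, duration_d / 2000)`.
#' @return An object of class `lake_sim` with components:
#'   * `series`: data frame over the output grid with columns `time_d`,
#'     `cw_total_ug_L`, `cw_diss_ug_L`, `log_kd_w`, `sed_ug_m2`,
#'     `pw_diss_ug_L`, `log_kd_s`, `frac_sulfide`;
#'   * `cumulative`: total input and cumulative gross settling, gross
#'     resuspension, net diffusion (signed, positive = into sediment),
#'     washout and burial (ug/m2);
#'   * `final`: final water-column and sediment inventories (ug/m2);
#'   * the inputs (`scenario`, `dose`, `model`, `duration_d`, `dt_d`).
#' @seealso [mass_balance()], [extract_removal_times()],
#'   [run_sensitivity_suite()]
#' @export
simulate_lake <- function(scenario, dose = NULL, model = NULL,
                          duration_d = 365, dt_d = 0.01,
                          record_dt_d = NULL) {
  if (inherits(scenario, "lake_setup") ||
      (is.list(scenario) && !inherits(scenario, "lake_scenario") &&
       all(c("scenario", "dose", "model") %in% names(scenario)))) {
    setup <- scenario
    scenario <- setup$scenario
    dose <- dose %||% setup$dose
    model <- model %||% setup$model
  }
  if (is.null(dose) || is.null(model)) {
    stop("dose and model are required unless a lake_setup is given",
         call. = FALSE)
  }
  validate_scenario(scenario)
  stopifnot(duration_d > 0, dt_d > 0)
  if (identical(dose$mode, "continuous") &&
      !is.finite(scenario$hydraulic_residence_time_d)) {
    stop("continuous dosing requires a finite hydraulic_residence_time_d",
         call. = FALSE)
  }

  # --- precomputed geometry and rate constants (per m2, ug, L, d) -------
  v_w <- scenario$depth_m * 1000                       # water volume, L
  m_kg_L <- scenario$spm_mg_L * 1e-6
  v_s <- scenario$settling_velocity_m_d
  k_f <- scenario$diffusion_mtc_m_d
  tau <- scenario$hydraulic_residence_time_d
  doc <- scenario$doc_mg_L
  m_solids <- sediment_solids_kg_m2(scenario)          # kg solids
  v_pw <- porewater_volume_L_m2(scenario)              # porewater, L
  kd_phase <- phase_kd_L_kg(scenario, model)
  kd_sed_oxic <- if (identical(model$mode, "empirical")) {
    10^model$log_kd_sediment
  } else {
    kd_phase
  }
  anoxic <- identical(scenario$sediment_redox, "anoxic") &&
    scenario$avs_umol_g > 0
  cap_ug <- if (anoxic) {
    scenario$avs_umol_g * 1e-6 * 1000 * m_solids *
      cu_per_avs(model) * CU_MOLAR_MASS * 1e6
  } else {
    0
  }
  pw_floor <- model$sulfide_porewater_ug_L
  settle_solids <- v_s * scenario$spm_mg_L / 1000          # kg/m2/d
  resusp_solids <- scenario$resuspension_velocity_cm_yr / 100 / 365 *
    scenario$sediment_solids_g_Lbulk                       # kg/m2/d
  burial_solids <- max(0, settle_solids - resusp_solids)   # kg/m2/d

  empirical <- identical(model$mode, "empirical")
  kd_w_const <- if (empirical) 10^model$log_kd_water else NA_real_
  fp_const <- if (empirical) {
    particulate_fraction(kd_w_const, scenario$spm_mg_L)
  } else {
    NA_real_
  }

  # water-column equilibrium: total conc -> list(c_diss, kd)
  water_eq <- function(c_tot) {
    if (c_tot <= 0) return(c(0, NA_real_))
    if (empirical) {
      return(c(c_tot * (1 - fp_const), kd_w_const))
    }
    c_diss <- c_tot
    for (i in 1:50) {
      kd <- isotherm_kd(c_diss, model, doc_mg_L = doc)
      c_new <- c_tot / (1 + kd * m_kg_L)
      if (abs(c_new - c_diss) <= 1e-12 * max(c_new, 1e-12)) {
        c_diss <- c_new
        break
      }
      c_diss <- c_new
    }
    c(c_diss, kd)
  }

  # sediment equilibrium: inventory -> c(c_pw, q_part, sulfide)
  sed_eq <- function(m_s) {
    if (m_s <= 0) return(c(0, 0, 0))
    if (anoxic) {
      if (m_s <= cap_ug) {
        c_pw <- min(pw_floor, m_s / v_pw)
        sulf <- m_s - c_pw * v_pw
        return(c(c_pw, sulf / m_solids, sulf))
      }
      excess <- m_s - cap_ug
      c_pw <- excess / (v_pw + kd_phase * m_solids)
      return(c(c_pw, (cap_ug + kd_phase * c_pw * m_solids) / m_solids,
               cap_ug))
    }
    c_pw <- m_s / (v_pw + kd_sed_oxic * m_solids)
    c(c_pw, kd_sed_oxic * c_pw, 0)
  }

  # --- state -----------------------------------------------------------
  m_wat <- if (identical(dose$mode, "spike")) {
    dose$spike_conc_ug_L * v_w
  } else {
    0
  }
  m_sed <- 0
  cum <- c(input = m_wat, settling = 0, resuspension = 0,
           diffusion_net = 0, washout = 0, burial = 0)
  inflow_rate <- if (identical(dose$mode, "continuous")) {
    dose$inflow_conc_ug_L * v_w / tau                      # ug/m2/d
  } else {
    0
  }

  # instantaneous fluxes (ug/m2/d) at a given state:
  # c(settling, resuspension, burial, diffusion-into-sediment, washout)
  rates <- function(m_wat, m_sed) {
    weq <- water_eq(m_wat / v_w)
    c_diss <- weq[1]
    seq_ <- sed_eq(m_sed)
    c(v_s * (m_wat / v_w - c_diss) * 1000,
      resusp_solids * seq_[2],
      burial_solids * seq_[2],
      k_f * (c_diss - seq_[1]) * 1000,
      if (is.finite(tau)) m_wat / tau else 0)
  }

  # one Heun (second-order predictor-corrector) substep of length h;
  # halves recursively on negative mass
  advance <- function(m_wat, m_sed, cum, h) {
    if (h < 1e-6) {
      stop("integration step fell below 1e-6 d without stabilising",
           call. = FALSE)
    }
    halve <- function() {
      half <- advance(m_wat, m_sed, cum, h / 2)
      advance(half$m_wat, half$m_sed, half$cum, h / 2)
    }
    f1 <- rates(m_wat, m_sed)
    dw1 <- inflow_rate - f1[1] - f1[5] - f1[4] + f1[2]
    ds1 <- f1[1] + f1[4] - f1[2] - f1[3]
    wp <- m_wat + h * dw1
    sp <- m_sed + h * ds1
    if (wp < 0 || sp < 0) return(halve())
    f2 <- rates(wp, sp)
    f <- (f1 + f2) / 2
    new_w <- m_wat + h * (inflow_rate - f[1] - f[5] - f[4] + f[2])
    new_s <- m_sed + h * (f[1] + f[4] - f[2] - f[3])
    if (new_w < 0 || new_s < 0) return(halve())
    cum["input"] <- cum["input"] + h * inflow_rate
    cum["settling"] <- cum["settling"] + h * f[1]
    cum["resuspension"] <- cum["resuspension"] + h * f[2]
    cum["burial"] <- cum["burial"] + h * f[3]
    cum["diffusion_net"] <- cum["diffusion_net"] + h * f[4]
    cum["washout"] <- cum["washout"] + h * f[5]
    list(m_wat = new_w, m_sed = new_s, cum = cum)
  }

  # --- breakpoints: output grid plus re-dose events --------------------
  record_dt_d <- record_dt_d %||% max(dt_d, duration_d / 2000)
  rec_times <- unique(c(seq(0, duration_d, by = record_dt_d), duration_d))
  redose <- dose$redose_schedule
  ev_times <- if (!is.null(redose)) redose$time_d else numeric(0)
  ev_times <- ev_times[ev_times > 0 & ev_times <= duration_d]
  breaks <- sort(unique(c(rec_times, ev_times)))

  n_rec <- length(rec_times)
  out <- matrix(NA_real_, nrow = n_rec, ncol = 8)
  colnames(out) <- c("time_d", "cw_total_ug_L", "cw_diss_ug_L",
                     "log_kd_w", "sed_ug_m2", "pw_diss_ug_L",
                     "log_kd_s", "frac_sulfide")
  rec_i <- 1L

  record_row <- function(t, m_wat, m_sed) {
    weq <- water_eq(m_wat / v_w)
    seq_ <- sed_eq(m_sed)
    log_kd_s <- if (seq_[1] > 0 && m_sed > 0) {
      log10(seq_[2] / seq_[1])
    } else {
      NA_real_
    }
    c(t, m_wat / v_w, weq[1], log10(weq[2]), m_sed, seq_[1], log_kd_s,
      if (m_sed > 0) seq_[3] / m_sed else NA_real_)
  }

  t <- 0
  out[rec_i, ] <- record_row(t, m_wat, m_sed)
  rec_i <- rec_i + 1L
  for (tb in breaks[breaks > 0]) {
    while (t < tb - 1e-12) {
      h <- min(dt_d, tb - t)
      st <- advance(m_wat, m_sed, cum, h)
      m_wat <- st$m_wat
      m_sed <- st$m_sed
      cum <- st$cum
      t <- t + h
    }
    t <- tb
    if (length(ev_times) > 0 && any(abs(ev_times - tb) < 1e-9)) {
      add <- redose$conc_ug_L[abs(redose$time_d - tb) < 1e-9] * v_w
      m_wat <- m_wat + sum(add)
      cum["input"] <- cum["input"] + sum(add)
    }
    if (any(abs(rec_times - tb) < 1e-9)) {
      out[rec_i, ] <- record_row(t, m_wat, m_sed)
      rec_i <- rec_i + 1L
    }
  }

  structure(list(series = as.data.frame(out),
                 cumulative = as.list(cum),
                 final = list(water_ug_m2 = m_wat,
                              sediment_ug_m2 = m_sed),
                 scenario = scenario, dose = dose, model = model,
                 duration_d = duration_d, dt_d = dt_d),
            class = "lake_sim")
}

#' @export
print.lake_sim <- function(x, ...) {
  cat("<lake_sim>", x$duration_d, "d,", nrow(x$series), "output rows\n")
  cat(sprintf("  final water %.4g ug/L, sediment %.4g ug/m2\n",
              utils::tail(x$series$cw_total_ug_L, 1),
              x$final$sediment_ug_m2))
  invisible(x)
}

#' Normalized mass-balance ledger
#'
#' Summarises a simulation as cumulative pools and gross fluxes normalized
#' to a total copper input of `normalize` units (100 by convention):
#' remaining in the water column, in the active sediment layer, buried,
#' and exported by washout, plus gross settling, gross resuspension and
#' the signed net diffusive exchange (positive = into the sediment).
#' The four pools close to the input within 0.1 unit.
#'
#' @param result A `lake_sim` from [simulate_lake()].
#' @param normalize Input mass the ledger is scaled to (default 100).
#' @return An object of class `mass_balance_ledger` (a named list).
#' @export
mass_balance <- function(result, normalize = 100) {
  stopifnot(inherits(result, "lake_sim"))
  cum <- result$cumulative
  input <- cum$input
  if (input <= 0) stop("simulation had no copper input", call. = FALSE)
  f <- normalize / input
  ledger <- list(
    input = normalize,
    remaining_water = result$final$water_ug_m2 * f,
    in_sediment = result$final$sediment_ug_m2 * f,
    buried = cum$burial * f,
    exported = cum$washout * f,
    gross_settling = cum$settling * f,
    gross_resuspension = cum$resuspension * f,
    net_diffusion = cum$diffusion_net * f,
    closure = (result$final$water_ug_m2 + result$final$sediment_ug_m2 +
                 cum$burial + cum$washout) * f
  )
  structure(ledger, class = "mass_balance_ledger")
}

#' @export
print.mass_balance_ledger <- function(x, ...) {
  cat("<mass_balance_ledger> (input normalized to", x$input, ")\n")
  for (nm in c("remaining_water", "in_sediment", "buried", "exported",
               "gross_settling", "gross_resuspension", "net_diffusion")) {
    cat(sprintf("  %-20s %10.4f\n", nm, x[[nm]]))
  }
  cat(sprintf("  closure: %.4f (should equal %g within 0.1)\n",
              x$closure, x$input))
  invisible(x)
}

#' Removal times from a simulated series
#'
#' Finds the times at which the simulated water-column concentration first
#' falls to 50 % and 30 % of its post-dose maximum, by linear
#' interpolation between output grid points.
#'
#' @param result A `lake_sim` from a spike-mode [simulate_lake()] run.
#' @param phase `"dissolved"` or `"total"` water-column copper.
#' @return A [removal_times()] record (method `"simulation"`); thresholds
#'   never reached within the run are reported as `NA` with a note.
#' @export
extract_removal_times <- function(result,
                                  phase = c("dissolved", "total")) {
  stopifnot(inherits(result, "lake_sim"))
  phase <- match.arg(phase)
  if (!identical(result$dose$mode, "spike")) {
    stop("removal times are defined for spike-mode simulations",
         call. = FALSE)
  }
  col <- if (phase == "dissolved") "cw_diss_ug_L" else "cw_total_ug_L"
  tt <- result$series$time_d
  cc <- result$series[[col]]
  if (max(cc) <= 0) {
    stop("series has no positive post-dose concentration", call. = FALSE)
  }
  i0 <- which.max(cc)
  tt <- tt[i0:length(tt)] - tt[i0]
  frac <- cc[i0:length(cc)] / cc[i0]
  t50 <- first_crossing(tt, frac, 0.5)
  t70 <- first_crossing(tt, frac, 0.3)
  note <- NULL
  if (is.na(t70)) {
    note <- sprintf("70%% removal not observed in %g d", max(tt))
  }
  if (is.na(t50)) {
    note <- sprintf("50%% removal not observed in %g d", max(tt))
  }
  removal_times(t50, t70, method = "simulation", note = note)
}

# first downward crossing of `level` by linear interpolation; NA if none
first_crossing <- function(t, frac, level) {
  hit <- which(frac <= level)
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  if (i == 1) return(t[1])
  t[i - 1] + (t[i] - t[i - 1]) * (frac[i - 1] - level) /
    (frac[i - 1] - frac[i])
}

#' Named sensitivity-variant grid
#'
#' The standard water-column / sediment sensitivity grid: copper loading
#' at the chronic classification cutoffs (0.1 and 1 mg/L) and at
#' 10/100/1000 ug/L, the pH 6/7/8 test-protocol chemistries, slow settling
#' (0.24 m/d), high DOC (15 mg/L), low AVS (1 umol/g), low sediment solids
#' (150 g/L bulk), hardness doubled and halved, and resuspension at 0.1,
#' 3.2 and 10 times the default 2.44 cm/yr.
#'
#' @return A named list of variants; each has elements `scenario` (named
#'   list of scenario-field overrides) and/or `spike_conc_ug_L`.
#' @export
sensitivity_grid <- function() {
  list(
    base = list(),
    loading_10_ug_L = list(spike_conc_ug_L = 10),
    loading_100_ug_L = list(spike_conc_ug_L = 100),
    loading_1000_ug_L = list(spike_conc_ug_L = 1000),
    ph_6 = list(scenario = list(ph_water = 6)),
    ph_7 = list(scenario = list(ph_water = 7)),
    ph_8 = list(scenario = list(ph_water = 8)),
    slow_settling = list(scenario = list(settling_velocity_m_d = 0.24)),
    high_doc = list(scenario = list(doc_mg_L = 15)),
    low_avs = list(scenario = list(avs_umol_g = 1)),
    low_sediment_solids = list(
      scenario = list(sediment_solids_g_Lbulk = 150)),
    hardness_x2 = list(scenario = list(hardness_mg_L_CaCO3 = 1032)),
    hardness_half = list(scenario = list(hardness_mg_L_CaCO3 = 258)),
    resuspension_x0.1 = list(
      scenario = list(resuspension_velocity_cm_yr = 0.244)),
    resuspension_x3.2 = list(
      scenario = list(resuspension_velocity_cm_yr = 7.808)),
    resuspension_x10 = list(
      scenario = list(resuspension_velocity_cm_yr = 24.4))
  )
}

#' Run a sensitivity suite of simulations
#'
#' Applies a grid of parameter variations to a base setup, simulates each
#' variant, and tabulates the dissolved-copper removal times.
#'
#' @param base Name of a built-in scenario (see [builtin_scenarios()]) or
#'   a `lake_setup` list.
#' @param variations A variant grid as returned by [sensitivity_grid()].
#' @param duration_d,dt_d Passed to [simulate_lake()].
#' @return A data frame with one row per variant: `variant`, `t50_d`,
#'   `t70_d`, `attained_70_within_28d`.
#' @export
run_sensitivity_suite <- function(base = "euses_base",
                                  variations = sensitivity_grid(),
                                  duration_d = 120, dt_d = 0.01) {
  setup <- if (is.character(base)) {
    cat <- builtin_scenarios()
    if (!base %in% names(cat)) {
      stop("unknown base scenario '", base, "'", call. = FALSE)
    }
    cat[[base]]
  } else {
    base
  }
  rows <- lapply(names(variations), function(nm) {
    v <- variations[[nm]]
    sc <- setup$scenario
    if (!is.null(v$scenario)) {
      sc[names(v$scenario)] <- v$scenario
      sc <- validate_scenario(sc)
    }
    dose <- setup$dose
    if (!is.null(v$spike_conc_ug_L)) {
      dose <- metal_dose("spike", spike_conc_ug_L = v$spike_conc_ug_L)
    }
    sim <- simulate_lake(sc, dose, setup$model, duration_d = duration_d,
                         dt_d = dt_d)
    rt <- extract_removal_times(sim, phase = "dissolved")
    data.frame(variant = nm, t50_d = rt$t50_d, t70_d = rt$t70_d,
               attained_70_within_28d = is.finite(rt$t70_d) &&
                 rt$t70_d <= 28,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
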