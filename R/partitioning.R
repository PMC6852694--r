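#' Partitioning / speciation model
#'
#' Describes how dissolved and particulate copper are distributed in the
#' water column and sediment. Two modes are supported:
#'
#' * `"empirical"`: constant distribution coefficients (defaults
#'   log KD 4.48 L/kg for water, 4.39 L/kg for sediment, the field-derived
#'   review values).
#' * `"isotherm"`: a one-parameter Freundlich-type, concentration-dependent
#'   KD that stands in for a full speciation calculation. It is anchored at
#'   a reference dissolved concentration and clamped to a calibrated
#'   log-KD band so the simulated water-column KD stays within the range a
#'   speciation model predicts for the base case (log KD 4.85-4.88).
#'
#' The model also carries the conditional Cu-DOC binding constant, the
#' copper-sulfide stoichiometry used for acid-volatile-sulfide (AVS)
#' precipitation in anoxic sediment, and the oxic-phase sorption
#' coefficients (L per kg of each phase) that both apportion particulate
#' copper across POC/HFO/HMO and set the sulfide-free sorptive KD. The
#' phase coefficients are calibrated constants reproducing the base-case
#' oxic apportionment (95.34/4.3/0.36 % of particulate copper on
#' POC/HFO/HMO) and an effective sulfide-free sediment KD of
#' 10^3.53 L/kg; they are not thermodynamic constants.
#'
#' @param mode `"empirical"` or `"isotherm"`.
#' @param log_kd_water log10 water-column distribution coefficient (L/kg),
#'   used in empirical mode.
#' @param log_kd_sediment log10 sediment distribution coefficient (L/kg):
#'   the sorptive KD applied to non-sulfide-bound copper in empirical mode
#'   while AVS capacity remains.
#' @param isotherm_ref_log_kd log10 KD at the reference dissolved
#'   concentration (isotherm mode).
#' @param isotherm_ref_conc_ug_L Reference dissolved concentration (ug/L).
#' @param isotherm_exponent Freundlich-type exponent n, 0 < n <= 1. n = 1
#'   gives a linear (constant-KD) isotherm; n < 1 makes KD rise as the
#'   dissolved concentration falls.
#' @param isotherm_log_kd_band Length-2 numeric: calibrated validity band
#'   for the isotherm log KD; outside it the KD is held at the boundary
#'   value. `NULL` disables clamping.
#' @param isotherm_ref_doc_mg_L DOC at which the isotherm was calibrated
#'   (mg/L). In isotherm mode the operational KD is scaled by
#'   (1 + K_DOC*DOC_ref)/(1 + K_DOC*DOC): extra DOC holds more copper in
#'   the (non-settling) dissolved phase and lowers the operational KD.
#' @param k_doc_conditional_L_mg Conditional Cu-DOC binding constant
#'   (L/mg DOC).
#' @param sulfide_stoichiometry `"CuS"` (1 mol Cu per mol AVS) or `"Cu2S"`
#'   (2 mol Cu per mol AVS).
#' @param kd_poc_L_kg,kd_hfo_L_kg,kd_hmo_L_kg Phase sorption coefficients
#'   (L per kg of POC / HFO / HMO).
#' @param sulfide_porewater_ug_L Solubility-limited porewater dissolved
#'   copper concentration while the sulfide pool is unsaturated (ug/L).
#'   Copper sulfides are highly insoluble; the default is a small
#'   operational floor.
#' @param cu_hydroxide_pksp -log10 solubility product used by
#'   [hydroxide_saturation_index()].
#' @return An object of class `partitioning_model`.
#' @export
partitioning_model <- function(mode = c("empirical", "isotherm"),
                               log_kd_water = 4.48,
                               log_kd_sediment = 4.39,
                               isotherm_ref_log_kd = 4.85,
                               isotherm_ref_conc_ug_L = 17,
                               isotherm_exponent = 0.964,
                               isotherm_log_kd_band = c(4.85, 4.88),
                               isotherm_ref_doc_mg_L = 2,
                               k_doc_conditional_L_mg = 100,
                               sulfide_stoichiometry = c("CuS", "Cu2S"),
                               kd_poc_L_kg = 64600,
                               kd_hfo_L_kg = 7830,
                               kd_hmo_L_kg = 79200,
                               sulfide_porewater_ug_L = 1e-3,
                               cu_hydroxide_pksp = 19.32) {
  mode <- match.arg(mode)
  sulfide_stoichiometry <- match.arg(sulfide_stoichiometry)
  if (isotherm_exponent <= 0 || isotherm_exponent > 1) {
    stop("isotherm_exponent must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(isotherm_log_kd_band)) {
    if (length(isotherm_log_kd_band) != 2 ||
        diff(isotherm_log_kd_band) < 0) {
      stop("isotherm_log_kd_band must be c(lower, upper)", call. = FALSE)
    }
  }
  stopifnot(log_kd_water >= 0, log_kd_sediment >= 0,
            k_doc_conditional_L_mg >= 0, sulfide_porewater_ug_L >= 0)
  structure(list(mode = mode,
                 log_kd_water = log_kd_water,
                 log_kd_sediment = log_kd_sediment,
                 isotherm_ref_log_kd = isotherm_ref_log_kd,
                 isotherm_ref_conc_ug_L = isotherm_ref_conc_ug_L,
                 isotherm_exponent = isotherm_exponent,
                 isotherm_log_kd_band = isotherm_log_kd_band,
                 isotherm_ref_doc_mg_L = isotherm_ref_doc_mg_L,
                 k_doc_conditional_L_mg = k_doc_conditional_L_mg,
                 sulfide_stoichiometry = sulfide_stoichiometry,
                 kd_poc_L_kg = kd_poc_L_kg,
                 kd_hfo_L_kg = kd_hfo_L_kg,
                 kd_hmo_L_kg = kd_hmo_L_kg,
                 sulfide_porewater_ug_L = sulfide_porewater_ug_L,
                 cu_hydroxide_pksp = cu_hydroxide_pksp),
            class = "partitioning_model")
}

#' @export
print.partitioning_model <- function(x, ...) {
  cat("<partitioning_model> mode =", x$mode, "\n")
  if (x$mode == "empirical") {
    cat(sprintf("  log KD water %.2f, sediment %.2f (L/kg)\n",
                x$log_kd_water, x$log_kd_sediment))
  } else {
    cat(sprintf("  log KD %.3f at %g ug/L, n = %.3f, band [%.2f, %.2f]\n",
                x$isotherm_ref_log_kd, x$isotherm_ref_conc_ug_L,
                x$isotherm_exponent, x$isotherm_log_kd_band[1],
                x$isotherm_log_kd_band[2]))
  }
  invisible(x)
}

# molar mass of copper, g/mol
CU_MOLAR_MASS <- 63.546

#' Fraction of total metal bound to particles
#'
#' The equilibrium particulate fraction KD*m / (1 + KD*m), where the
#' dimensionless product KD*m uses m converted from mg/L to kg/L.
#'
#' @param kd_L_kg Distribution coefficient (L/kg), >= 0.
#' @param m_mg_L Suspended solids concentration (mg/L), >= 0.
#' @return The particulate fraction in `[0, 1)`. Vectorised.
#' @examples
#' particulate_fraction(10^4.48, 15)   # ~0.31 for the base-case lake
#' @export
particulate_fraction <- function(kd_L_kg, m_mg_L) {
  if (any(kd_L_kg < 0) || any(m_mg_L < 0)) {
    stop("kd_L_kg and m_mg_L must be >= 0", call. = FALSE)
  }
  x <- kd_L_kg * m_mg_L * 1e-6
  x / (1 + x)
}

#' Concentration-dependent distribution coefficient
#'
#' Freundlich-type stand-in for a per-step speciation calculation:
#' log10 KD = ref_log_kd + (n - 1) * log10(c / c_ref), optionally clamped
#' to the model's calibrated log-KD band, then (if the ambient DOC differs
#' from the calibration DOC) rescaled by the DOC partitioning factor.
#' KD is non-increasing in the dissolved concentration for n < 1 and
#' equals 10^ref_log_kd at the reference concentration.
#'
#' @param c_dissolved_ug_L Dissolved copper concentration (ug/L), > 0.
#' @param model A [partitioning_model()] with `mode = "isotherm"`.
#' @param doc_mg_L Ambient DOC (mg/L); defaults to the calibration DOC so
#'   the plain isotherm is returned.
#' @return KD in L/kg. Vectorised over `c_dissolved_ug_L`.
#' @export
isotherm_kd <- function(c_dissolved_ug_L, model,
                        doc_mg_L = model$isotherm_ref_doc_mg_L) {
  if (any(c_dissolved_ug_L <= 0)) {
    stop("c_dissolved_ug_L must be > 0", call. = FALSE)
  }
  if (!identical(model$mode, "isotherm")) {
    stop("isotherm_kd() requires a model with mode = 'isotherm'",
         call. = FALSE)
  }
  lkd <- model$isotherm_ref_log_kd +
    (model$isotherm_exponent - 1) *
    log10(c_dissolved_ug_L / model$isotherm_ref_conc_ug_L)
  band <- model$isotherm_log_kd_band
  if (!is.null(band)) {
    lkd <- pmin(pmax(lkd, band[1]), band[2])
  }
  kd <- 10^lkd
  if (!isTRUE(all.equal(doc_mg_L, model$isotherm_ref_doc_mg_L))) {
    kdoc <- model$k_doc_conditional_L_mg
    kd <- kd * (1 + kdoc * model$isotherm_ref_doc_mg_L) /
      (1 + kdoc * doc_mg_L)
  }
  kd
}

#' Fraction of dissolved metal complexed by DOC
#'
#' K_DOC*DOC / (1 + K_DOC*DOC). With the default conditional constant the
#' complexed fraction exceeds 0.98 already at 2 mg/L DOC, consistent with
#' the strong Cu-organic binding observed in typical natural waters.
#'
#' @param doc_mg_L DOC concentration (mg/L), >= 0.
#' @param model A [partitioning_model()].
#' @return Fraction in `[0, 1)`. Vectorised.
#' @export
doc_complexed_fraction <- function(doc_mg_L, model = partitioning_model()) {
  if (any(doc_mg_L < 0)) stop("doc_mg_L must be >= 0", call. = FALSE)
  x <- model$k_doc_conditional_L_mg * doc_mg_L
  x / (1 + x)
}

# moles of Cu bound per mole of AVS for the configured stoichiometry
cu_per_avs <- function(model) {
  if (identical(model$sulfide_stoichiometry, "Cu2S")) 2 else 1
}

# effective sulfide-free sorptive KD (L/kg bulk solid) from phase contents
phase_kd_L_kg <- function(scenario, model) {
  model$kd_poc_L_kg * scenario$poc_fraction +
    model$kd_hfo_L_kg * scenario$hfo_mg_kg * 1e-6 +
    model$kd_hmo_L_kg * scenario$hmo_mg_kg * 1e-6
}

# porewater volume per m2 (L) from a simple solids-density porosity
porewater_volume_L_m2 <- function(scenario) {
  phi <- max(0.3, 1 - scenario$sediment_solids_g_Lbulk / 2600)
  phi * scenario$sediment_depth_m * 1000
}

# sediment solids inventory per m2 (kg)
sediment_solids_kg_m2 <- function(scenario) {
  scenario$sediment_solids_g_Lbulk * scenario$sediment_depth_m
}

# hydrolysis side-reaction coefficient: fraction of dissolved-inorganic
# copper present as the free aquo ion, 1 / (1 + 10^(pH - pK1)), pK1 = 6.5
free_ion_fraction <- function(ph) {
  1 / (1 + 10^(ph - 6.5))
}

# Fast internal sediment equilibrium used inside the simulator time loop.
# inventory_ug: total Cu in the active layer per m2. Returns porewater
# dissolved concentration (ug/L), particulate load per kg solid (ug/kg)
# and the sulfide-bound mass (ug).
sediment_equilibrium_core <- function(inventory_ug, scenario, model) {
  m_solids <- sediment_solids_kg_m2(scenario)
  v_pw <- porewater_volume_L_m2(scenario)
  kd_phase <- phase_kd_L_kg(scenario, model)
  anoxic <- identical(scenario$sediment_redox, "anoxic") &&
    scenario$avs_umol_g > 0

  if (!anoxic) {
    # empirical mode keeps the field-derived whole-sediment KD; the
    # calculated mode derives the sorptive KD from the phase contents
    kd <- if (identical(model$mode, "empirical")) {
      10^model$log_kd_sediment
    } else {
      kd_phase
    }
    c_pw <- inventory_ug / (v_pw + kd * m_solids)
    return(list(c_pw_ug_L = c_pw,
                q_part_ug_kg = kd * c_pw,
                sulfide_ug = 0,
                sorbed_ug = kd * c_pw * m_solids,
                capacity_ug = 0))
  }

  # avs umol/g * 1e-6 mol/umol * 1000 g/kg = mol/kg; * kg solids = mol;
  # * (mol Cu / mol AVS) * 63.546 g/mol * 1e6 ug/g = ug
  cap_ug <- scenario$avs_umol_g * 1e-6 * 1000 * m_solids *
    cu_per_avs(model) * CU_MOLAR_MASS * 1e6

  if (inventory_ug <= cap_ug) {
    # sulfide controls; porewater at the solubility-limited floor
    c_pw <- min(model$sulfide_porewater_ug_L, inventory_ug / v_pw)
    diss <- c_pw * v_pw
    sulf <- inventory_ug - diss
    return(list(c_pw_ug_L = c_pw,
                q_part_ug_kg = sulf / m_solids,
                sulfide_ug = sulf,
                sorbed_ug = 0,
                capacity_ug = cap_ug))
  }

  # AVS exhausted: the excess partitions to the sulfide-free sorptive
  # phases (POC/HFO/HMO); the empirical anoxic KD does not apply to an
  # AVS-saturated sediment
  excess <- inventory_ug - cap_ug
  c_pw <- excess / (v_pw + kd_phase * m_solids)
  sorbed <- kd_phase * c_pw * m_solids
  list(c_pw_ug_L = c_pw,
       q_part_ug_kg = (cap_ug + sorbed) / m_solids,
       sulfide_ug = cap_ug,
       sorbed_ug = sorbed,
       capacity_ug = cap_ug)
}

#' Sediment-layer equilibrium speciation
#'
#' Distributes a total copper inventory in the active sediment layer
#' across porewater (inorganic and DOC-complexed) and particulate
#' (sulfide, POC, HFO, HMO) pools.
#'
#' Under anoxic conditions copper precipitates as a copper sulfide
#' (1 mol Cu per mol AVS for CuS, 2 for Cu2S) up to the stoichiometric AVS
#' capacity of the layer; copper binds sulfide before any sorptive phase.
#' While capacity remains, the porewater concentration sits at a small
#' solubility-limited floor. Copper beyond the capacity - and all copper
#' under oxic conditions - sorbs to POC/HFO/HMO with the model's
#' phase coefficients, and the particulate pool is apportioned across the
#' phases in proportion to phase content times coefficient.
#'
#' @param cu_inventory_ug_m2 Total copper mass in the layer (ug per m2 of
#'   lake bed), >= 0.
#' @param scenario A validated [lake_scenario()].
#' @param model A [partitioning_model()].
#' @return An object of class `speciation_breakdown`: fractions of the
#'   total inventory in each pool (summing to 1 for a positive inventory),
#'   the porewater dissolved concentration, the free-ion share of
#'   dissolved copper, and the effective log10 KD of the layer.
#' @export
sediment_equilibrium <- function(cu_inventory_ug_m2, scenario, model) {
  stopifnot(cu_inventory_ug_m2 >= 0)
  validate_scenario(scenario)
  if (cu_inventory_ug_m2 == 0) {
    br <- list(dissolved_inorganic = 0, dissolved_doc = 0,
               particulate_sulfide = 0, particulate_poc = 0,
               particulate_hfo = 0, particulate_hmo = 0)
    return(structure(list(fractions = br, total_ug_m2 = 0,
                          porewater_ug_L = 0, free_ion_of_dissolved = 0,
                          effective_log_kd = NA_real_),
                     class = "speciation_breakdown"))
  }
  eq <- sediment_equilibrium_core(cu_inventory_ug_m2, scenario, model)
  v_pw <- porewater_volume_L_m2(scenario)
  diss <- eq$c_pw_ug_L * v_pw
  fdoc <- doc_complexed_fraction(scenario$doc_mg_L, model)

  w <- c(poc = model$kd_poc_L_kg * scenario$poc_fraction,
         hfo = model$kd_hfo_L_kg * scenario$hfo_mg_kg * 1e-6,
         hmo = model$kd_hmo_L_kg * scenario$hmo_mg_kg * 1e-6)
  w <- if (sum(w) > 0) w / sum(w) else c(poc = 1, hfo = 0, hmo = 0)

  tot <- cu_inventory_ug_m2
  fr <- list(
    dissolved_inorganic = diss * (1 - fdoc) / tot,
    dissolved_doc = diss * fdoc / tot,
    particulate_sulfide = eq$sulfide_ug / tot,
    particulate_poc = eq$sorbed_ug * w[["poc"]] / tot,
    particulate_hfo = eq$sorbed_ug * w[["hfo"]] / tot,
    particulate_hmo = eq$sorbed_ug * w[["hmo"]] / tot
  )
  part <- eq$sulfide_ug + eq$sorbed_ug
  eff_kd <- if (eq$c_pw_ug_L > 0) {
    (part / sediment_solids_kg_m2(scenario)) / eq$c_pw_ug_L
  } else {
    Inf
  }
  structure(list(fractions = fr, total_ug_m2 = tot,
                 porewater_ug_L = eq$c_pw_ug_L,
                 free_ion_of_dissolved =
                   (1 - fdoc) * free_ion_fraction(scenario$ph_sediment),
                 effective_log_kd = log10(eff_kd)),
            class = "speciation_breakdown")
}

#' @export
print.speciation_breakdown <- function(x, ...) {
  cat("<speciation_breakdown> total", format(x$total_ug_m2),
      "ug/m2, porewater", format(x$porewater_ug_L), "ug/L\n")
  fr <- unlist(x$fractions)
  for (nm in names(fr)) {
    cat(sprintf("  %-22s %8.4f\n", nm, fr[[nm]]))
  }
  cat(sprintf("  effective log KD: %s\n", format(x$effective_log_kd)))
  invisible(x)
}

#' Copper (hydr)oxide saturation index
#'
#' Diagnostic log10(IAP/Ksp) for Cu(OH)2, with the free Cu2+ activity
#' estimated from the dissolved-inorganic concentration through a simple
#' hydrolysis side-reaction coefficient. A positive index flags
#' oversaturation (direct hydroxide/oxide precipitation plausible, as in
#' high-pH, high-dose mesocosm waters); no precipitation is simulated in
#' the water column.
#'
#' @param ph Water pH, in `[2, 12]`.
#' @param dissolved_inorganic_cu_ug_L Dissolved inorganic copper (ug/L),
#'   > 0.
#' @param model A [partitioning_model()] (supplies the solubility product).
#' @return The saturation index (log10 units).
#' @export
hydroxide_saturation_index <- function(ph, dissolved_inorganic_cu_ug_L,
                                       model = partitioning_model()) {
  if (any(ph < 2) || any(ph > 12)) {
    stop("ph must lie in [2, 12]", call. = FALSE)
  }
  if (any(dissolved_inorganic_cu_ug_L <= 0)) {
    stop("dissolved_inorganic_cu_ug_L must be > 0", call. = FALSE)
  }
  cu_mol <- dissolved_inorganic_cu_ug_L * 1e-6 / CU_MOLAR_MASS
  free <- cu_mol * free_ion_fraction(ph)
  log_iap <- log10(free) + 2 * (ph - 14)
  log_iap + model$cu_hydroxide_pksp
}
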