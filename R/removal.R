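#' First-order settling loss rate for total metal
#'
#' The well-mixed water-column loss rate via particle settling,
#' \deqn{k = \frac{S K_D}{H (1 + K_D m)},\qquad S = v_s m,}
#' with the two limiting forms k = v_s/H (all metal on particles,
#' KD*m >> 1) and k = v_s m KD / H (KD*m << 1).
#'
#' @param H_m Mean depth H (m), > 0.
#' @param settling_velocity_m_d Settling velocity v_s (m/d), >= 0.
#' @param m_mg_L Suspended solids m (mg/L), >= 0.
#' @param kd_L_kg Distribution coefficient KD (L/kg), >= 0.
#' @return Loss rate k (1/d). Vectorised.
#' @examples
#' settling_loss_rate(3, 2.5, 15, 10^4.48)  # base-case lake, ~0.26 1/d
#' @export
settling_loss_rate <- function(H_m, settling_velocity_m_d, m_mg_L,
                               kd_L_kg) {
  if (any(H_m <= 0)) stop("H_m must be > 0", call. = FALSE)
  if (any(settling_velocity_m_d < 0) || any(m_mg_L < 0) ||
      any(kd_L_kg < 0)) {
    stop("settling velocity, m and KD must be >= 0", call. = FALSE)
  }
  (settling_velocity_m_d / H_m) * particulate_fraction(kd_L_kg, m_mg_L)
}

#' Time for the water column to fall to x percent remaining
#'
#' Closed form t_x = ln(100/x) / k with k from [settling_loss_rate()]:
#' x = 50 gives the half-time, x = 30 the 70 % removal time. For any
#' first-order process t70/t50 = ln(100/30)/ln(2).
#'
#' @inheritParams settling_loss_rate
#' @param x_percent_remaining Percentage remaining, in (0, 100].
#' @return t_x in days (`Inf` when k = 0 and x < 100).
#' @export
removal_time <- function(x_percent_remaining, H_m, settling_velocity_m_d,
                         m_mg_L, kd_L_kg) {
  if (any(x_percent_remaining <= 0) || any(x_percent_remaining > 100)) {
    stop("x_percent_remaining must lie in (0, 100]", call. = FALSE)
  }
  k <- settling_loss_rate(H_m, settling_velocity_m_d, m_mg_L, kd_L_kg)
  out <- log(100 / x_percent_remaining) / k
  out[x_percent_remaining == 100] <- 0
  out
}

#' Dilution-only half-time
#'
#' Half-time under washout alone: first-order loss at rate 1/tau gives
#' t50 = ln(2) * tau. Used to judge whether hydraulic flushing can explain
#' an observed removal rate (e.g. ~250 d for a detention time above a
#' year, ~63 d for a quarter year - both far longer than observed
#' half-times of a few days, implicating settling instead).
#'
#' @param hydraulic_residence_time_d Detention time tau (d), > 0.
#' @return t50 in days. Vectorised.
#' @export
dilution_half_time <- function(hydraulic_residence_time_d) {
  if (any(hydraulic_residence_time_d <= 0)) {
    stop("hydraulic_residence_time_d must be > 0", call. = FALSE)
  }
  log(2) * hydraulic_residence_time_d
}

#' Removal time as a function of H/S
#'
#' Generates the theoretical t_x versus H/S line: with S = v_s m,
#' t_x = ln(100/x) * (H/S) * (1 + KD m) / KD, linear in H/S. Defaults
#' (m = 10.5 mg/L, KD = 10^4.78 L/kg, x = 30) are the cross-system average
#' partitioning parameters used for the published comparison of lakes,
#' microcosms and mesocosms.
#'
#' @param h_over_s H/S values (m per g m^-2 d^-1, i.e. m^3 d / g), > 0.
#' @param m_mg_L Suspended solids (mg/L).
#' @param kd_L_kg Distribution coefficient (L/kg).
#' @param x_percent Percentage remaining (30 for 70 % removal).
#' @return A data frame with columns `h_over_s` and `t_x_d`.
#' @export
removal_time_curve <- function(h_over_s, m_mg_L = 10.5,
                               kd_L_kg = 10^4.78, x_percent = 30) {
  if (any(h_over_s <= 0)) stop("h_over_s must be > 0", call. = FALSE)
  if (x_percent <= 0 || x_percent > 100) {
    stop("x_percent must lie in (0, 100]", call. = FALSE)
  }
  kd_m3_g <- kd_L_kg * 1e-6                    # L/kg -> m^3/g
  m_kg_L <- m_mg_L * 1e-6
  t_x <- log(100 / x_percent) * h_over_s * (1 + kd_L_kg * m_kg_L) / kd_m3_g
  data.frame(h_over_s = h_over_s, t_x_d = t_x)
}

#' Steady state under continuous loading
#'
#' For a flow-through system with inflow concentration C_in, detention
#' time tau and first-order in-lake loss k, the steady-state water-column
#' concentration is C_ss = C_in / (1 + k tau); with no loss, C_ss = C_in.
#'
#' @param inflow_conc_ug_L Inflow concentration (ug/L).
#' @param residence_time_d Detention time tau (d), > 0.
#' @param loss_rate_per_d First-order loss rate k (1/d), >= 0.
#' @return Steady-state concentration (ug/L). Vectorised.
#' @export
steady_state_continuous <- function(inflow_conc_ug_L, residence_time_d,
                                    loss_rate_per_d) {
  if (any(residence_time_d <= 0)) {
    stop("residence_time_d must be > 0", call. = FALSE)
  }
  if (any(loss_rate_per_d < 0)) {
    stop("loss_rate_per_d must be >= 0", call. = FALSE)
  }
  inflow_conc_ug_L / (1 + loss_rate_per_d * residence_time_d)
}

#' Removal-times record
#'
#' Small container for 50 % and 70 % removal times with optional 95 %
#' bounds, as tabulated for field and model systems.
#'
#' @param t50_d,t70_d Times to 50 % and 70 % removal (d); `NA` when not
#'   attained/computable.
#' @param t50_ci,t70_ci Optional length-2 lower/upper 95 % bounds (d).
#' @param method One of `"analytic"`, `"fit"`, `"interpolation"`,
#'   `"simulation"`.
#' @param note Optional free-text flag (e.g. "70% removal not observed").
#' @return Object of class `removal_times`.
#' @export
removal_times <- function(t50_d, t70_d, t50_ci = c(NA_real_, NA_real_),
                          t70_ci = c(NA_real_, NA_real_),
                          method = c("analytic", "fit", "interpolation",
                                     "simulation"),
                          note = NULL) {
  method <- match.arg(method)
  if (is.finite(t50_d) && is.finite(t70_d) &&
      (t50_d < 0 || t70_d < t50_d)) {
    stop("need t70 >= t50 >= 0", call. = FALSE)
  }
  structure(list(t50_d = t50_d, t70_d = t70_d,
                 t50_ci = t50_ci, t70_ci = t70_ci,
                 method = method, note = note),
            class = "removal_times")
}

#' @export
print.removal_times <- function(x, ...) {
  fmt <- function(t, ci) {
    s <- if (is.na(t)) "not attained" else sprintf("%.3g d", t)
    if (!any(is.na(ci))) {
      s <- paste0(s, sprintf(" (%.3g-%.3g)", ci[1], ci[2]))
    }
    s
  }
  cat("<removal_times> [", x$method, "]\n", sep = "")
  cat("  t50:", fmt(x$t50_d, x$t50_ci), "\n")
  cat("  t70:", fmt(x$t70_d, x$t70_ci), "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}
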