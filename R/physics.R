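#' Physical constants for the sublimation model
#'
#' Bundles the empirical coefficients of the ice vapour-pressure correlation
#' (a Clausius-Clapeyron-type form in the Murphy-Koop family), the latent
#' heat of sublimation correlation, and the material constants of the frozen
#' product. Defaults are the values used throughout the drying model.
#'
#' Units: `beta_pi` is in K and `delta_pi` in 1/K (both enter Eq. forms
#' dimensionlessly once combined with temperature); `eps_h` is in K and is
#' squared inside the exponential of the latent-heat correlation.
#'
#' @param alpha_pi,beta_pi,gamma_pi,delta_pi vapour-pressure coefficients.
#' @param alpha_h,beta_h,gamma_h,delta_h,eps_h latent-heat coefficients
#'   (J/mol, J/(mol K), J/(mol K^2), J/mol, K).
#' @param rho_ice mass density of ice, kg/m^3.
#' @param theta_dr dried-layer porosity (ice volume fraction of the frozen
#'   layer), dimensionless.
#' @param M molecular weight of water, kg/mol.
#' @return An object of class `physical_constants` (a validated list).
#' @examples
#' pc <- physical_constants()
#' vapor_pressure_ice(273.16, pc)
#' @export
physical_constants <- function(alpha_pi = 9.550426,
                               beta_pi = 5723.2658,
                               gamma_pi = 3.53068,
                               delta_pi = 0.00728332,
                               alpha_h = 4.68e4,
                               beta_h = 35.9,
                               gamma_h = 0.0741,
                               delta_h = 542,
                               eps_h = 124,
                               rho_ice = 918,
                               theta_dr = 0.97,
                               M = 18.01528e-3) {
  pc <- list(alpha_pi = alpha_pi, beta_pi = beta_pi, gamma_pi = gamma_pi,
             delta_pi = delta_pi,
             alpha_h = alpha_h, beta_h = beta_h, gamma_h = gamma_h,
             delta_h = delta_h, eps_h = eps_h,
             rho_ice = rho_ice, theta_dr = theta_dr, M = M)
  bad <- names(pc)[!vapply(pc, function(x)
    is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0, logical(1))]
  if (length(bad))
    stop("physical constants must be positive scalars; offending: ",
         paste(bad, collapse = ", "))
  structure(pc, class = "physical_constants")
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("<physical_constants>\n")
  for (nm in names(x)) cat(sprintf("  %-9s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Load physical constants from a config list
#'
#' Accepts a list (typically the `physics` block of a JSON run config) whose
#' entries override the defaults of [physical_constants()].
#'
#' @param block named list of overrides, or `NULL` for all defaults.
#' @return `physical_constants` object.
#' @export
constants_from_config <- function(block = NULL) {
  if (is.null(block)) return(physical_constants())
  known <- names(formals(physical_constants))
  unknown <- setdiff(names(block), known)
  if (length(unknown))
    stop("unknown physics constant(s): ", paste(unknown, collapse = ", "))
  do.call(physical_constants, block)
}

#' Saturation vapour pressure over ice
#'
#' Empirical Clausius-Clapeyron-type correlation
#' \deqn{P_i = \exp(\alpha - \beta/T_i + \gamma \ln T_i - \delta T_i)}
#' valid for sublimation-front temperatures between roughly 150 K and the
#' triple point (273.16 K); a warning is emitted outside that range.
#'
#' @param T_i temperature in K (vectorised).
#' @param constants a [physical_constants()] object.
#' @return vapour pressure in Pa.
#' @export
vapor_pressure_ice <- function(T_i, constants = physical_constants()) {
  stopifnot(inherits(constants, "physical_constants"))
  if (any(!is.finite(T_i)) || any(T_i <= 0))
    stop("vapor_pressure_ice: temperature must be positive and finite")
  if (any(T_i <= 150) || any(T_i >= 273.16 + 1e-9))
    warning("vapor_pressure_ice: temperature outside validity range (150, 273.16] K")
  exp(constants$alpha_pi - constants$beta_pi / T_i +
        constants$gamma_pi * log(T_i) - constants$delta_pi * T_i)
}

#' Latent heat of sublimation of ice
#'
#' Temperature-dependent correlation
#' \deqn{\Delta H_{sub} = \alpha + \beta T_i - \gamma T_i^2 +
#'   \delta e^{-(T_i/\epsilon)^2}}
#'
#' @inheritParams vapor_pressure_ice
#' @return latent heat in J/mol.
#' @export
latent_heat_sublimation <- function(T_i, constants = physical_constants()) {
  stopifnot(inherits(constants, "physical_constants"))
  if (any(!is.finite(T_i)) || any(T_i <= 0))
    stop("latent_heat_sublimation: temperature must be positive and finite")
  constants$alpha_h + constants$beta_h * T_i - constants$gamma_h * T_i^2 +
    constants$delta_h * exp(-(T_i / constants$eps_h)^2)
}

#' Solve the vial-level heat balance for the interface temperature
#'
#' Finds the sublimation-front temperature `T_i` at which the power consumed
#' by sublimation equals the power delivered to the vial:
#' \deqn{P_{tot} = \frac{A_{p,vial}\,(P_i(T_i) - P_c)}{R_{p,vial}}
#'   \cdot \frac{\Delta H_{sub}(T_i)}{M}}
#' The residual is monotone in `T_i`, so a bracketed bisection on
#' `[180, 273.16]` K is guaranteed once a sign change exists.
#'
#' @param P_tot total power delivered to the vial, W (> 0).
#' @param A_p_vial total sublimating area, m^2 (> 0).
#' @param R_p_vial vial-level dried-product resistance, m/s (> 0).
#' @param P_c chamber pressure, Pa.
#' @param constants a [physical_constants()] object.
#' @param bracket search interval for `T_i` in K.
#' @param tol_watt absolute residual tolerance on the power balance, W.
#' @return a list of class `heat_balance_state` with elements `T_i` (K),
#'   `P_i` (Pa), `dH_sub` (J/mol), `m_dot` (total sublimation rate, kg/s),
#'   `residual` (W) plus the inputs `A_p_vial`, `R_p_vial`, `P_c`, `P_tot`.
#' @export
solve_interface_temperature <- function(P_tot, A_p_vial, R_p_vial, P_c,
                                        constants = physical_constants(),
                                        bracket = c(180, 273.16),
                                        tol_watt = 1e-9) {
  if (!is.finite(P_tot) || P_tot <= 0) stop("P_tot must be > 0")
  if (!is.finite(A_p_vial) || A_p_vial <= 0) stop("A_p_vial must be > 0")
  if (!is.finite(R_p_vial) || R_p_vial <= 0) stop("R_p_vial must be > 0")
  resid <- function(T_i) {
    P_i <- suppressWarnings(vapor_pressure_ice(T_i, constants))
    A_p_vial * (P_i - P_c) / R_p_vial *
      latent_heat_sublimation(T_i, constants) / constants$M - P_tot
  }
  lo <- bracket[1L]; hi <- bracket[2L]
  f_lo <- resid(lo); f_hi <- resid(hi)
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo * f_hi > 0)
    stop(sprintf(paste0(
      "solve_interface_temperature: no sign change on [%.2f, %.2f] K ",
      "(residuals %.3g / %.3g W); P_tot may be unreachable at this ",
      "area/resistance/pressure"), lo, hi, f_lo, f_hi))
  # bisection: robust, and the Watt tolerance is checked directly
  for (it in seq_len(200L)) {
    mid <- 0.5 * (lo + hi)
    f_mid <- resid(mid)
    if (abs(f_mid) <= tol_watt) break
    if (f_lo * f_mid <= 0) { hi <- mid; f_hi <- f_mid } else { lo <- mid; f_lo <- f_mid }
  }
  T_i <- mid
  P_i <- suppressWarnings(vapor_pressure_ice(T_i, constants))
  dH <- latent_heat_sublimation(T_i, constants)
  structure(list(T_i = T_i, P_i = P_i, dH_sub = dH,
                 m_dot = A_p_vial * (P_i - P_c) / R_p_vial,
                 residual = resid(T_i),
                 A_p_vial = A_p_vial, R_p_vial = R_p_vial,
                 P_c = P_c, P_tot = P_tot),
            class = "heat_balance_state")
}
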