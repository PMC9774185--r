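#' Goldman-Hodgkin-Katz single-channel current
#'
#' Constant-field current through the channel carried by internal Na+ and
#' external Li+ (the recording configuration: 140 mM LiCl in the pipette
#' facing the extracellular side, ~3 mM Na+ on the cytosolic side).
#' Voltage is membrane potential (intracellular minus extracellular), inward
#' current is negative, and the `V = 0` singularity is evaluated by its
#' analytic limit. The zero-current (reversal) potential satisfies
#' `Erev = (RT/F) log(P_Li [Li]_out / (P_Na [Na]_in))`.
#'
#' The absolute permeability `p_na` is a composite scale in pA per mM (the
#' GHK permeability times area, valence-squared Faraday factors and unit
#' conversions folded together); only its product with concentration and the
#' dimensionless voltage factor is observable in a current.
#'
#' @param voltage_mV Membrane potential(s) in mV.
#' @param p_na Absolute Na+ permeability scale (pA per mM, > 0).
#' @param perm_ratio Permeability ratio P_Li / P_Na (> 0).
#' @param na_in Internal Na+ concentration, mM.
#' @param li_out External Li+ concentration, mM.
#' @param temperature Absolute temperature in K (default 295.15, i.e. 22 C).
#' @return Current(s) in pA, same length as `voltage_mV`.
#' @export
#' @examples
#' ghk_current(c(-100, 0, 50), p_na = 0.05, perm_ratio = 0.56)
ghk_current <- function(voltage_mV, p_na, perm_ratio,
                        na_in = 3, li_out = 140, temperature = 295.15) {
  if (!is.numeric(temperature) || temperature <= 0) {
    rlang::abort("temperature must be positive (K)")
  }
  if (any(c(na_in, li_out) < 0)) rlang::abort("concentrations must be >= 0")
  if (p_na <= 0 || perm_ratio <= 0) {
    rlang::abort("permeabilities must be positive")
  }
  u <- ghk_u(voltage_mV, temperature)
  p_na * (ghk_flux_shape(u, c_in = na_in, c_out = 0) +
            perm_ratio * ghk_flux_shape(u, c_in = 0, c_out = li_out))
}

# dimensionless voltage FV/RT
ghk_u <- function(voltage_mV, temperature) {
  (voltage_mV / 1000) * 96485.332 / (8.314463 * temperature)
}

# u (c_in - c_out e^{-u}) / (1 - e^{-u}), with the analytic u -> 0 limit
ghk_flux_shape <- function(u, c_in, c_out) {
  out <- numeric(length(u))
  small <- abs(u) < 1e-6
  out[small] <- (c_in - c_out) + u[small] * (c_in + c_out) / 2
  ub <- u[!small]
  out[!small] <- ub * (c_in - c_out * exp(-ub)) / (1 - exp(-ub))
  out
}

#' Reversal potential of the two-ion GHK current
#'
#' @inheritParams ghk_current
#' @return Reversal potential in mV.
#' @export
#' @examples
#' ghk_reversal(0.560) # about +83 mV for 140 Li out / 3 Na in at 22 C
ghk_reversal <- function(perm_ratio, na_in = 3, li_out = 140,
                         temperature = 295.15) {
  rt_f <- 1000 * 8.314463 * temperature / 96485.332 # mV
  rt_f * log(perm_ratio * li_out / na_in)
}

#' Calibrate GHK generative parameters to target observables
#'
#' `perm_ratio_for_reversal()` inverts the reversal-potential relation to the
#' permeability ratio producing a target `Erev`. `p_na_for_conductance()`
#' scales the absolute permeability so the noiseless GHK curve's
#' least-squares slope on a voltage window (1 mV grid) equals a target slope
#' conductance in pS. Both are used to turn the published reversal potential
#' and unit conductance into generative simulation parameters.
#'
#' @param erev_mV Target reversal potential, mV.
#' @param g_pS Target slope conductance, pS.
#' @param perm_ratio Permeability ratio P_Li/P_Na.
#' @param v_lo,v_hi Window over which the slope is measured, mV.
#' @inheritParams ghk_current
#' @return A single numeric parameter value.
#' @export
#' @examples
#' r <- perm_ratio_for_reversal(83)
#' p <- p_na_for_conductance(6.6, r)
perm_ratio_for_reversal <- function(erev_mV, na_in = 3, li_out = 140,
                                    temperature = 295.15) {
  rt_f <- 1000 * 8.314463 * temperature / 96485.332
  exp(erev_mV / rt_f) * na_in / li_out
}

#' @rdname perm_ratio_for_reversal
#' @export
p_na_for_conductance <- function(g_pS, perm_ratio, v_lo = -120, v_hi = -40,
                                 na_in = 3, li_out = 140,
                                 temperature = 295.15) {
  grid <- seq(v_lo, v_hi, by = 1)
  i_unit <- ghk_current(grid, p_na = 1, perm_ratio = perm_ratio,
                        na_in = na_in, li_out = li_out,
                        temperature = temperature)
  slope_unit <- stats::coef(stats::lm(i_unit ~ grid))[["grid"]] # pA/mV = nS
  (g_pS / 1000) / slope_unit
}
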