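R_KCAL <- 1.987e-3 # kcal mol^-1 K^-1

#' Electrostatic binding energy from a dissociation constant
#'
#' Depth of the energy well holding PIP2 near a polybasic effector domain:
#' `deltaG = R T ln(C0 / Kd)` with standard state `C0 = 1 mol/L` and
#' `R = 1.987e-3 kcal/(mol K)`. A reported MLP-1/PIP2 dissociation constant
#' of 10-30 uM translates to a well of roughly 6-7 kcal/mol at 20 C.
#'
#' @param kd_uM Dissociation constant in uM (> 0).
#' @param temperature Absolute temperature in K (default 293.15, i.e. 20 C).
#' @return A one-row tibble: `kd_uM`, `temperature_K`, `delta_g_kcal`.
#' @export
#' @examples
#' binding_energy(15) # about 6.47 kcal/mol
binding_energy <- function(kd_uM, temperature = 293.15) {
  if (any(kd_uM <= 0)) rlang::abort("Kd must be positive")
  if (any(temperature <= 0)) rlang::abort("temperature must be positive (K)")
  tibble::tibble(
    kd_uM = kd_uM,
    temperature_K = temperature,
    delta_g_kcal = R_KCAL * temperature * log(1e6 / kd_uM)
  )
}

#' Boltzmann local-concentration enhancement of a binding well
#'
#' `exp(deltaG / (R T)) = C0 / Kd`: the factor by which the equilibrium
#' local concentration of the ligand inside the well exceeds its bulk
#' membrane concentration. For a 15 uM well this is about 6.7e4, comfortably
#' more than the hundred-fold enrichment needed to explain observed channel
#' opening rates.
#'
#' @param well A [binding_energy()] row (or any data frame with
#'   `delta_g_kcal` and `temperature_K`).
#' @return Numeric enhancement factor(s).
#' @export
#' @examples
#' enhancement_factor(binding_energy(15))
enhancement_factor <- function(well) {
  stopifnot(all(c("delta_g_kcal", "temperature_K") %in% names(well)))
  exp(well$delta_g_kcal / (R_KCAL * well$temperature_K))
}

#' Diffusion-limited encounter time between PIP2 and a channel
#'
#' Mean time for a channel to encounter a PIP2 molecule by pure lateral
#' diffusion, with no electrostatic sequestration. Each channel is assigned
#' a disc of radius `b = (pi * channel_density)^(-1/2)` (the area it "owns"
#' in the membrane); the mean capture time of a single diffuser started
#' uniformly in the disc with an absorbing trap of radius `a` at the centre
#' and a reflecting outer boundary is
#' `tau1 = (b^2 / (2 D)) (ln(b/a) - 3/4)`, and the mean first arrival of any
#' of the `N = pip2_mole_fraction * lipid_density / channel_density`
#' independent diffusers in the disc is approximately `tau1 / N`.
#' All intermediate terms are returned. The estimate is homogeneous in the
#' geometry: scaling every length by `c` and `D` by `c^2` leaves it
#' unchanged.
#'
#' With measured membrane parameters (about 7 channels per um^2, PIP2 at 1
#' per 1000 lipids, D = 4 um^2/s) this model yields sub-millisecond
#' encounter times; it is a deliberately simple capture model and is not
#' calibrated to reproduce any published encounter interval.
#'
#' @param channel_density Channels per um^2 (> 0).
#' @param diffusion_um2_s PIP2 lateral diffusion constant, um^2/s (> 0).
#' @param pip2_mole_fraction PIP2 fraction of membrane lipids, in (0, 1].
#' @param lipid_density Lipids per um^2 in the leaflet (> 0).
#' @param capture_radius_nm Capture (reaction) radius in nm (> 0, and small
#'   compared to the inter-channel half-spacing `b`).
#' @return A one-row tibble: `b_um`, `capture_radius_um`, `tau_single_s`,
#'   `n_diffusers`, `tau_encounter_s`.
#' @export
#' @examples
#' encounter_time()
encounter_time <- function(channel_density = 7, diffusion_um2_s = 4,
                           pip2_mole_fraction = 1e-3, lipid_density = 2e6,
                           capture_radius_nm = 1) {
  vals <- c(channel_density, diffusion_um2_s, pip2_mole_fraction,
            lipid_density, capture_radius_nm)
  if (any(vals <= 0)) rlang::abort("all parameters must be positive")
  if (pip2_mole_fraction > 1) rlang::abort("mole fraction must be <= 1")
  b <- 1 / sqrt(pi * channel_density) # um
  a <- capture_radius_nm / 1000 # um
  if (b <= a) {
    rlang::abort("capture radius must be smaller than the channel spacing")
  }
  tau1 <- (b^2 / (2 * diffusion_um2_s)) * (log(b / a) - 3 / 4)
  n_diff <- pip2_mole_fraction * lipid_density / channel_density
  tibble::tibble(
    b_um = b,
    capture_radius_um = a,
    tau_single_s = tau1,
    n_diffusers = n_diff,
    tau_encounter_s = tau1 / n_diff
  )
}
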