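#' Hill dose-response mean
#'
#' `Po = Pmax / (1 + (K05/L)^n)`, with the `L = 0` case evaluated in the
#' limit (Po = 0).
#'
#' @param concentration Ligand concentration(s), uM (>= 0).
#' @param pmax Maximal open probability, in (0, 1].
#' @param k05 Half-activating concentration, uM (> 0).
#' @param n_hill Hill coefficient (> 0).
#' @return Open probability, same length as `concentration`.
#' @export
hill_po <- function(concentration, pmax, k05, n_hill) {
  ifelse(concentration <= 0, 0, pmax / (1 + (k05 / concentration)^n_hill))
}

#' Simulate a dose-response dataset
#'
#' Draws replicate open probabilities at each concentration as Hill means
#' plus Gaussian noise, clipped to `[0, 1]`. The defaults reproduce the study
#' conditions under which the dose-response was measured: 5 concentrations
#' (0-50 uM PIP2), 11 patches per concentration, and generative parameters
#' equal to the published fit (Pmax 0.411, K0.5 22 uM, n 2.5).
#'
#' @inheritParams hill_po
#' @param concentrations Concentration grid, uM.
#' @param replicates Replicates per concentration.
#' @param noise_sd Gaussian noise s.d. on Po.
#' @param seed Optional integer seed.
#' @return A tibble with columns `concentration`, `replicate`, `po`.
#' @export
#' @examples
#' dr <- simulate_dose_response(seed = 1)
#' fit_hill(dr)
simulate_dose_response <- function(pmax = 0.411, k05 = 22, n_hill = 2.5,
                                   concentrations = c(0, 10, 20, 30, 50),
                                   replicates = 11L, noise_sd = 0.02,
                                   seed = NULL) {
  if (pmax <= 0 || pmax > 1) rlang::abort("pmax must lie in (0, 1]")
  if (k05 <= 0) rlang::abort("k05 must be positive")
  if (n_hill <= 0) rlang::abort("n_hill must be positive")
  if (any(concentrations < 0)) rlang::abort("concentrations must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  out <- tidyr::expand_grid(
    concentration = as.numeric(concentrations),
    replicate = seq_len(replicates)
  )
  mu <- hill_po(out$concentration, pmax, k05, n_hill)
  po <- mu + if (noise_sd > 0) stats::rnorm(nrow(out), 0, noise_sd) else 0
  out$po <- pmin(pmax(po, 0), 1)
  attr(out, "truth") <- list(pmax = pmax, k05 = k05, n_hill = n_hill,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate a single-channel current-voltage dataset
#'
#' GHK means plus Gaussian noise at each voltage, for the asymmetric
#' Li+(out)/Na+(in) recording solutions.
#'
#' @inheritParams ghk_current
#' @param voltages Test potentials, mV (at least 4 distinct values).
#' @param noise_sd Gaussian noise s.d., pA.
#' @param seed Optional integer seed.
#' @return A tibble with columns `voltage_mV`, `current_pA`.
#' @export
#' @examples
#' ratio <- perm_ratio_for_reversal(83)
#' iv <- simulate_iv(p_na_for_conductance(6.6, ratio), ratio, seed = 1)
#' fit_ghk(iv)
simulate_iv <- function(p_na, perm_ratio,
                        voltages = seq(-120, 60, length.out = 10),
                        na_in = 3, li_out = 140, temperature = 295.15,
                        noise_sd = 0.05, seed = NULL) {
  if (length(unique(voltages)) < 4L) {
    rlang::abort("at least 4 distinct voltages are required")
  }
  if (!is.null(seed)) set.seed(seed)
  mu <- ghk_current(voltages, p_na, perm_ratio, na_in = na_in,
                    li_out = li_out, temperature = temperature)
  out <- tibble::tibble(
    voltage_mV = as.numeric(voltages),
    current_pA = mu + if (noise_sd > 0) {
      stats::rnorm(length(voltages), 0, noise_sd)
    } else 0
  )
  attr(out, "truth") <- list(p_na = p_na, perm_ratio = perm_ratio,
                             na_in = na_in, li_out = li_out,
                             temperature = temperature, noise_sd = noise_sd,
                             seed = seed)
  out
}
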