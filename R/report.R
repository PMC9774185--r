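#' End-to-end analysis report
#'
#' Runs the full pipeline on self-generated data with known ground truth and
#' collects every intermediate result into one nested list suitable for JSON
#' serialization: gating-scheme equilibrium properties, a simulated and
#' re-idealized patch with NPo and dwell statistics, a Hill dose-response fit,
#' a GHK current-voltage fit with slope conductance, a two-channel
#' colocalization report, and the electrostatic sequestration quantities.
#' Given the same seed the report is identical between runs. Units are fixed
#' package-wide: ms, pA, uM, mV (membrane convention), K.
#'
#' @param seed Integer seed controlling every stochastic stage (required).
#' @param patch_duration_ms Length of the simulated patch recording.
#' @param out Optional path; when given, the report is also written as JSON.
#' @return A nested list (invisibly when `out` is given).
#' @export
#' @examples
#' rep <- pipeline_report(seed = 1, patch_duration_ms = 20000)
#' rep$activity$npo
pipeline_report <- function(seed, patch_duration_ms = 6e4, out = NULL) {
  if (missing(seed) || !is.numeric(seed)) {
    rlang::abort("an integer seed is required")
  }
  seed <- as.integer(seed)
  cfg <- list(
    seed = seed,
    units = list(time = "ms", current = "pA", concentration = "uM",
                 voltage = "mV", temperature = "K"),
    package_version = as.character(utils::packageVersion("pipgate"))
  )

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
  }

  scheme <- coo_scheme(0.001, 0.01, 0.0005, 0.005)
  kinetics <- run_stage("kinetics", {
    sj <- sojourn_means(scheme, 20)
    list(
      po_at_20uM = open_probability(scheme, 20),
      mean_open_ms = sj$mean_open,
      mean_closed_ms = sj$mean_closed,
      hill_slope_at_20uM = hill_slope_local(scheme, 20)
    )
  })

  patch <- run_stage("patch", {
    sim <- simulate_patch(scheme, L = 20, duration_ms = patch_duration_ms,
                          unit_current = -0.5, noise_sd = 0.1,
                          filter_cutoff = 1000, seed = seed)
    # known single-channel patch: idealize on one conductance level
    ev <- idealize(sim$trace, unit_current = -0.5, max_levels = 1)
    act <- channel_activity(sim$trace, unit_current = -0.5)
    dw <- dwell_summary(ev)
    list(sim = sim, events = ev, activity = act, dwell = dw)
  })

  hill <- run_stage("hill", {
    dr <- simulate_dose_response(seed = seed + 1L)
    fit <- fit_hill(dr)
    list(estimates = tidy(fit), r_squared = fit$r_squared)
  })

  ghk <- run_stage("ghk", {
    ratio <- perm_ratio_for_reversal(83)
    p_na <- p_na_for_conductance(6.6, ratio)
    iv <- simulate_iv(p_na, ratio, seed = seed + 2L)
    fit <- fit_ghk(iv)
    list(estimates = tidy(fit),
         slope_conductance = slope_conductance(fit))
  })

  coloc <- run_stage("coloc", {
    pair <- simulate_image_pair(coloc_fraction = 0.5, seed = seed + 3L)
    tidy(coloc_report(pair))
  })

  electro <- run_stage("electrostatics", {
    well <- binding_energy(15)
    list(
      energy_well = well,
      enhancement = enhancement_factor(well),
      encounter = encounter_time()
    )
  })

  report <- list(
    config = cfg,
    kinetics = kinetics,
    activity = c(
      as.list(patch$activity),
      list(npo_truth = compute_npo(patch$sim$events))
    ),
    dwell = as.list(patch$dwell),
    hill = hill,
    ghk = ghk,
    colocalization = coloc,
    electrostatics = electro
  )
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         force = TRUE, null = "null")
    return(invisible(report))
  }
  report
}
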