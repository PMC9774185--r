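#' Fit the GHK current equation to a single-channel I-V dataset
#'
#' Least-squares fit of the two-ion constant-field current over the absolute
#' Na+ permeability scale and the Li+/Na+ permeability ratio. The reversal
#' potential is computed analytically from the fitted ratio and the ion
#' concentrations (with a delta-method standard error); it equals the root of
#' the fitted current function. Multi-start over the ratio guards against
#' local minima. If the currents do not bracket zero, the fit proceeds with a
#' warning and the reversal potential is an extrapolation.
#'
#' @param data A data frame with columns `voltage_mV` and `current_pA`
#'   (>= 4 distinct voltages).
#' @inheritParams ghk_current
#' @return An object of class `ghk_fit` with fitted `p_na`, `perm_ratio`,
#'   `erev` (mV), their standard errors, and the input data. See [tidy()],
#'   [glance()], [autoplot()], [slope_conductance()].
#' @export
#' @examples
#' ratio <- perm_ratio_for_reversal(83)
#' iv <- simulate_iv(p_na_for_conductance(6.6, ratio), ratio, seed = 1)
#' fit <- fit_ghk(iv)
#' slope_conductance(fit)
fit_ghk <- function(data, na_in = 3, li_out = 140, temperature = 295.15) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("voltage_mV", "current_pA") %in% names(data)))
  if (length(unique(data$voltage_mV)) < 4L) {
    rlang::abort("at least 4 distinct voltages are required")
  }
  if (all(data$current_pA > 0) || all(data$current_pA < 0)) {
    rlang::warn(paste("currents do not bracket zero;",
                      "the reversal potential is extrapolated"))
  }

  best <- NULL
  for (r0 in c(0.1, 0.5, 1, 2)) {
    # p_na is conditionally linear: start it at the OLS value given r0
    shape <- ghk_current(data$voltage_mV, 1, r0, na_in, li_out, temperature)
    p0 <- sum(shape * data$current_pA) / sum(shape^2)
    if (!is.finite(p0) || p0 <= 0) p0 <- 0.01
    fit <- tryCatch(
      minpack.lm::nlsLM(
        current_pA ~ ghk_current(voltage_mV, p_na, perm_ratio,
                                 na_in, li_out, temperature),
        data = data,
        start = list(p_na = p0, perm_ratio = r0),
        lower = c(p_na = 1e-12, perm_ratio = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) rlang::abort("GHK fit failed to converge")

  fit <- best$fit
  cf <- stats::coef(fit)
  vc <- stats::vcov(fit)
  rt_f <- 1000 * 8.314463 * temperature / 96485.332
  erev <- ghk_reversal(cf[["perm_ratio"]], na_in, li_out, temperature)
  erev_se <- rt_f * sqrt(vc["perm_ratio", "perm_ratio"]) / cf[["perm_ratio"]]

  structure(
    list(
      fit = fit, data = data,
      p_na = cf[["p_na"]], perm_ratio = cf[["perm_ratio"]],
      se = c(p_na = sqrt(vc["p_na", "p_na"]),
             perm_ratio = sqrt(vc["perm_ratio", "perm_ratio"])),
      vcov = vc,
      erev = erev, erev_se = erev_se,
      na_in = na_in, li_out = li_out, temperature = temperature,
      rss = best$rss, nobs = nrow(data)
    ),
    class = "ghk_fit"
  )
}

#' @export
print.ghk_fit <- function(x, ...) {
  g <- slope_conductance(x)
  cat(sprintf(
    paste0("<ghk_fit> P_Li/P_Na = %.3f (se %.3f), Erev = %.1f mV (se %.2f),",
           " slope conductance %.2f pS on [-120, -40] mV\n"),
    x$perm_ratio, x$se[["perm_ratio"]], x$erev, x$erev_se, g$conductance_pS
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ghk_fit <- function(x, ...) {
  tibble::tibble(
    term = c("p_na", "perm_ratio", "erev_mV"),
    estimate = c(x$p_na, x$perm_ratio, x$erev),
    std.error = c(unname(x$se), x$erev_se)
  )
}

#' @exportS3Method generics::glance
glance.ghk_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, nobs = x$nobs, erev_mV = x$erev,
                 temperature_K = x$temperature)
}

#' @export
predict.ghk_fit <- function(object, voltage_mV = NULL, ...) {
  if (is.null(voltage_mV)) voltage_mV <- object$data$voltage_mV
  ghk_current(voltage_mV, object$p_na, object$perm_ratio,
              object$na_in, object$li_out, object$temperature)
}

#' @exportS3Method ggplot2::autoplot
autoplot.ghk_fit <- function(object, ...) {
  rng <- range(object$data$voltage_mV)
  grid <- tibble::tibble(voltage_mV = seq(rng[1], rng[2], length.out = 200))
  grid$current_pA <- predict(object, grid$voltage_mV)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$voltage_mV, y = .data$current_pA)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(
      x = "Membrane potential (mV)", y = "Current (pA)",
      title = sprintf("GHK fit: Erev = %.1f mV", object$erev)
    ) +
    ggplot2::theme_minimal()
}

#' Slope conductance of a fitted I-V curve
#'
#' Least-squares slope of the fitted GHK current on a 1 mV grid over
#' `[v_lo, v_hi]` (default the -120 to -40 mV window used for the published
#' unit conductance), converted to picosiemens. The standard error propagates
#' the fit covariance through a numerical gradient.
#'
#' @param fit A `ghk_fit`.
#' @param v_lo,v_hi Window bounds in mV (`v_lo < v_hi`).
#' @return A one-row tibble with `conductance_pS`, `std.error`, `v_lo`,
#'   `v_hi`.
#' @export
slope_conductance <- function(fit, v_lo = -120, v_hi = -40) {
  stopifnot(inherits(fit, "ghk_fit"))
  if (v_lo >= v_hi) rlang::abort("v_lo must be less than v_hi")
  rng <- range(fit$data$voltage_mV)
  if (v_lo < rng[1] - 20 || v_hi > rng[2] + 20) {
    rlang::warn("conductance window extends well beyond the fitted data")
  }
  grid <- seq(v_lo, v_hi, by = 1)
  slope_of <- function(p_na, perm_ratio) {
    i <- ghk_current(grid, p_na, perm_ratio, fit$na_in, fit$li_out,
                     fit$temperature)
    stats::coef(stats::lm(i ~ grid))[["grid"]] * 1000 # pA/mV -> pS
  }
  g <- slope_of(fit$p_na, fit$perm_ratio)
  # delta method with a numerical gradient
  h <- c(fit$p_na, fit$perm_ratio) * 1e-5
  grad <- c(
    (slope_of(fit$p_na + h[1], fit$perm_ratio) -
       slope_of(fit$p_na - h[1], fit$perm_ratio)) / (2 * h[1]),
    (slope_of(fit$p_na, fit$perm_ratio + h[2]) -
       slope_of(fit$p_na, fit$perm_ratio - h[2])) / (2 * h[2])
  )
  se <- sqrt(drop(t(grad) %*% fit$vcov %*% grad))
  tibble::tibble(conductance_pS = g, std.error = se, v_lo = v_lo, v_hi = v_hi)
}
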