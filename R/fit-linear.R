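#' Linear fit of a gating rate against ligand concentration
#'
#' Ordinary least squares of a rate (e.g. the opening rate, the reciprocal
#' mean closed time) on concentration, with slope/intercept standard errors
#' and a two-sided t-test p-value for the slope. Under the sequential gating
#' schemes the opening rate is `k1 L`, so the slope estimates the
#' pseudo-first-order binding coefficient.
#'
#' @param data A data frame with columns `concentration` and `rate`
#'   (>= 3 points).
#' @return An object of class `rate_fit` wrapping the `lm` fit.
#' @export
#' @examples
#' d <- tibble::tibble(concentration = c(10, 20, 50),
#'                     rate = 1 / c(100, 50, 20))
#' tidy(linear_rate_fit(d))
linear_rate_fit <- function(data) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("concentration", "rate") %in% names(data)))
  if (nrow(data) < 3L) rlang::abort("at least 3 points are required")
  if (length(unique(data$concentration)) < 2L) {
    rlang::abort("design is singular: concentrations do not vary")
  }
  fit <- stats::lm(rate ~ concentration, data = data)
  cf <- summary(fit)$coefficients
  structure(
    list(
      fit = fit, data = data,
      slope = cf["concentration", "Estimate"],
      slope_se = cf["concentration", "Std. Error"],
      intercept = cf["(Intercept)", "Estimate"],
      intercept_se = cf["(Intercept)", "Std. Error"],
      p_value = cf["concentration", "Pr(>|t|)"],
      nobs = nrow(data)
    ),
    class = "rate_fit"
  )
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("<rate_fit> slope = %.3g (se %.3g), p = %.3g\n",
              x$slope, x$slope_se, x$p_value))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rate_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se),
    p.value = c(summary(x$fit)$coefficients["(Intercept)", "Pr(>|t|)"],
                x$p_value)
  )
}

#' @exportS3Method generics::glance
glance.rate_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(r.squared = s$r.squared, sigma = s$sigma, nobs = x$nobs,
                 p.value = x$p_value)
}

#' @exportS3Method ggplot2::autoplot
autoplot.rate_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$concentration, y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::labs(x = "[PIP2] (uM)", y = "Rate (1/ms)") +
    ggplot2::theme_minimal()
}
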