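#' Dwell-time summary of a single-channel record
#'
#' Arithmetic means, standard deviations and counts of the open and closed
#' sojourn durations of a single-channel event list. The first and last
#' events are excluded as censored (their true durations extend beyond the
#' record). Multi-channel records (any level above 1) are rejected: per-event
#' dwell times are only meaningful when the record contains one channel.
#'
#' @param events An `event_list` from [idealize()] or [superpose_paths()].
#' @return A one-row tibble: `mean_open`, `mean_closed`, `sd_open`,
#'   `sd_closed` (ms), `n_open_events`, `n_closed_events`.
#' @export
#' @examples
#' sim <- simulate_patch(co_scheme(0.001, 0.02), L = 20, duration_ms = 1e5,
#'                       unit_current = -0.5, seed = 11)
#' dwell_summary(sim$events)
dwell_summary <- function(events) {
  if (!nrow(events)) rlang::abort("event list is empty")
  if (max(events$level) > 1L) {
    rlang::abort(paste(
      "record contains more than one channel;",
      "per-channel dwell analysis requires a single-channel record",
      "(consider burst analysis for multi-channel patches)"
    ))
  }
  ev <- events
  if (nrow(ev) > 2) ev <- ev[-c(1L, nrow(ev)), ] # censored sojourns
  open_d <- ev$duration_ms[ev$level == 1L]
  closed_d <- ev$duration_ms[ev$level == 0L]
  tibble::tibble(
    mean_open = mean(open_d),
    mean_closed = mean(closed_d),
    sd_open = stats::sd(open_d),
    sd_closed = stats::sd(closed_d),
    n_open_events = length(open_d),
    n_closed_events = length(closed_d)
  )
}

#' Maximum-likelihood exponential-mixture fit to dwell times
#'
#' Fits a mixture of 1-3 exponential components to a set of dwell durations
#' by expectation-maximization. The aggregated open class of the sequential
#' two-site scheme predicts a two-exponential open-time density, so comparing
#' one- and two-component fits by likelihood ratio tests for multiple open
#' states. The EM iterations never decrease the log-likelihood; convergence
#' is declared when the gain drops below `tol` (default 1e-8) or after
#' `max_iter` iterations. Five random restarts are run and the best
#' likelihood kept.
#'
#' @param durations Positive dwell times, ms (>= 50 values).
#' @param n_components 1, 2 or 3.
#' @param seed Optional seed for the restarts.
#' @param max_iter,tol EM stopping rule.
#' @param n_starts Number of random restarts.
#' @return An object of class `exp_mixture_fit` with elements `components`
#'   (tibble `weight`, `tau` sorted by tau), `log_likelihood`,
#'   `n_iterations`, `converged`, `n`.
#' @export
#' @examples
#' set.seed(1)
#' d <- c(rexp(300, 1 / 10), rexp(300, 1 / 200))
#' fit <- fit_exponential_mixture(d, 2, seed = 1)
#' tidy(fit)
fit_exponential_mixture <- function(durations, n_components, seed = NULL,
                                    max_iter = 500L, tol = 1e-8,
                                    n_starts = 5L) {
  durations <- as.numeric(durations)
  if (length(durations) < 50L) {
    rlang::abort("at least 50 durations are required")
  }
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    rlang::abort("durations must be positive")
  }
  if (!n_components %in% 1:3) rlang::abort("n_components must be 1, 2 or 3")
  if (stats::sd(durations) == 0) {
    rlang::abort("degenerate data: all durations are equal")
  }
  if (!is.null(seed)) set.seed(seed)

  k <- n_components
  if (k == 1L) {
    tau <- mean(durations)
    ll <- sum(stats::dexp(durations, 1 / tau, log = TRUE))
    return(new_exp_mixture_fit(tibble::tibble(weight = 1, tau = tau),
                               ll, 1L, TRUE, length(durations)))
  }

  best <- NULL
  for (s in seq_len(n_starts)) {
    # initialize taus spread over the quantiles, jittered per restart
    qs <- stats::quantile(durations, probs = seq(0.15, 0.9, length.out = k),
                          names = FALSE)
    tau <- qs * exp(stats::rnorm(k, 0, 0.3))
    w <- rep(1 / k, k)
    ll_old <- -Inf
    converged <- FALSE
    iter <- 0L
    while (iter < max_iter) {
      iter <- iter + 1L
      # E-step in log space
      logd <- vapply(seq_len(k), function(j) {
        log(w[j]) + stats::dexp(durations, 1 / tau[j], log = TRUE)
      }, numeric(length(durations)))
      m <- apply(logd, 1, max)
      lse <- m + log(rowSums(exp(logd - m)))
      resp <- exp(logd - lse)
      ll <- sum(lse)
      # M-step
      nk <- colSums(resp)
      w <- nk / length(durations)
      tau <- colSums(resp * durations) / nk
      if (is.finite(ll_old) && ll - ll_old < tol) {
        converged <- TRUE
        ll_old <- ll
        break
      }
      ll_old <- ll
    }
    if (is.null(best) || ll_old > best$ll) {
      best <- list(w = w, tau = tau, ll = ll_old, iter = iter,
                   converged = converged)
    }
  }
  ord <- order(best$tau)
  new_exp_mixture_fit(
    tibble::tibble(weight = best$w[ord], tau = best$tau[ord]),
    best$ll, best$iter, best$converged, length(durations)
  )
}

new_exp_mixture_fit <- function(components, ll, iter, converged, n) {
  structure(
    list(components = components, log_likelihood = ll, n_iterations = iter,
         converged = converged, n = n),
    class = "exp_mixture_fit"
  )
}

#' @export
print.exp_mixture_fit <- function(x, ...) {
  cat(sprintf("<exp_mixture_fit> %d component(s), logLik %.2f, %s\n",
              nrow(x$components), x$log_likelihood,
              if (x$converged) "converged" else "NOT converged"))
  print(x$components)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.exp_mixture_fit <- function(x, ...) {
  dplyr::mutate(x$components, component = dplyr::row_number(),
                .before = 1L)
}

#' @exportS3Method generics::glance
glance.exp_mixture_fit <- function(x, ...) {
  tibble::tibble(
    log_likelihood = x$log_likelihood,
    n_components = nrow(x$components),
    n_iterations = x$n_iterations,
    converged = x$converged,
    nobs = x$n
  )
}

#' Recover rate constants from a dwell-time titration
#'
#' Given dwell-time summaries at three or more ligand concentrations, exploits
#' the closed forms of the sequential two-site scheme: the opening rate
#' `1/mean_closed` equals `k1 L` (regression through the origin gives `k1`),
#' and `mean_open = 1/k_1 + (k2/(k_2 k_1)) L` (the intercept gives `k_1`, the
#' slope times `k_1` gives the ratio `k2/k_2`). Only the ratio `k2/k_2` is
#' identifiable from class means; the individual stabilization rates are not.
#'
#' @param summaries A data frame with columns `concentration` (uM, > 0,
#'   at least 3 distinct values), `mean_open` and `mean_closed` (ms), e.g.
#'   one [dwell_summary()] row per concentration.
#' @return A tibble with columns `term` (`"k1"`, `"k_1"`, `"k2_over_k_2"`),
#'   `estimate` and `std.error` (delta-method for the derived terms).
#' @export
#' @examples
#' tit <- tibble::tibble(
#'   concentration = c(10, 20, 50),
#'   mean_open = c(200, 300, 600),
#'   mean_closed = c(100, 50, 20)
#' )
#' recover_rates_from_titration(tit)
recover_rates_from_titration <- function(summaries) {
  s <- tibble::as_tibble(summaries)
  stopifnot(all(c("concentration", "mean_open", "mean_closed") %in% names(s)))
  if (length(unique(s$concentration)) < 3L) {
    rlang::abort("at least 3 distinct concentrations are required")
  }
  if (any(s$concentration <= 0)) rlang::abort("concentrations must be > 0")

  opening_rate <- 1 / s$mean_closed
  fit_open_rate <- stats::lm(opening_rate ~ 0 + concentration, data = s)
  k1 <- stats::coef(fit_open_rate)[["concentration"]]
  k1_se <- summary(fit_open_rate)$coefficients["concentration", "Std. Error"]

  fit_open_time <- stats::lm(mean_open ~ concentration, data = s)
  cf <- stats::coef(fit_open_time)
  vc <- stats::vcov(fit_open_time)
  intercept <- cf[["(Intercept)"]]
  slope <- cf[["concentration"]]
  if (intercept <= 0) {
    rlang::abort("mean-open intercept is non-positive; cannot recover k_1")
  }
  k_1 <- 1 / intercept
  k_1_se <- sqrt(vc[1, 1]) / intercept^2
  ratio <- slope / intercept # slope * k_1
  grad <- c(-slope / intercept^2, 1 / intercept)
  ratio_se <- sqrt(drop(t(grad) %*% vc %*% grad))

  tibble::tibble(
    term = c("k1", "k_1", "k2_over_k_2"),
    estimate = c(k1, k_1, ratio),
    std.error = c(k1_se, k_1_se, ratio_se)
  )
}
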