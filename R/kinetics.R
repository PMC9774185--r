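#' Generator (Q) matrix of a gating scheme at a given ligand concentration
#'
#' Off-diagonal entries are the effective transition rates
#' `coefficient * L^ligand_order` (per ms); diagonal entries are set so every
#' row sums to zero.
#'
#' @param scheme A [gating_scheme()].
#' @param L Ligand concentration in uM (single value, >= 0).
#' @return A square numeric matrix (per ms) with state labels as dimnames.
#' @export
#' @examples
#' generator_matrix(coo_scheme(0.001, 0.01, 0.0005, 0.005), L = 20)
generator_matrix <- function(scheme, L) {
  stopifnot(inherits(scheme, "gating_scheme"))
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L < 0) {
    rlang::abort("L must be a single finite concentration >= 0")
  }
  labels <- scheme$states$label
  n <- length(labels)
  Q <- matrix(0, n, n, dimnames = list(labels, labels))
  tr <- scheme$transitions
  rates <- tr$coefficient * L^tr$ligand_order
  for (i in seq_along(rates)) {
    Q[tr$from[i], tr$to[i]] <- rates[i]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# stationary distribution of an irreducible generator; solves pi Q = 0,
# sum(pi) = 1 by an augmented least-squares system
stationary_distribution <- function(Q) {
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi_hat <- qr.solve(A, b)
  pi_hat[pi_hat < 0 & pi_hat > -1e-12] <- 0
  pi_hat / sum(pi_hat)
}

# states whose exit rate is zero at this L (absorbing)
absorbing_states <- function(Q) which(abs(diag(Q)) < .Machine$double.eps * 10)

#' Stationary open probability
#'
#' Sum of the stationary probabilities of the open-class states. For the
#' sequential two-binding-site scheme ([coo_scheme()]) this equals
#' `(a + a b)/(1 + a + a b)` with `a = k1 L / k_1` and `b = k2 L / k_2`.
#' `L = 0` is handled as a defined degenerate case: with purely
#' ligand-dependent opening the closed state is absorbing and Po is 0
#' (PIP2 is required to open the channel).
#'
#' @inheritParams generator_matrix
#' @param L Ligand concentration(s) in uM; vectorized.
#' @return Numeric vector of open probabilities in `[0, 1]`.
#' @export
#' @examples
#' open_probability(coo_scheme(0.001, 0.01, 0.0005, 0.005), L = c(0, 20))
open_probability <- function(scheme, L) {
  stopifnot(inherits(scheme, "gating_scheme"))
  if (!is.numeric(L) || any(!is.finite(L)) || any(L < 0)) {
    rlang::abort("L must be finite and >= 0")
  }
  open_idx <- which(scheme$states$class == "open")
  vapply(L, function(l) {
    Q <- generator_matrix(scheme, l)
    abs_states <- absorbing_states(Q)
    if (length(abs_states)) {
      # chain is eventually trapped in the absorbing state(s)
      return(as.numeric(any(abs_states %in% open_idx)))
    }
    sum(stationary_distribution(Q)[open_idx])
  }, numeric(1))
}

#' Mean open and closed sojourn times
#'
#' Mean dwell times of the aggregated open and closed conductance classes at
#' stationarity, computed from the stationary distribution and the
#' probability flux between classes: the mean class dwell time equals the
#' stationary occupancy of the class divided by the flux leaving it. For
#' [coo_scheme()] this reduces to `mean_closed = 1/(k1 L)` and
#' `mean_open = (1 + k2 L / k_2) / k_1`; for [co_scheme()]
#' `mean_open = 1/k_1` independent of L.
#'
#' @inheritParams generator_matrix
#' @param L Ligand concentration(s) in uM, strictly positive (at `L = 0` the
#'   closed sojourn is infinite); vectorized.
#' @return A tibble with columns `concentration`, `mean_open`, `mean_closed`
#'   (ms).
#' @export
#' @examples
#' sojourn_means(coo_scheme(0.001, 0.01, 0.0005, 0.005), L = 20)
sojourn_means <- function(scheme, L) {
  stopifnot(inherits(scheme, "gating_scheme"))
  if (!is.numeric(L) || any(!is.finite(L)) || any(L <= 0)) {
    rlang::abort("L must be strictly positive for sojourn means")
  }
  open_idx <- which(scheme$states$class == "open")
  closed_idx <- which(scheme$states$class == "closed")
  res <- purrr::map_dfr(L, function(l) {
    Q <- generator_matrix(scheme, l)
    if (length(absorbing_states(Q))) {
      rlang::abort("scheme is reducible at this concentration")
    }
    pi_hat <- stationary_distribution(Q)
    flux_oc <- sum(pi_hat[open_idx] *
                     rowSums(Q[open_idx, closed_idx, drop = FALSE]))
    flux_co <- sum(pi_hat[closed_idx] *
                     rowSums(Q[closed_idx, open_idx, drop = FALSE]))
    tibble::tibble(
      concentration = l,
      mean_open = sum(pi_hat[open_idx]) / flux_oc,
      mean_closed = sum(pi_hat[closed_idx]) / flux_co
    )
  })
  res
}

#' Equilibrium dose-response curve of a scheme
#'
#' @inheritParams generator_matrix
#' @param concentrations Ligand concentrations in uM (non-empty, >= 0).
#' @return A tibble with columns `concentration` and `po`.
#' @export
#' @examples
#' dose_response_curve(coo_scheme(0.001, 0.01, 0.0005, 0.005),
#'                     c(0, 10, 20, 30, 50))
dose_response_curve <- function(scheme, concentrations) {
  if (length(concentrations) == 0L) {
    rlang::abort("concentration grid must be non-empty")
  }
  tibble::tibble(
    concentration = as.numeric(concentrations),
    po = open_probability(scheme, concentrations)
  )
}

#' Local Hill slope of a scheme's dose-response
#'
#' The logarithmic sensitivity `d log(Po/(1-Po)) / d log L`, evaluated by a
#' central difference. This is the local slope a Hill fit would see; for the
#' sequential two-site scheme it equals `1 + bL/(1 + bL)` with
#' `b = k2/k_2` and therefore lies strictly between 1 and 2 at every finite
#' concentration, so a fitted Hill coefficient above 2 cannot arise from that
#' scheme at equilibrium.
#'
#' @inheritParams generator_matrix
#' @param L Ligand concentration in uM with `0 < Po(L) < 1`.
#' @param rel_step Relative step of the central difference on the log scale.
#' @return A single numeric slope.
#' @export
#' @examples
#' hill_slope_local(coo_scheme(0.001, 0.01, 0.0005, 0.005), L = 20)
hill_slope_local <- function(scheme, L, rel_step = 1e-5) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0) {
    rlang::abort("L must be a single positive concentration")
  }
  po <- open_probability(scheme, L)
  if (po <= 0 || po >= 1) {
    rlang::abort("Po must lie strictly inside (0, 1)")
  }
  l_lo <- L * exp(-rel_step)
  l_hi <- L * exp(rel_step)
  po2 <- open_probability(scheme, c(l_lo, l_hi))
  (stats::qlogis(po2[2]) - stats::qlogis(po2[1])) / (2 * rel_step)
}
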