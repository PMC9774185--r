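# Independent oracles used to check closed-form implementations.

# Stationary distribution by eigen-decomposition of t(Q) (null space),
# independent of the package's augmented linear solve.
oracle_stationary <- function(Q) {
  e <- eigen(t(Q))
  i <- which.min(abs(e$values))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

# Mean aggregated-class sojourn by first-step absorption analysis: start from
# the stationary entry distribution into the class, absorb on exit.
oracle_mean_sojourn <- function(Q, class_idx) {
  other <- setdiff(seq_len(nrow(Q)), class_idx)
  pi_hat <- oracle_stationary(Q)
  # entry distribution: flux from outside into each class state
  entry <- colSums(Q[other, class_idx, drop = FALSE] * pi_hat[other])
  entry <- entry / sum(entry)
  sub <- Q[class_idx, class_idx, drop = FALSE]
  drop(entry %*% solve(-sub, rep(1, length(class_idx))))
}

# Peak amplitude of a rectangular pulse of duration w (s) after an ideal
# Gaussian filter with -3 dB cutoff fc (Hz): erf(w / (2 sqrt(2) sigma_t)).
oracle_filtered_peak <- function(w_s, fc_hz) {
  sigma_t <- sqrt(log(2)) / (2 * pi * fc_hz)
  z <- w_s / (2 * sqrt(2) * sigma_t)
  2 * stats::pnorm(z * sqrt(2)) - 1
}

# Monte-Carlo mean capture time for a single diffuser in a disc of radius b
# with an absorbing trap of radius a at the centre and a reflecting rim:
# fixed-step-length 2-D random walk, uniform start in the annulus.
oracle_capture_time_mc <- function(b, a, D, n_walkers = 1000,
                                   step = a / 4, seed = 1) {
  set.seed(seed)
  dt <- step^2 / (4 * D)
  r0 <- sqrt(stats::runif(n_walkers, a^2, b^2))
  th0 <- stats::runif(n_walkers, 0, 2 * pi)
  x <- r0 * cos(th0)
  y <- r0 * sin(th0)
  t_abs <- rep(NA_real_, n_walkers)
  active <- seq_len(n_walkers)
  steps <- 0L
  max_steps <- 2e5L
  while (length(active) && steps < max_steps) {
    steps <- steps + 1L
    ang <- stats::runif(length(active), 0, 2 * pi)
    x[active] <- x[active] + step * cos(ang)
    y[active] <- y[active] + step * sin(ang)
    r <- sqrt(x[active]^2 + y[active]^2)
    out <- r > b
    if (any(out)) { # radial reflection at the rim
      idx <- active[out]
      scale <- (2 * b - r[out]) / r[out]
      x[idx] <- x[idx] * scale
      y[idx] <- y[idx] * scale
      r[out] <- 2 * b - r[out]
    }
    hit <- r < a
    if (any(hit)) {
      t_abs[active[hit]] <- steps * dt
      active <- active[!hit]
    }
  }
  mean(t_abs, na.rm = TRUE)
}

# Hand-built state path (latent trajectory) for rendering tests.
make_path <- function(classes, durations, L = 20) {
  starts <- cumsum(c(0, utils::head(durations, -1)))
  out <- tibble::tibble(
    state = paste0("S", seq_along(classes)),
    class = classes,
    start_ms = starts,
    duration_ms = durations
  )
  attr(out, "total_duration") <- sum(durations)
  attr(out, "L") <- L
  out
}

# Random valid sequential scheme for property sweeps.
random_coo_scheme <- function() {
  coo_scheme(
    k1 = stats::runif(1, 1e-4, 1e-2),
    k_1 = stats::runif(1, 1e-3, 1e-1),
    k2 = stats::runif(1, 1e-4, 1e-2),
    k_2 = stats::runif(1, 1e-3, 1e-1)
  )
}
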