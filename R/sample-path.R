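#' Exact stochastic simulation of a gating scheme
#'
#' Samples a continuous-time Markov trajectory of the channel: in each state
#' the waiting time is exponential with the total exit rate and the
#' destination is chosen with probability proportional to the individual
#' rates. The initial state is drawn from the stationary distribution at the
#' given concentration (recordings analysed downstream are assumed to start
#' in steady state), or can be forced to the first closed state for
#' excision-style protocols. At `L = 0` a ligand-gated scheme has an
#' absorbing closed state and the path is a single everlasting closed
#' sojourn.
#'
#' @inheritParams generator_matrix
#' @param duration_ms Length of the trajectory in ms (> 0).
#' @param seed Optional integer seed; the path is reproducible per seed. If
#'   `NULL` the current RNG stream is used.
#' @param init `"stationary"` (default) or `"closed"`.
#' @return A tibble of sojourns with columns `state`, `class`, `start_ms`,
#'   `duration_ms`, and attributes `total_duration`, `L`, `seed`.
#' @export
#' @examples
#' sample_path(coo_scheme(0.001, 0.01, 0.0005, 0.005), L = 20,
#'             duration_ms = 1000, seed = 1)
sample_path <- function(scheme, L, duration_ms, seed = NULL,
                        init = c("stationary", "closed")) {
  stopifnot(inherits(scheme, "gating_scheme"))
  init <- match.arg(init)
  if (!is.numeric(duration_ms) || length(duration_ms) != 1L ||
      !is.finite(duration_ms) || duration_ms <= 0) {
    rlang::abort("duration_ms must be a single positive number")
  }
  if (!is.null(seed)) set.seed(seed)

  Q <- generator_matrix(scheme, L)
  n <- nrow(Q)
  exit_rate <- -diag(Q)
  # destination probabilities per state
  jump_prob <- Q
  diag(jump_prob) <- 0
  for (i in seq_len(n)) {
    if (exit_rate[i] > 0) jump_prob[i, ] <- jump_prob[i, ] / exit_rate[i]
  }

  if (init == "closed") {
    state <- which(scheme$states$class == "closed")[1L]
  } else if (length(absorbing_states(Q))) {
    state <- absorbing_states(Q)[1L]
  } else {
    state <- sample.int(n, 1L, prob = stationary_distribution(Q))
  }

  cap <- 1024L
  states <- integer(cap)
  starts <- numeric(cap)
  k <- 0L
  t_now <- 0
  while (t_now < duration_ms) {
    k <- k + 1L
    if (k > cap) {
      cap <- cap * 2L
      length(states) <- cap
      length(starts) <- cap
    }
    states[k] <- state
    starts[k] <- t_now
    if (exit_rate[state] <= 0) break # absorbing: sojourn lasts to the end
    t_now <- t_now + stats::rexp(1L, exit_rate[state])
    if (t_now < duration_ms) {
      state <- sample.int(n, 1L, prob = jump_prob[state, ])
    }
  }
  states <- states[seq_len(k)]
  starts <- starts[seq_len(k)]
  durations <- c(diff(starts), duration_ms - starts[k])

  out <- tibble::tibble(
    state = scheme$states$label[states],
    class = scheme$states$class[states],
    start_ms = starts,
    duration_ms = durations
  )
  attr(out, "total_duration") <- duration_ms
  attr(out, "L") <- L
  attr(out, "seed") <- seed
  out
}

#' Time-averaged occupancy of each state along a path
#'
#' @param path A path from [sample_path()].
#' @return A tibble with columns `state` and `occupancy` (fraction of time).
#' @export
path_occupancy <- function(path) {
  dplyr::summarise(
    dplyr::group_by(path, .data$state),
    occupancy = sum(.data$duration_ms) / attr(path, "total_duration"),
    .groups = "drop"
  )
}
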