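#' Render a sampled current trace from state paths
#'
#' Converts one latent state trajectory per channel into a digitized current
#' record: ideal current equals `unit_current` times the number of channels
#' in an open-class state, sampled at `sampling_rate`, low-pass filtered with
#' a Gaussian response whose -3 dB point is `filter_cutoff`, then overlaid
#' with white Gaussian noise. The Gaussian filter attenuates brief events:
#' an isolated opening shorter than the dead time `0.179 / filter_cutoff`
#' never reaches half amplitude and is invisible to half-amplitude
#' idealization, reproducing the flickery, attenuated openings seen at low
#' bandwidth.
#'
#' @param paths A single path from [sample_path()] or a list of paths (one
#'   per channel, equal durations).
#' @param unit_current Single-channel current in pA (negative for inward).
#' @param noise_sd Gaussian noise s.d. in pA (default 0.15 pA r.m.s.).
#' @param filter_cutoff -3 dB cutoff in Hz, or `NULL` for no filtering.
#'   Must satisfy `sampling_rate >= 4 * filter_cutoff`.
#' @param sampling_rate Samples per second (default 4000 Hz).
#' @param seed Optional integer seed for the noise.
#' @return A tibble of class `ion_trace` with columns `time_ms`,
#'   `current_pA` and a `metadata` attribute (L, n_channels, unit_current,
#'   noise_sd, filter_cutoff, sampling_rate, seed).
#' @export
#' @examples
#' p <- sample_path(co_scheme(0.001, 0.01), L = 20, duration_ms = 500,
#'                  seed = 1)
#' tr <- render_trace(p, unit_current = -0.5, noise_sd = 0.1,
#'                    filter_cutoff = 500, seed = 2)
render_trace <- function(paths, unit_current, noise_sd = 0.15,
                         filter_cutoff = 100, sampling_rate = 4000,
                         seed = NULL) {
  if (inherits(paths, "data.frame")) paths <- list(paths)
  if (!length(paths)) rlang::abort("at least one path is required")
  if (unit_current == 0) rlang::abort("unit_current must be non-zero")
  if (noise_sd < 0) rlang::abort("noise_sd must be >= 0")
  if (!is.null(filter_cutoff)) {
    if (filter_cutoff <= 0) rlang::abort("filter_cutoff must be positive")
    if (sampling_rate < 4 * filter_cutoff) {
      rlang::abort("sampling_rate must be at least 4x the filter cutoff")
    }
  }
  durations <- vapply(paths, function(p) attr(p, "total_duration"),
                      numeric(1))
  if (max(durations) - min(durations) > 1e-9) {
    rlang::abort("all channel paths must share the same duration")
  }
  if (!is.null(seed)) set.seed(seed)

  dt <- 1000 / sampling_rate # ms per sample
  n <- floor(durations[1] / dt)
  times <- (seq_len(n) - 1) * dt
  level <- integer(n)
  for (p in paths) {
    idx <- findInterval(times, p$start_ms)
    level <- level + as.integer(p$class[idx] == "open")
  }
  ideal <- unit_current * level
  filtered <- if (is.null(filter_cutoff)) {
    ideal
  } else {
    gaussian_lowpass(ideal, filter_cutoff, sampling_rate)
  }
  current <- filtered + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0

  meta <- list(
    L = attr(paths[[1]], "L"),
    n_channels = length(paths),
    unit_current = unit_current,
    noise_sd = noise_sd,
    filter_cutoff = filter_cutoff,
    sampling_rate = sampling_rate,
    seed = seed
  )
  new_ion_trace(times, current, meta)
}

new_ion_trace <- function(time_ms, current_pA, metadata = list()) {
  out <- tibble::tibble(time_ms = time_ms, current_pA = current_pA)
  class(out) <- c("ion_trace", class(out))
  attr(out, "metadata") <- metadata
  out
}

#' Gaussian low-pass filter with a -3 dB cutoff
#'
#' Zero-phase convolution with a discrete Gaussian kernel whose frequency
#' response falls to 1/sqrt(2) at `cutoff_hz` (time-domain s.d.
#' `sqrt(log 2)/(2 pi f_c)`). Edges are handled by reflection. Kernels
#' narrower than a twentieth of a sample are treated as identity.
#'
#' @param x Numeric vector of samples.
#' @param cutoff_hz -3 dB cutoff frequency, Hz.
#' @param sampling_hz Sampling rate, Hz.
#' @return Filtered vector, same length as `x`.
#' @export
gaussian_lowpass <- function(x, cutoff_hz, sampling_hz) {
  sigma <- sqrt(log(2)) / (2 * pi * cutoff_hz) * sampling_hz # in samples
  if (sigma < 0.05) return(x)
  half <- max(1L, ceiling(4 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  n <- length(x)
  pad_l <- rev(x[seq_len(min(half, n))])
  pad_r <- rev(x[seq(max(1L, n - half + 1L), n)])
  if (length(pad_l) < half) pad_l <- c(rep(x[1], half - length(pad_l)), pad_l)
  if (length(pad_r) < half) pad_r <- c(pad_r, rep(x[n], half - length(pad_r)))
  xp <- c(pad_l, x, pad_r)
  y <- stats::filter(xp, kern, sides = 2)
  as.numeric(y[(half + 1L):(half + n)])
}

#' Ground-truth event list from superposed channel paths
#'
#' Collapses one or more latent state trajectories into the piecewise-constant
#' number of simultaneously open channels, as an event list with the same
#' layout produced by [idealize()].
#'
#' @inheritParams render_trace
#' @return An `event_list` tibble (`level`, `start_ms`, `duration_ms`) with a
#'   `total_time` attribute.
#' @export
superpose_paths <- function(paths) {
  if (inherits(paths, "data.frame")) paths <- list(paths)
  total <- attr(paths[[1]], "total_duration")
  bounds <- sort(unique(c(0, unlist(lapply(paths, function(p) p$start_ms)),
                          total)))
  bounds <- bounds[bounds <= total]
  if (bounds[length(bounds)] < total) bounds <- c(bounds, total)
  mids <- utils::head(bounds, -1) + diff(bounds) / 2
  level <- integer(length(mids))
  for (p in paths) {
    idx <- findInterval(mids, p$start_ms)
    level <- level + as.integer(p$class[idx] == "open")
  }
  r <- rle(level)
  ends <- bounds[-1][cumsum(r$lengths)]
  starts <- c(0, utils::head(ends, -1))
  new_event_list(r$values, starts, ends - starts, total)
}

#' Simulate a multi-channel patch recording
#'
#' Superposes `n_channels` independent channels obeying the same gating
#' scheme, renders the digitized noisy trace, and keeps the ground truth:
#' the per-channel latent paths and the exact superposed event list (used to
#' validate idealization and NPo estimates).
#'
#' @inheritParams generator_matrix
#' @param n_channels Number of independent channels in the patch (>= 1).
#' @param duration_ms Recording length, ms.
#' @inheritParams render_trace
#' @param seed Integer seed controlling both gating and noise.
#' @return A list of class `patch_sim` with elements `trace` (an
#'   [render_trace()] tibble), `events` (ground-truth event list) and
#'   `paths`.
#' @export
#' @examples
#' sim <- simulate_patch(co_scheme(0.001, 0.02), L = 20, duration_ms = 2000,
#'                       unit_current = -0.5, seed = 7)
#' npo_true <- compute_npo(sim$events)
simulate_patch <- function(scheme, L, duration_ms, n_channels = 1L,
                           unit_current = -0.5, noise_sd = 0.1,
                           filter_cutoff = 1000, sampling_rate = 4000,
                           seed = NULL) {
  if (n_channels < 1L) rlang::abort("n_channels must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  paths <- lapply(seq_len(n_channels), function(i) {
    sample_path(scheme, L, duration_ms) # seeded by the stream above
  })
  trace <- render_trace(paths, unit_current = unit_current,
                        noise_sd = noise_sd, filter_cutoff = filter_cutoff,
                        sampling_rate = sampling_rate)
  meta <- attr(trace, "metadata")
  meta$seed <- seed
  attr(trace, "metadata") <- meta
  structure(
    list(trace = trace, events = superpose_paths(paths), paths = paths),
    class = "patch_sim"
  )
}

#' @export
print.patch_sim <- function(x, ...) {
  meta <- attr(x$trace, "metadata")
  cat(sprintf(
    "<patch_sim> %d channel(s), %.0f ms at %g Hz, NPo (truth) = %.3f\n",
    meta$n_channels, attr(x$events, "total_time"), meta$sampling_rate,
    compute_npo(x$events)
  ))
  invisible(x)
}
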