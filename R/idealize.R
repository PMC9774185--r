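new_event_list <- function(level, start_ms, duration_ms, total_time) {
  keep <- duration_ms > 0
  out <- tibble::tibble(
    level = as.integer(level[keep]),
    start_ms = start_ms[keep],
    duration_ms = duration_ms[keep]
  )
  class(out) <- c("event_list", class(out))
  attr(out, "total_time") <- total_time
  out
}

#' Estimate the closed-level baseline of a trace
#'
#' The closed level is taken as the mode of the all-points amplitude
#' histogram (the closed state is assumed to be the most occupied level).
#' The bin width is `noise_sd / 4` when the trace metadata records the noise
#' level, otherwise the Freedman-Diaconis width. A constant trace returns
#' that constant.
#'
#' @param trace An `ion_trace` tibble (or any data frame with `current_pA`).
#' @return Baseline current in pA.
#' @export
estimate_baseline <- function(trace) {
  x <- trace$current_pA
  if (!length(x)) rlang::abort("trace is empty")
  if (max(x) - min(x) < .Machine$double.eps * 100) return(x[1])
  meta <- attr(trace, "metadata")
  bw <- if (!is.null(meta$noise_sd) && is.numeric(meta$noise_sd) &&
            meta$noise_sd > 0) {
    meta$noise_sd / 4
  } else {
    2 * stats::IQR(x) / length(x)^(1 / 3)
  }
  if (bw <= 0) bw <- (max(x) - min(x)) / 100
  breaks <- seq(min(x) - bw, max(x) + bw, by = bw)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  h$mids[which.max(h$counts)]
}

#' Half-amplitude idealization of a current trace
#'
#' Assigns each sample the integer conductance level nearest to
#' `(current - baseline) / unit_current` (i.e. the half-amplitude threshold
#' criterion, generalized to multi-level records), clips levels to
#' `[0, max_levels]`, and merges runs of equal level into events. Events
#' whose filtered amplitude never reaches half of the unit current - those
#' shorter than the dead time `0.179 / f_c` of the Gaussian filter - do not
#' appear in the output.
#'
#' @param trace An `ion_trace` tibble.
#' @param unit_current Single-channel current in pA; its sign must match the
#'   trace polarity.
#' @param max_levels Maximum number of simultaneously open channels.
#' @param baseline Closed-level current in pA; estimated with
#'   [estimate_baseline()] when `NULL`.
#' @return An `event_list` tibble with columns `level`, `start_ms`,
#'   `duration_ms` and attribute `total_time`.
#' @export
#' @examples
#' sim <- simulate_patch(co_scheme(0.001, 0.02), L = 20, duration_ms = 2000,
#'                       unit_current = -0.5, seed = 7)
#' ev <- idealize(sim$trace, unit_current = -0.5)
idealize <- function(trace, unit_current, max_levels = 5L, baseline = NULL) {
  z <- trace_levels(trace, unit_current, baseline)
  level <- pmin(pmax(as.integer(round(z)), 0L), as.integer(max_levels))
  dt <- if (nrow(trace) > 1) trace$time_ms[2] - trace$time_ms[1] else 0
  r <- rle(level)
  n_run <- length(r$lengths)
  ends <- cumsum(r$lengths) * dt
  starts <- c(0, ends[-n_run])
  new_event_list(r$values, starts, ends - starts, nrow(trace) * dt)
}

# Normalized level signal (current - baseline) / unit_current.
#
# Polarity is validated against the trace metadata sign flag when present
# (simulated/imported traces record their unit current). When the baseline
# was auto-estimated on a high-activity record the histogram mode is an open
# level, which shows up as the whole signal sitting at negative normalized
# levels: the baseline is then shifted down by the corresponding number of
# unit currents. A signal that deflects opposite to unit_current from an
# explicit baseline is a polarity error.
trace_levels <- function(trace, unit_current, baseline = NULL) {
  if (unit_current == 0) rlang::abort("unit_current must be non-zero")
  meta <- attr(trace, "metadata")
  if (!is.null(meta$unit_current) && is.numeric(meta$unit_current) &&
      sign(meta$unit_current) != sign(unit_current)) {
    rlang::abort("unit_current sign is inconsistent with the trace polarity")
  }
  auto <- is.null(baseline)
  if (auto) baseline <- estimate_baseline(trace)
  z <- (trace$current_pA - baseline) / unit_current
  k_lo <- round(stats::quantile(z, 0.001, names = FALSE))
  if (k_lo < 0) {
    if (!auto) {
      rlang::abort(
        "unit_current sign is inconsistent with the trace polarity"
      )
    }
    z <- z - k_lo # mode was an open level: re-anchor the closed level
  }
  z
}

#' Channel activity NPo from an event list
#'
#' The activity statistic `NPo = sum_n n t_n / T`: the time-weighted mean
#' number of simultaneously open channels, computed without assuming the
#' channel count or per-channel open probability.
#'
#' @param events An `event_list` tibble.
#' @return A single numeric NPo.
#' @export
#' @examples
#' ev <- event_list(c(0, 1, 2), c(0, 60e3, 90e3), c(60e3, 30e3, 10e3), 100e3)
#' compute_npo(ev) # 0.5
compute_npo <- function(events) {
  total <- attr(events, "total_time")
  if (is.null(total) || total <= 0) rlang::abort("total_time must be > 0")
  if (!nrow(events)) rlang::abort("event list is empty")
  sum(events$level * events$duration_ms) / total
}

#' Build an event list from its components
#'
#' @param level Integer number of simultaneously open channels per event.
#' @param start_ms,duration_ms Event start times and durations, ms; events
#'   must be contiguous and non-overlapping.
#' @param total_time Total record length, ms.
#' @return An `event_list` tibble.
#' @export
event_list <- function(level, start_ms, duration_ms, total_time) {
  if (any(duration_ms <= 0)) rlang::abort("event durations must be > 0")
  if (length(start_ms) > 1) {
    gaps <- utils::head(start_ms + duration_ms, -1) - start_ms[-1]
    if (any(abs(gaps) > 1e-9 * total_time)) {
      rlang::abort("events must be contiguous and non-overlapping")
    }
  }
  if (abs(sum(duration_ms) - total_time) > 1e-6 * total_time) {
    rlang::abort("event durations must sum to total_time")
  }
  new_event_list(level, start_ms, duration_ms, total_time)
}

#' Estimate the number of channels in a patch
#'
#' Counts peaks in the all-points amplitude histogram: the occupancy of each
#' integer current level (samples within 0.3 unit currents of the level) is
#' measured and the channel count `N` is the highest level whose occupancy
#' exceeds `prominence`. When the fitted per-channel open probability makes
#' it plausible (probability > 0.05) that a level above `N` simply was never
#' visited during the record, a warning flags possible undercounting.
#'
#' @inheritParams idealize
#' @param prominence Minimum occupancy fraction for a level to count as a
#'   histogram peak.
#' @return Integer channel count (>= 1).
#' @export
estimate_channel_count <- function(trace, unit_current, max_levels = 5L,
                                   baseline = NULL, prominence = 5e-4) {
  z <- trace_levels(trace, unit_current, baseline)
  occ <- vapply(0:max_levels, function(k) mean(abs(z - k) < 0.3), numeric(1))
  peaks <- which(occ > prominence) - 1L
  if (!length(peaks) || max(peaks) < 1L) {
    rlang::abort("no open-level peaks found in the amplitude histogram")
  }
  n_hat <- max(peaks)
  # undercount risk: with N+1 channels at the implied per-channel Po, could
  # the top level have been missed?  crude independent-visits approximation
  ev <- idealize(trace, unit_current, max_levels = max_levels,
                 baseline = baseline)
  npo <- compute_npo(ev)
  po <- min(npo / n_hat, 0.999)
  n_visits <- max(sum(ev$level > 0), 1L)
  p_top <- po^(n_hat + 1L)
  if ((1 - p_top)^n_visits > 0.05 && po > 0) {
    rlang::warn(sprintf(
      "channel count %d may be an underestimate (top level may be unvisited; P > 0.05)",
      n_hat
    ))
  }
  as.integer(n_hat)
}

#' Channel activity summary of a trace
#'
#' Convenience wrapper: idealizes the trace, estimates the channel count from
#' the amplitude histogram, and reports NPo, N and Po = NPo / N.
#'
#' @inheritParams estimate_channel_count
#' @return A one-row tibble with columns `npo`, `n_channels`, `po`,
#'   `total_time_ms`.
#' @export
channel_activity <- function(trace, unit_current, max_levels = 5L,
                             baseline = NULL) {
  ev <- idealize(trace, unit_current, max_levels = max_levels,
                 baseline = baseline)
  n_hat <- estimate_channel_count(trace, unit_current,
                                  max_levels = max_levels,
                                  baseline = baseline)
  npo <- compute_npo(ev)
  tibble::tibble(
    npo = npo,
    n_channels = n_hat,
    po = npo / n_hat,
    total_time_ms = attr(ev, "total_time")
  )
}
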