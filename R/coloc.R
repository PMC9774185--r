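as_pair <- function(pair) {
  if (inherits(pair, "image_pair")) return(pair)
  rlang::abort("expected an image_pair (see image_pair())")
}

#' Pearson correlation between two image channels
#'
#' Product-moment correlation of pixel intensities over the whole image, or
#' restricted to pixels where both channels are above (`"above"`) or below
#' (`"below"`) their thresholds.
#'
#' @param pair An [image_pair()].
#' @param region `"all"`, `"above"` or `"below"`.
#' @param thresholds Numeric length-2 vector `(threshold_ch1, threshold_ch2)`;
#'   required for the restricted regions.
#' @return A single correlation in `[-1, 1]`.
#' @export
pearson_coefficient <- function(pair, region = c("all", "above", "below"),
                                thresholds = NULL) {
  pair <- as_pair(pair)
  region <- match.arg(region)
  s1 <- as.numeric(pair$ch1)
  s2 <- as.numeric(pair$ch2)
  if (region != "all") {
    if (is.null(thresholds) || length(thresholds) != 2L) {
      rlang::abort("thresholds (t1, t2) are required for restricted regions")
    }
    keep <- if (region == "above") {
      s1 > thresholds[1] & s2 > thresholds[2]
    } else {
      s1 < thresholds[1] & s2 < thresholds[2]
    }
    if (sum(keep) < 2L) rlang::abort("selected region is empty")
    s1 <- s1[keep]
    s2 <- s2[keep]
  }
  if (stats::sd(s1) == 0 || stats::sd(s2) == 0) {
    rlang::abort("zero-variance channel in the selected region")
  }
  stats::cor(s1, s2)
}

#' Intensity-ratio colocalization coefficients
#'
#' The pair of coefficients
#' `m1 = sum(s1 s2) / sum(s1^2)` and `m2 = sum(s1 s2) / sum(s2^2)`,
#' computed over all pixels exactly as defined (note these are intensity
#' ratio, overlap-style quantities and are not bounded by 1: doubling channel
#' 2 doubles `m1` and halves `m2`).
#'
#' @param pair An [image_pair()].
#' @return A one-row tibble with columns `m1`, `m2`.
#' @export
#' @examples
#' p <- image_pair(matrix(1:4, 2), matrix(4:1, 2))
#' manders_coefficients(p) # both 2/3
manders_coefficients <- function(pair) {
  pair <- as_pair(pair)
  s1 <- as.numeric(pair$ch1)
  s2 <- as.numeric(pair$ch2)
  s11 <- sum(s1^2)
  s22 <- sum(s2^2)
  if (s11 == 0 || s22 == 0) rlang::abort("all-zero channel")
  cross <- sum(s1 * s2)
  tibble::tibble(m1 = cross / s11, m2 = cross / s22)
}

#' Automatic (Costes-style) colocalization thresholds
#'
#' Determines unbiased intensity thresholds below which the two channels show
#' no positive correlation. Channel 2 is regressed on channel 1 by ordinary
#' least squares; candidate threshold pairs `(t, slope*t + intercept)` are
#' scanned downward from the channel-1 maximum in unit intensity steps, and
#' the scan stops at the first pair for which the Pearson coefficient of the
#' pixels with BOTH channels below their thresholds is <= 0. If no threshold
#' achieves non-positive correlation the minimum intensity is returned with a
#' warning (fully uncorrelated channels).
#'
#' Implementation note: a pixel lies in the below-both region exactly when
#' `t > max(s1, (s2 - intercept)/slope)`, so the scan is evaluated for all
#' candidate thresholds at once from cumulative sums over pixels ordered by
#' that critical value; the result is identical to the naive downward scan.
#'
#' @param pair An [image_pair()].
#' @param step Scan step in intensity units (default 1).
#' @return A one-row tibble: `threshold_ch1`, `threshold_ch2`, `slope`,
#'   `intercept`, `below_r` (the below-threshold Pearson at the stop point).
#' @export
costes_thresholds <- function(pair, step = 1) {
  pair <- as_pair(pair)
  s1 <- as.numeric(pair$ch1)
  s2 <- as.numeric(pair$ch2)
  if (stats::sd(s1) == 0 || stats::sd(s2) == 0) {
    rlang::abort("channels must have positive variance")
  }
  ols <- stats::lm(s2 ~ s1)
  intercept <- stats::coef(ols)[[1]]
  slope <- stats::coef(ols)[[2]]
  if (slope <= 0) {
    rlang::warn("non-positive regression slope; thresholds set to minimum")
    return(tibble::tibble(threshold_ch1 = min(s1),
                          threshold_ch2 = min(s2),
                          slope = slope, intercept = intercept,
                          below_r = NA_real_))
  }

  # critical channel-1 threshold at which each pixel joins the below-both set
  crit <- pmax(s1, (s2 - intercept) / slope)
  ord <- order(crit)
  s1o <- s1[ord]
  s2o <- s2[ord]
  crit_o <- crit[ord]
  cs1 <- cumsum(s1o)
  cs2 <- cumsum(s2o)
  cs11 <- cumsum(s1o^2)
  cs22 <- cumsum(s2o^2)
  cs12 <- cumsum(s1o * s2o)

  t_grid <- seq(max(s1), min(s1), by = -abs(step))
  # m = number of pixels with crit < t (strictly below both thresholds)
  m <- findInterval(t_grid, crit_o, left.open = TRUE)
  r_of <- function(i) {
    if (i < 2L) return(NA_real_)
    num <- i * cs12[i] - cs1[i] * cs2[i]
    v1 <- i * cs11[i] - cs1[i]^2
    v2 <- i * cs22[i] - cs2[i]^2
    if (v1 <= 0 || v2 <= 0) return(NA_real_)
    num / sqrt(v1 * v2)
  }
  r_vals <- vapply(m, r_of, numeric(1))
  hit <- which(!is.na(r_vals) & r_vals <= 0)
  if (length(hit)) {
    t1 <- t_grid[hit[1]]
    below_r <- r_vals[hit[1]]
  } else {
    rlang::warn(paste("no threshold yields non-positive below-threshold",
                      "correlation; returning the minimum intensity"))
    t1 <- min(s1)
    below_r <- r_vals[length(r_vals)]
  }
  tibble::tibble(
    threshold_ch1 = t1,
    threshold_ch2 = slope * t1 + intercept,
    slope = slope, intercept = intercept,
    below_r = below_r
  )
}

#' Thresholded overlap statistics and colocalization mask
#'
#' Over the pixels with both channels above their thresholds: the overlap
#' coefficient `R = sum(s1 s2)/sqrt(sum(s1^2) sum(s2^2))` (and the same
#' quantity over the below-both region), the per-channel overlap
#' coefficients `k1 = sum(s1 s2)/sum(s1^2)` and `k2 = sum(s1 s2)/sum(s2^2)`,
#' the per-channel counts of above-threshold pixels, and the colocalized
#' pixel mask: both channels above threshold AND intensity ratio
#' `min(s1,s2)/max(s1,s2) > ratio_min` (the pixels recolored white in merged
#' images).
#'
#' @param pair An [image_pair()].
#' @param thresholds Length-2 numeric `(threshold_ch1, threshold_ch2)` or a
#'   [costes_thresholds()] row.
#' @param ratio_min Minimum between-channel intensity ratio for a pixel to
#'   count as colocalized (default 0.1).
#' @return A list with `stats` (one-row tibble: `overlap_r_above`,
#'   `overlap_r_below`, `k1`, `k2`, `n_coloc_pixels`, `n_ch1_above`,
#'   `n_ch2_above`) and `mask` (logical matrix).
#' @export
overlap_and_counts <- function(pair, thresholds, ratio_min = 0.1) {
  pair <- as_pair(pair)
  if (is.data.frame(thresholds)) {
    thresholds <- c(thresholds$threshold_ch1[1], thresholds$threshold_ch2[1])
  }
  s1 <- pair$ch1
  s2 <- pair$ch2
  rng1 <- range(s1)
  rng2 <- range(s2)
  if (thresholds[1] < rng1[1] - 1 || thresholds[1] > rng1[2] ||
      thresholds[2] < rng2[1] - 1 || thresholds[2] > rng2[2]) {
    rlang::warn("thresholds lie outside the intensity range")
  }
  n1_above <- sum(s1 > thresholds[1])
  n2_above <- sum(s2 > thresholds[2])
  if (n1_above == 0L || n2_above == 0L) {
    rlang::abort("no pixels above threshold in one of the channels")
  }
  above <- s1 > thresholds[1] & s2 > thresholds[2]
  below <- s1 < thresholds[1] & s2 < thresholds[2]

  overlap_r <- function(mask) {
    if (sum(mask) < 1L) return(NA_real_)
    a <- as.numeric(s1[mask])
    b <- as.numeric(s2[mask])
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) return(NA_real_)
    sum(a * b) / den
  }
  # fully disjoint channels: no jointly-above pixel, zero colocalization
  a1 <- as.numeric(s1[above])
  a2 <- as.numeric(s2[above])
  cross <- sum(a1 * a2)

  ratio <- pmin(s1, s2) / pmax(s1, s2)
  ratio[pmax(s1, s2) == 0] <- 0
  mask <- above & ratio > ratio_min

  list(
    stats = tibble::tibble(
      overlap_r_above = overlap_r(above),
      overlap_r_below = overlap_r(below),
      k1 = if (any(above)) cross / sum(a1^2) else NA_real_,
      k2 = if (any(above)) cross / sum(a2^2) else NA_real_,
      n_coloc_pixels = sum(mask),
      n_ch1_above = n1_above,
      n_ch2_above = n2_above
    ),
    mask = mask
  )
}

#' Full colocalization report for an image pair
#'
#' Runs the whole two-channel colocalization analysis with default settings:
#' global Pearson correlation, the intensity-ratio coefficients m1/m2,
#' automatic threshold determination, thresholded overlap coefficients and
#' counts, and the colocalized-pixel mask.
#'
#' @inheritParams overlap_and_counts
#' @param ratio_min Minimum intensity ratio for the colocalization mask.
#' @return An object of class `coloc_result`: list with `stats` (one-row
#'   tibble covering the full statistic set), `mask`, and the input
#'   thresholds. `tidy()` returns the statistics in long form.
#' @export
#' @examples
#' pair <- simulate_image_pair(coloc_fraction = 0.75, seed = 5)
#' rep <- coloc_report(pair)
#' tidy(rep)
coloc_report <- function(pair, ratio_min = 0.1) {
  pair <- as_pair(pair)
  thr <- costes_thresholds(pair)
  ov <- overlap_and_counts(pair, thr, ratio_min = ratio_min)
  stats <- dplyr::bind_cols(
    tibble::tibble(pearson = pearson_coefficient(pair)),
    manders_coefficients(pair),
    thr[, c("threshold_ch1", "threshold_ch2", "slope", "intercept")],
    ov$stats
  )
  structure(
    list(stats = stats, mask = ov$mask, thresholds = thr,
         ratio_min = ratio_min),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  s <- x$stats
  cat(sprintf(
    paste0("<coloc_result> pearson %.3f | m1 %.3f m2 %.3f | R(above) %.3f ",
           "R(below) %.4f | k1 %.3f k2 %.3f | %d colocalized pixels\n"),
    s$pearson, s$m1, s$m2, s$overlap_r_above, s$overlap_r_below,
    s$k1, s$k2, s$n_coloc_pixels
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.coloc_result <- function(x, ...) {
  tidyr::pivot_longer(x$stats, dplyr::everything(),
                      names_to = "statistic", values_to = "value")
}

#' @exportS3Method ggplot2::autoplot
autoplot.coloc_result <- function(object, ...) {
  df <- tibble::tibble(
    row = as.integer(row(object$mask)),
    col = as.integer(col(object$mask)),
    colocalized = as.logical(object$mask)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$colocalized)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "black",
                                          `TRUE` = "white")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Colocalized pixels", x = NULL, y = NULL) +
    ggplot2::theme_void()
}
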