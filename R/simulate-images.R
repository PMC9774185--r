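#' Simulate a registered two-channel fluorescence image pair
#'
#' Generates a pair of 16-bit single-plane images containing Gaussian puncta
#' (point-spread-limited spots), a fraction of which sit at coordinates
#' shared by both channels (the colocalized population); the remainder are
#' placed at channel-specific coordinates. A uniform background and Gaussian
#' noise (an approximation to Poisson shot noise at high background) are
#' added, and intensities are rounded and clipped to the 16-bit range.
#' Used as a ground-truth fixture for the colocalization statistics.
#'
#' @param shape Image dimensions `c(rows, cols)`.
#' @param n_puncta Number of puncta per channel.
#' @param coloc_fraction Fraction of puncta placed at shared coordinates,
#'   in `[0, 1]`.
#' @param psf_sigma Gaussian spot s.d. in pixels.
#' @param amplitude Peak intensity of a punctum (counts).
#' @param background Uniform background level (counts).
#' @param noise_sd Gaussian noise s.d. (counts).
#' @param min_separation Minimum distance in pixels between any two punctum
#'   centres (0 = unconstrained). Use a few PSF widths to guarantee that
#'   non-colocalized spots do not overlap by chance.
#' @param seed Optional integer seed.
#' @return An object of class `image_pair`: list with integer matrices
#'   `ch1`, `ch2` and a `truth` list (coordinates, fraction, psf, seed).
#' @export
#' @examples
#' pair <- simulate_image_pair(coloc_fraction = 0.5, seed = 3)
#' coloc_report(pair)
simulate_image_pair <- function(shape = c(256, 256), n_puncta = 150,
                                coloc_fraction = 0.5, psf_sigma = 2,
                                amplitude = 8000, background = 200,
                                noise_sd = 20, min_separation = 0,
                                seed = NULL) {
  if (coloc_fraction < 0 || coloc_fraction > 1) {
    rlang::abort("coloc_fraction must lie in [0, 1]")
  }
  if (2 * n_puncta > prod(shape)) {
    rlang::abort("more puncta than pixels")
  }
  if (!is.null(seed)) set.seed(seed)
  nr <- shape[1]
  nc <- shape[2]

  n_shared <- round(coloc_fraction * n_puncta)
  n_solo <- n_puncta - n_shared
  n_total <- n_shared + 2 * n_solo
  # disjoint coordinate pool so fraction-0 pairs share no spot centres
  if (min_separation <= 0) {
    pool <- sample.int(nr * nc, n_total)
    xy <- cbind((pool - 1L) %% nr + 1L, (pool - 1L) %/% nr + 1L)
  } else {
    xy <- matrix(0L, 0, 2)
    tries <- 0L
    while (nrow(xy) < n_total) {
      tries <- tries + 1L
      if (tries > 200L * n_total) {
        rlang::abort("cannot place puncta with this minimum separation")
      }
      cand <- c(sample.int(nr, 1L), sample.int(nc, 1L))
      if (!nrow(xy) ||
          min(sqrt((xy[, 1] - cand[1])^2 + (xy[, 2] - cand[2])^2)) >=
            min_separation) {
        xy <- rbind(xy, cand)
      }
    }
  }
  shared <- xy[seq_len(n_shared), , drop = FALSE]
  solo1 <- xy[n_shared + seq_len(n_solo), , drop = FALSE]
  solo2 <- xy[n_shared + n_solo + seq_len(n_solo), , drop = FALSE]

  ch1 <- render_puncta(rbind(shared, solo1), nr, nc, psf_sigma, amplitude)
  ch2 <- render_puncta(rbind(shared, solo2), nr, nc, psf_sigma, amplitude)
  add_noise <- function(img) {
    img <- img + background + stats::rnorm(length(img), 0, noise_sd)
    matrix(as.integer(pmin(pmax(round(img), 0), 65535)), nr, nc)
  }
  structure(
    list(
      ch1 = add_noise(ch1),
      ch2 = add_noise(ch2),
      truth = list(
        n_puncta = n_puncta, coloc_fraction = coloc_fraction,
        psf_sigma = psf_sigma, amplitude = amplitude,
        background = background, noise_sd = noise_sd, seed = seed,
        shared = shared, solo1 = solo1, solo2 = solo2
      )
    ),
    class = "image_pair"
  )
}

# additive Gaussian spots at integer centres
render_puncta <- function(centres, nr, nc, psf_sigma, amplitude) {
  img <- matrix(0, nr, nc)
  if (!nrow(centres)) return(img)
  half <- ceiling(4 * psf_sigma)
  offs <- seq(-half, half)
  kern <- exp(-outer(offs^2, offs^2, "+") / (2 * psf_sigma^2))
  for (i in seq_len(nrow(centres))) {
    r0 <- centres[i, 1]
    c0 <- centres[i, 2]
    rr <- r0 + offs
    cc <- c0 + offs
    rok <- rr >= 1 & rr <= nr
    cok <- cc >= 1 & cc <= nc
    img[rr[rok], cc[cok]] <- img[rr[rok], cc[cok]] +
      amplitude * kern[rok, cok]
  }
  img
}

#' Construct an image pair from two matrices
#'
#' @param ch1,ch2 Non-negative numeric matrices of identical dimensions.
#' @param truth Optional ground-truth list (for simulated pairs).
#' @return An `image_pair` object.
#' @export
image_pair <- function(ch1, ch2, truth = NULL) {
  if (!is.matrix(ch1) || !is.matrix(ch2) ||
      !identical(dim(ch1), dim(ch2))) {
    rlang::abort("ch1 and ch2 must be matrices of identical dimensions")
  }
  if (any(ch1 < 0) || any(ch2 < 0)) {
    rlang::abort("intensities must be non-negative")
  }
  structure(list(ch1 = ch1, ch2 = ch2, truth = truth),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair> %d x %d pixels", nrow(x$ch1), ncol(x$ch1)))
  if (!is.null(x$truth)) {
    cat(sprintf(", %d puncta/channel, colocalized fraction %.2f",
                x$truth$n_puncta, x$truth$coloc_fraction))
  }
  cat("\n")
  invisible(x)
}
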