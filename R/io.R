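#' Read and write current traces as CSV with a JSON metadata sidecar
#'
#' Traces are stored as two-column CSV (`time_ms,current_pA`); metadata
#' (ligand concentration, channel count, unit current, noise level, filter
#' cutoff, sampling rate and seed) goes to `<path>.json`. Reading a trace
#' without a sidecar marks its metadata as unknown.
#'
#' @param trace An `ion_trace` tibble.
#' @param path CSV file path.
#' @param sidecar Write the JSON sidecar (default `TRUE`).
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   an `ion_trace`.
#' @export
write_trace <- function(trace, path, sidecar = TRUE) {
  stopifnot(all(c("time_ms", "current_pA") %in% names(trace)))
  # %.17g guarantees a bit-exact double round trip
  writeLines(
    c("time_ms,current_pA",
      sprintf("%.17g,%.17g", trace$time_ms, trace$current_pA)),
    path
  )
  if (sidecar) {
    meta <- attr(trace, "metadata")
    if (is.null(meta)) meta <- list()
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  required <- c("time_ms", "current_pA")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    rlang::abort(sprintf("malformed trace header: missing column '%s'",
                         missing[1]))
  }
  if (is.unsorted(df$time_ms, strictly = TRUE)) {
    rlang::abort("time_ms column must be strictly increasing")
  }
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    list(unknown = TRUE)
  }
  new_ion_trace(df$time_ms, df$current_pA, meta)
}

#' Read and write event lists as TSV
#'
#' Columns `level`, `start_ms`, `duration_ms`; the total record time is the
#' sum of durations.
#'
#' @param events An `event_list`.
#' @param path TSV file path.
#' @return `write_events()` returns `path` invisibly; `read_events()` an
#'   `event_list`.
#' @export
write_events <- function(events, path) {
  utils::write.table(events[, c("level", "start_ms", "duration_ms")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path)
  required <- c("level", "start_ms", "duration_ms")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    rlang::abort(sprintf("malformed event table: missing column '%s'",
                         missing[1]))
  }
  event_list(df$level, df$start_ms, df$duration_ms, sum(df$duration_ms))
}

#' Read and write image pairs as 16-bit grayscale TIFF
#'
#' One file per channel. Intensities are stored on the 16-bit scale.
#'
#' @param pair An [image_pair()].
#' @param path_ch1,path_ch2 TIFF file paths.
#' @return `write_image_pair()` returns the paths invisibly;
#'   `read_image_pair()` an `image_pair`.
#' @export
write_image_pair <- function(pair, path_ch1, path_ch2) {
  pair <- as_pair(pair)
  tiff::writeTIFF(pair$ch1 / 65535, path_ch1, bits.per.sample = 16)
  tiff::writeTIFF(pair$ch2 / 65535, path_ch2, bits.per.sample = 16)
  invisible(c(path_ch1, path_ch2))
}

#' @rdname write_image_pair
#' @export
read_image_pair <- function(path_ch1, path_ch2) {
  ch1 <- round(tiff::readTIFF(path_ch1) * 65535)
  ch2 <- round(tiff::readTIFF(path_ch2) * 65535)
  image_pair(matrix(as.integer(ch1), nrow(ch1), ncol(ch1)),
             matrix(as.integer(ch2), nrow(ch2), ncol(ch2)))
}

#' Write a colocalization mask as 8-bit TIFF
#'
#' Colocalized pixels are written as 255, everything else 0.
#'
#' @param result A `coloc_result` from [coloc_report()].
#' @param path TIFF file path.
#' @export
write_coloc_mask <- function(result, path) {
  stopifnot(inherits(result, "coloc_result"))
  tiff::writeTIFF(result$mask * 1.0, path, bits.per.sample = 8)
  invisible(path)
}
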