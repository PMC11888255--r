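# TIFF stack and trace-table I/O.

#' Read a multi-page TIFF into a z/T x H x W array
#'
#' @param path TIFF file path.
#' @return Numeric array `planes x H x W` (intensities as stored, grayscale).
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  arr <- array(0, dim = c(length(pages), dim(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  arr
}

#' Write a z/T x H x W array as a multi-page TIFF
#'
#' Intensities are stored as 16-bit after scaling by `max(stack)` (recorded
#' nowhere in the file; keep quantitative work in memory or in CSV).
#'
#' @param stack Numeric array `planes x H x W`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(length(dim(stack)) == 3)
  hi <- max(stack, 1e-12)
  pages <- lapply(seq_len(dim(stack)[1]),
                  function(i) pmax(stack[i, , ], 0) / hi)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Write a trace set as a wide CSV (one row per unit)
#'
#' @param ts A `trace_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(ts, path) {
  stopifnot(inherits(ts, "trace_set"))
  df <- as.data.frame(ts$traces)
  names(df) <- sprintf("f%06d", seq_len(ncol(df)))
  df <- cbind(unit_id = ts$units$unit_id, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a wide trace CSV written by [write_trace_csv()]
#'
#' @param path CSV path.
#' @param frame_rate Sampling rate, Hz.
#' @return A `trace_set`.
#' @export
read_trace_csv <- function(path, frame_rate = 10) {
  df <- utils::read.csv(path)
  traces <- as.matrix(df[, -1, drop = FALSE])
  dimnames(traces) <- NULL
  structure(
    list(traces = traces, frame_rate = frame_rate,
         time_s = (seq_len(ncol(traces)) - 1) / frame_rate,
         units = tibble::tibble(unit_id = df[[1]],
                                condition = NA_character_,
                                compartment = NA_character_)),
    class = "trace_set")
}
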