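#' Whole-body fluorescence trace
#'
#' Uniformly sampled whole-body intensity series. Frame `i` (0-based) is at
#' time `i / frame_rate`; the time origin is the first frame.
#'
#' @param values Numeric vector of intensities (raw a.u. or dF/F).
#' @param frame_rate Sampling rate, Hz.
#' @param units `"raw"` or `"dff"`.
#' @param metadata Named list; recognised entries are `condition`, `tissue`
#'   (`"neuron"`, `"ectoderm"` or `"endoderm"`) and `source`.
#' @return An object of class `fluor_trace` with elements `times`,
#'   `values`, `frame_rate`, `units`, `metadata`.
#' @export
#' @examples
#' tr <- fluor_trace(100 + sin(1:100), frame_rate = 2)
#' tr$times[1:3]
fluor_trace <- function(values, frame_rate, units = c("raw", "dff"),
                        metadata = list()) {
  units <- match.arg(units)
  values <- as.numeric(values)
  if (length(values) < 2L) stop("a trace needs at least 2 samples")
  if (!all(is.finite(values))) stop("trace values must be finite")
  if (!(is.numeric(frame_rate) && length(frame_rate) == 1L && frame_rate > 0)) {
    stop("frame_rate must be a positive scalar")
  }
  structure(list(times = (seq_along(values) - 1) / frame_rate,
                 values = values,
                 frame_rate = frame_rate,
                 units = units,
                 metadata = metadata),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace> %d frames at %g Hz (%.1f s), units: %s\n",
              length(x$values), x$frame_rate,
              length(x$values) / x$frame_rate, x$units))
  if (length(x$metadata) > 0) {
    cat("  ", paste(names(x$metadata), unlist(x$metadata),
                    sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
as.data.frame.fluor_trace <- function(x, ...) {
  data.frame(frame = seq_along(x$values) - 1L,
             time_s = x$times,
             intensity = x$values)
}

#' Read and write multi-page TIFF movie stacks
#'
#' `read_stack()` reads a single-channel multi-page TIFF into an
#' `height x width x frames` integer-valued array in 16-bit intensity
#' units (0-65535), frames in acquisition order. Frame rate is never
#' guessed from TIFF tags; it is supplied wherever a time base is needed.
#' `write_stack()` writes such an array (or a single matrix) as an
#' uncompressed 16-bit multi-page TIFF.
#'
#' @param path TIFF file path.
#' @param stack Numeric array `h x w x n` (or `h x w`) with values in
#'   0-65535.
#' @return `read_stack()` the array; `write_stack()` `path`, invisibly.
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("cannot read stack: ", path)
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  if (length(frames) == 0L) stop("stack has zero frames")
  if (any(vapply(frames, function(f) length(dim(f)) > 2L, logical(1)))) {
    stop("single-channel required: multi-channel TIFF")
  }
  d <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1)))) {
    stop("frames differ in shape")
  }
  arr <- array(round(unlist(frames, use.names = FALSE) * 65535),
               dim = c(d, length(frames)))
  arr
}

#' @rdname read_stack
#' @export
write_stack <- function(stack, path) {
  if (length(dim(stack)) == 2L) dim(stack) <- c(dim(stack), 1L)
  stopifnot(length(dim(stack)) == 3L)
  if (min(stack) < 0 || max(stack) > 65535) {
    stop("stack intensities must lie in [0, 65535]")
  }
  frames <- lapply(seq_len(dim(stack)[3L]),
                   function(i) stack[, , i] / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Extract the whole-body fluorescence trace from a movie stack
#'
#' Computes one intensity value per frame: the mean over all pixels
#' (`whole_frame`, the simplest reading of a whole-frame ImageJ
#' measurement) or the mean over a per-frame Otsu foreground mask
#' (`otsu_mask`, restricting to the animal so that background dilution
#' does not modulate the trace as the animal changes shape).
#'
#' @param stack Array from [read_stack()] or [render_movie()].
#' @param frame_rate Acquisition rate, Hz (required; never inferred).
#' @param mask_mode `"whole_frame"` or `"otsu_mask"`.
#' @return A raw-units [fluor_trace].
#' @export
extract_whole_body_trace <- function(stack, frame_rate,
                                     mask_mode = c("whole_frame", "otsu_mask")) {
  mask_mode <- match.arg(mask_mode)
  if (length(dim(stack)) == 2L) dim(stack) <- c(dim(stack), 1L)
  stopifnot(length(dim(stack)) == 3L, dim(stack)[3L] >= 1L)
  n <- dim(stack)[3L]
  vals <- numeric(n)
  for (i in seq_len(n)) {
    fr <- stack[, , i]
    if (mask_mode == "whole_frame") {
      vals[i] <- mean(fr)
    } else {
      thr <- EBImage::otsu(fr / 65535) * 65535
      mask <- fr > thr
      if (!any(mask)) stop("empty foreground mask in frame ", i)
      vals[i] <- mean(fr[mask])
    }
  }
  fluor_trace(vals, frame_rate, units = "raw",
              metadata = list(mask_mode = mask_mode))
}

#' Read and write fluorescence traces as CSV
#'
#' Tabular format with columns `frame`, `time_s`, `intensity` and the
#' trace metadata in a `# key: value` comment header. Values are written
#' with full double precision, so a write/read round trip is lossless.
#' `read_trace()` rejects files whose timestamps are not uniform at the
#' stated frame rate (relative tolerance 1e-6).
#'
#' @param trace A [fluor_trace].
#' @param path CSV file path.
#' @return `read_trace()` a `fluor_trace`; `write_trace()` `path`,
#'   invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fluor_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(frame_rate = trace$frame_rate, units = trace$units,
           trace$metadata)
  writeLines(sprintf("# %s: %s", names(hdr), unlist(hdr)), con)
  writeLines("frame,time_s,intensity", con)
  writeLines(sprintf("%d,%.17g,%.17g",
                     seq_along(trace$values) - 1L,
                     trace$times, trace$values), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("cannot read trace: ", path)
  lines <- readLines(path)
  hdr_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr_lines) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L) meta[[trimws(m[2L])]] <- trimws(m[3L])
  }
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  req <- c("frame", "time_s", "intensity")
  if (!all(req %in% names(df))) {
    stop("trace file must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(df) < 2L) stop("a trace needs at least 2 samples")
  dt <- diff(df$time_s)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * mean(dt)) {
    stop("non-uniform sampling in trace file")
  }
  frame_rate <- if (!is.null(meta$frame_rate)) {
    as.numeric(meta$frame_rate)
  } else {
    1 / mean(dt)
  }
  units <- if (identical(meta$units, "dff")) "dff" else "raw"
  meta$frame_rate <- NULL
  meta$units <- NULL
  fluor_trace(df$intensity, frame_rate, units = units, metadata = meta)
}
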