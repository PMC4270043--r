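#' Fluorescence trace container
#'
#' A `fluorescence_trace` holds one ROI's sampled fluorescence versus time:
#' a numeric value vector, the frame interval in seconds, a channel tag and
#' the time of the first frame. Frame `i` (1-based) is sampled at
#' `t0 + (i - 1) * frame_interval`.
#'
#' @param values numeric vector of fluorescence values (arbitrary units),
#'   finite, length >= 1.
#' @param frame_interval sampling interval in seconds (> 0). Single-channel
#'   pHluorin recordings are typically ~0.12 s (~8 Hz); interleaved
#'   dual-channel recordings ~0.18 s per cycle.
#' @param roi_id identifier for the ROI (coerced to character).
#' @param channel `"green"` or `"red"`.
#' @param t0 time of the first frame in seconds (default 0).
#'
#' @return An object of class `fluorescence_trace`: a list with elements
#'   `roi_id`, `frame_interval`, `values`, `channel`, `t0`.
#' @export
#' @examples
#' tr <- fluorescence_trace(rnorm(100), frame_interval = 0.12)
#' trace_times(tr)[1:5]
fluorescence_trace <- function(values, frame_interval, roi_id = "roi1",
                               channel = c("green", "red"), t0 = 0) {
  channel <- match.arg(channel)
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("trace must contain at least one value", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("trace values must be finite", call. = FALSE)
  }
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be a single positive number", call. = FALSE)
  }
  structure(
    list(roi_id = as.character(roi_id),
         frame_interval = as.numeric(frame_interval),
         values = values,
         channel = channel,
         t0 = as.numeric(t0)),
    class = "fluorescence_trace"
  )
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf(
    "<fluorescence_trace> roi %s, %d frames @ %.4g s (%s channel)\n",
    x$roi_id, length(x$values), x$frame_interval, x$channel))
  invisible(x)
}

#' Frame times of a trace
#'
#' @param trace a [fluorescence_trace()].
#' @return numeric vector of frame times in seconds.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$values) - 1) * trace$frame_interval
}

#' Read per-ROI fluorescence traces from a CSV table
#'
#' The expected dialect is a comma-separated UTF-8 table with a header row
#' and `.` decimal separator. The first column is time ("time_s", seconds)
#' or a frame index ("frame"); every remaining column is one ROI's
#' fluorescence values. All columns must be numeric and of equal length.
#'
#' @param path path to the CSV file.
#' @param frame_interval frame interval in seconds. When the time column is
#'   "time_s" and `frame_interval` is `NULL` it is inferred from the median
#'   time step; with a "frame" column it must be supplied.
#' @param channel channel tag applied to all traces.
#' @return list of [fluorescence_trace()] objects, one per ROI column.
#' @export
read_traces <- function(path, frame_interval = NULL,
                        channel = c("green", "red")) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, header = TRUE, check.names = FALSE,
                    colClasses = NA, fileEncoding = "UTF-8"),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("parse error in ", path,
         ": need a time column plus at least one ROI column and one row",
         call. = FALSE)
  }
  tcol <- names(df)[1]
  if (!tcol %in% c("time_s", "frame")) {
    stop("parse error in ", path,
         ": first column must be named 'time_s' or 'frame', got '",
         tcol, "'", call. = FALSE)
  }
  for (j in seq_len(ncol(df))) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1]
      stop("parse error in ", path, ": non-numeric cell at row ",
           ifelse(is.na(bad), 1L, bad), ", column '", names(df)[j], "'",
           call. = FALSE)
    }
    if (anyNA(col)) {
      stop("parse error in ", path, ": missing value at row ",
           which(is.na(col))[1], ", column '", names(df)[j], "'",
           call. = FALSE)
    }
  }
  if (is.null(frame_interval)) {
    if (tcol == "frame") {
      stop("frame_interval must be given when the time column is 'frame'",
           call. = FALSE)
    }
    if (nrow(df) < 2L) {
      stop("frame_interval cannot be inferred from a single row",
           call. = FALSE)
    }
    frame_interval <- stats::median(diff(df[[1]]))
  }
  if (frame_interval <= 0) {
    stop("parse error in ", path, ": nonpositive frame interval",
         call. = FALSE)
  }
  t0 <- if (tcol == "time_s") df[[1]][1] else 0
  lapply(names(df)[-1], function(id) {
    fluorescence_trace(df[[id]], frame_interval = frame_interval,
                       roi_id = id, channel = channel, t0 = t0)
  })
}

#' Write fluorescence traces to a CSV table
#'
#' Inverse of [read_traces()]: one "time_s" column followed by one column
#' per trace. All traces must share length, frame interval and t0.
#'
#' @param traces list of [fluorescence_trace()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "fluorescence_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L)
  lens <- vapply(traces, function(tr) length(tr$values), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("all traces must have equal length to share a table", call. = FALSE)
  }
  dt <- vapply(traces, function(tr) tr$frame_interval, numeric(1))
  if (diff(range(dt)) > 1e-12) {
    stop("all traces must share one frame interval", call. = FALSE)
  }
  out <- data.frame(time_s = trace_times(traces[[1]]))
  for (tr in traces) out[[tr$roi_id]] <- tr$values
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write detected-event tables
#'
#' Event tables are plain CSV with one row per detected event and at least
#' the columns produced by [detect_events()] (`roi_id`, `onset_frame`,
#' `onset_time`, `amplitude`, `dff`, `baseline_mean`, `baseline_sd`,
#' `polarity`).
#'
#' @param path path to CSV.
#' @return `read_events`: data.frame of events.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE, fileEncoding = "UTF-8")
  if (nrow(df) > 0 && !all(c("roi_id", "onset_time") %in% names(df))) {
    stop("parse error in ", path,
         ": expected at least columns roi_id, onset_time", call. = FALSE)
  }
  df
}

#' @rdname read_events
#' @param events data.frame of events.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Extract mean-intensity ROI traces from an image stack
#'
#' Averages pixel intensities in square ROIs over the frames of a grayscale
#' stack, emulating the standard bouton-ROI trace extraction (square ROIs of
#' fixed side centred on user-supplied bouton positions).
#'
#' Coordinates are 0-based `(row, col)` pixel positions. An odd `side`
#' yields a square centred on the pixel; an even `side` is biased toward
#' lower indices (one extra row/column on the low side). ROIs are clipped
#' at the image border; an ROI falling entirely outside the image is an
#' error naming the offending centre.
#'
#' @param stack a 3-d numeric array `[row, col, frame]`, or a list of
#'   equally sized matrices (one per frame) as returned by
#'   `tiff::readTIFF(..., all = TRUE)`.
#' @param centers numeric matrix or data.frame with two columns
#'   (row, col), 0-based, one row per ROI.
#' @param side ROI side length in pixels (>= 1).
#' @param frame_interval frame interval in seconds for the output traces.
#' @param channel channel tag.
#' @return list of [fluorescence_trace()], one per centre, roi_id
#'   `"roi<k>"`.
#' @export
extract_rois <- function(stack, centers, side, frame_interval = 0.12,
                         channel = c("green", "red")) {
  channel <- match.arg(channel)
  if (is.list(stack) && !is.array(stack)) {
    stack <- simplify2array(stack)
  }
  if (!(is.array(stack) && length(dim(stack)) == 3L)) {
    stop("stack must be a [row, col, frame] array or list of matrices",
         call. = FALSE)
  }
  centers <- as.matrix(centers)
  if (ncol(centers) != 2L) stop("centers must have two columns (row, col)",
                                call. = FALSE)
  if (side < 1) stop("side must be >= 1", call. = FALSE)
  side <- as.integer(side)
  nr <- dim(stack)[1]; nc <- dim(stack)[2]; nt <- dim(stack)[3]
  lo <- side %/% 2L                      # extra extent on the low side
  hi <- (side - 1L) %/% 2L
  lapply(seq_len(nrow(centers)), function(k) {
    r <- as.integer(centers[k, 1]) + 1L  # to 1-based
    cc <- as.integer(centers[k, 2]) + 1L
    r0 <- max(1L, r - lo); r1 <- min(nr, r + hi)
    c0 <- max(1L, cc - lo); c1 <- min(nc, cc + hi)
    if (r0 > nr || r1 < 1L || c0 > nc || c1 < 1L || r0 > r1 || c0 > c1) {
      stop(sprintf("ROI %d centred at (%d, %d) lies outside the image",
                   k, r - 1L, cc - 1L), call. = FALSE)
    }
    vals <- vapply(seq_len(nt),
                   function(f) mean(stack[r0:r1, c0:c1, f]),
                   numeric(1))
    fluorescence_trace(vals, frame_interval = frame_interval,
                       roi_id = paste0("roi", k), channel = channel)
  })
}

#' Read a multi-page grayscale TIFF stack
#'
#' Thin wrapper over `tiff::readTIFF(all = TRUE)` returning the
#' `[row, col, frame]` array expected by [extract_rois()]. Multi-sample
#' (RGB) pages are averaged to grayscale.
#'
#' @param path path to a TIFF file.
#' @return 3-d numeric array.
#' @export
read_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to read TIFF stacks", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) apply(p, c(1, 2), mean) else p
  })
  simplify2array(pages)
}
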