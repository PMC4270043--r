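#' Fit a single-exponential decay to one detected event
#'
#' Least-squares fit of `A * exp(-(t - t_peak)/tau) + c` to the post-peak
#' segment of the raw trace, by Levenberg-Marquardt minimisation
#' (`minpack.lm::nlsLM`). The decay of spontaneous pHluorin events is
#' dominated by vesicle re-acidification, so `tau` estimates the
#' re-acidification time constant. The offset `c` is free, tolerating
#' imperfect baseline subtraction.
#'
#' The fit window runs from the event peak to `min(onset + window,
#' next event onset - 1, trace end)`. Because single-vesicle events rise
#' within one frame and decay immediately (no dwell), the peak is taken
#' to be the onset sample itself (`peak = "onset"`, the default); picking
#' the largest raw value near the onset (`peak = "max"`) is available for
#' waveforms with a slower rise, at the cost of a noise-selection bias
#' toward faster fitted decays. Initial guesses: `A = peak - baseline`,
#' `tau = 3 * frame_interval`, `c = baseline`.
#'
#' @param trace a [fluorescence_trace()].
#' @param event one-row data.frame (or list) with at least `onset_frame`
#'   and `baseline_mean`, as produced by [detect_events()].
#' @param window maximum fit-window length in frames past the onset
#'   (default 40).
#' @param next_onset optional onset frame of the following event; the fit
#'   window ends before it.
#' @param peak `"onset"` or `"max"` (see above).
#' @return list of class `decay_fit`: `tau` (s), `amplitude`, `offset`
#'   (a.u.), `rss`, `converged`, `n_points`. On non-convergence `converged`
#'   is `FALSE` and `tau` is `NA`.
#' @export
fit_decay <- function(trace, event, window = 40L, next_onset = NULL,
                      peak = c("onset", "max")) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  peak <- match.arg(peak)
  event <- as.list(event)
  onset <- as.integer(event$onset_frame)
  n <- length(trace$values)
  end <- min(onset + as.integer(window), n)
  if (!is.null(next_onset)) end <- min(end, as.integer(next_onset) - 1L)
  rise_end <- min(onset + 2L, end)
  peak <- if (peak == "onset") onset else
    onset - 1L + which.max(trace$values[onset:rise_end])
  if (end - peak + 1L < 4L) {
    stop("insufficient points for decay fit: need >= 4 after the peak",
         call. = FALSE)
  }
  idx <- peak:end
  y <- trace$values[idx]
  t <- (idx - peak) * trace$frame_interval
  bl <- if (!is.null(event$baseline_mean)) event$baseline_mean else min(y)
  start <- list(A = max(y[1] - bl, .Machine$double.eps),
                tau = 3 * trace$frame_interval, c = bl)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-t / tau) + c,
                      start = start,
                      lower = c(A = 0, tau = 1e-6, c = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(tau = NA_real_, amplitude = NA_real_,
                          offset = NA_real_, rss = NA_real_,
                          converged = FALSE, n_points = length(y)),
                     class = "decay_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(tau = unname(cf["tau"]), amplitude = unname(cf["A"]),
                 offset = unname(cf["c"]),
                 rss = sum(stats::resid(fit)^2), converged = TRUE,
                 n_points = length(y)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<decay_fit> tau = %.4g s, A = %.4g, c = %.4g (n = %d)\n",
                x$tau, x$amplitude, x$offset, x$n_points))
  } else {
    cat("<decay_fit> not converged\n")
  }
  invisible(x)
}

#' Dwell time of a detected event
#'
#' Time between the fluorescence rise and the onset of decay: the number
#' of consecutive frames after the peak whose value stays within
#' `k_sd * baseline_sd` of the peak value, times the frame interval.
#' Spontaneous fusion events typically decay immediately (dwell 0);
#' folimycin-staircase events never decay, so the dwell extends to the end
#' of the trace.
#'
#' @inheritParams fit_decay
#' @param k_sd tolerance multiplier on the event's `baseline_sd`
#'   (default 2).
#' @return dwell time in seconds (0 when decay starts immediately).
#' @export
dwell_time <- function(trace, event, k_sd = 2) {
  stopifnot(inherits(trace, "fluorescence_trace"))
  event <- as.list(event)
  onset <- as.integer(event$onset_frame)
  n <- length(trace$values)
  rise_end <- min(onset + 2L, n)
  peak <- onset - 1L + which.max(trace$values[onset:rise_end])
  tol <- k_sd * event$baseline_sd
  last <- peak
  j <- peak + 1L
  while (j <= n && abs(trace$values[j] - trace$values[peak]) <= tol) {
    last <- j
    j <- j + 1L
  }
  (last - peak) * trace$frame_interval
}

#' Onset-aligned average event waveform
#'
#' Aligns detected events at their onset frame, subtracts each event's
#' baseline mean, and returns the per-frame mean waveform with its
#' standard error. Used when individual events are too small for reliable
#' per-event kinetics, in which case decay constants are fit to the
#' average waveform of an experiment.
#'
#' @param traces list of [fluorescence_trace()] (or a single trace); must
#'   share a frame interval. Events are matched to traces by `roi_id`.
#' @param events data.frame from [detect_events()] with at least
#'   `roi_id`, `onset_frame`, `baseline_mean`.
#' @param pre_frames,post_frames frames before / after the onset to
#'   include (the window is `onset - pre_frames .. onset + post_frames`).
#' @return data.frame with columns `frame_offset`, `time_s`, `mean`,
#'   `sem`, `n_events`. Events whose window exceeds their trace are
#'   dropped; an empty usable event set is an error.
#' @export
average_events <- function(traces, events, pre_frames = 8L,
                           post_frames = 25L) {
  if (inherits(traces, "fluorescence_trace")) traces <- list(traces)
  if (is.null(events) || nrow(events) == 0L) {
    stop("no events to average", call. = FALSE)
  }
  ids <- vapply(traces, function(tr) tr$roi_id, character(1))
  dt <- traces[[1]]$frame_interval
  segs <- list()
  for (i in seq_len(nrow(events))) {
    k <- match(events$roi_id[i], ids)
    if (is.na(k)) next
    tr <- traces[[k]]
    f <- events$onset_frame[i]
    lo <- f - pre_frames; hi <- f + post_frames
    if (lo < 1L || hi > length(tr$values)) next
    segs[[length(segs) + 1L]] <-
      tr$values[lo:hi] - events$baseline_mean[i]
  }
  if (!length(segs)) {
    stop("no events with a complete averaging window", call. = FALSE)
  }
  m <- do.call(rbind, segs)
  mu <- colMeans(m)
  sem <- if (nrow(m) > 1L) apply(m, 2, stats::sd) / sqrt(nrow(m)) else
    rep(0, ncol(m))
  data.frame(frame_offset = seq(-pre_frames, post_frames),
             time_s = seq(-pre_frames, post_frames) * dt,
             mean = mu, sem = sem, n_events = nrow(m))
}
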